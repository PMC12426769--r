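# Chemistry-relevant baselines: popularity and nearest neighbor, both
# class-conditional on the most detailed reaction-class label.
#
# Popularity answers "what is usually done for this kind of reaction";
# nearest neighbor answers "what was done for the most similar literature
# reaction of this kind". Both are pure functions of a precomputed
# training index and are the reference points every learned stage must
# beat.

#' Extract the recorded condition set of a reaction record
#'
#' The ground-truth counterpart of a model prediction: agent indices,
#' binned temperature, binned equivalence ratio of every reactant (in
#' record order) and of every agent (aligned to the sorted agent index
#' set).
#'
#' @param record a [reaction_record()] with full condition information.
#' @param vocab an [agent_vocabulary()].
#' @param schemes bin schemes, as from [default_bin_schemes()].
#' @return a [condition_set()].
#' @export
record_condition_set <- function(record, vocab,
                                 schemes = default_bin_schemes()) {
  asmis <- .side_smiles(record$agents)
  idx <- if (length(asmis) == 0L) integer(0) else vocab_index(vocab, asmis)
  eq <- if (length(record$reactants) > 0L &&
            !anyNA(vapply(record$reactants, `[[`, numeric(1), "moles"))) {
    equivalence_ratios(record)
  } else NULL
  r_bins <- if (is.null(eq)) integer(0) else
    assign_bin(eq$reactants, schemes$reactant_amount)
  a_bins <- integer(0)
  agents_sorted <- sort(unique(idx))
  if (length(agents_sorted) > 0L && !is.null(eq) && !anyNA(eq$agents)) {
    bins_by_idx <- stats::setNames(assign_bin(eq$agents, schemes$agent_amount),
                                   idx)
    a_bins <- vapply(agents_sorted, function(v) {
      as.integer(bins_by_idx[[as.character(v)]][1L])
    }, integer(1))
    names(a_bins) <- vocab$agents[agents_sorted]
  } else if (length(agents_sorted) > 0L) {
    a_bins <- rep(NA_integer_, length(agents_sorted))
    names(a_bins) <- vocab$agents[agents_sorted]
  }
  condition_set(agents = agents_sorted,
                temperature_bin = if (is.na(record$temperature_c)) NA_integer_
                                  else assign_bin(record$temperature_c,
                                                  schemes$temperature),
                reactant_bins = r_bins,
                agent_bins = a_bins)
}

.agent_set_key <- function(idx) paste(sort(idx), collapse = ",")

.full_condition_key <- function(cs) {
  paste(.agent_set_key(cs$agents), cs$temperature_bin,
        paste(sort(cs$reactant_bins), collapse = ","),
        paste(cs$agent_bins, collapse = ","), sep = "|")
}

#' Build the class-conditional training index for the baselines
#'
#' Precomputes, per most-detailed reaction class, the recorded condition
#' sets and the reaction fingerprints of the training records.
#'
#' @param records training [reaction_record()]s. Records without a class
#'   label, or with agents outside the vocabulary, are dropped: the index
#'   only ever recommends conditions expressible in the shared vocabulary.
#' @param vocab an [agent_vocabulary()].
#' @param schemes bin schemes.
#' @param radius,n_bits fingerprint parameters.
#' @return an object of class `class_index`.
#' @export
class_index <- function(records, vocab, schemes = default_bin_schemes(),
                        radius = 2L, n_bits = 2048L) {
  cls <- vapply(records, `[[`, character(1), "class_id")
  keep <- !is.na(cls) &
    vapply(records, vocab_covers, logical(1), vocab = vocab)
  records <- records[keep]; cls <- cls[keep]
  by_class <- split(seq_along(records), cls)
  classes <- lapply(by_class, function(rows) {
    conds <- lapply(records[rows], record_condition_set, vocab = vocab,
                    schemes = schemes)
    nz_list <- lapply(records[rows], function(rec) {
      which(reaction_fingerprint(rec, radius = radius, n_bits = n_bits) == 1L)
    })
    fp <- Matrix::sparseMatrix(
      i = rep.int(seq_along(rows), lengths(nz_list)),
      j = unlist(nz_list), x = 1,
      dims = c(length(rows), 2L * n_bits))
    keys <- vapply(conds, .full_condition_key, character(1))
    set_keys <- vapply(conds, function(cs) .agent_set_key(cs$agents),
                       character(1))
    list(n = length(rows), conds = conds, fp = fp, keys = keys,
         set_keys = set_keys)
  })
  structure(list(classes = classes, vocab = vocab, schemes = schemes,
                 radius = radius, n_bits = n_bits),
            class = "class_index")
}

#' @export
print.class_index <- function(x, ...) {
  cat("Baseline index:", length(x$classes), "classes,",
      sum(vapply(x$classes, `[[`, integer(1), "n")), "records\n")
  invisible(x)
}

# Most frequent values of a character key vector, ties lexicographic.
.ranked_by_freq <- function(keys) {
  tab <- table(keys)
  names(tab)[order(-as.integer(tab), names(tab))]
}

.unseen <- function() structure(list(), unseen = TRUE)

#' Is a baseline prediction the unseen-class marker?
#'
#' @param x a baseline prediction.
#' @return TRUE when the query's class was absent from the training index
#'   (scored as incorrect, but distinguishable from a wrong prediction).
#' @export
is_unseen_class <- function(x) isTRUE(attr(x, "unseen"))

#' Popularity baseline
#'
#' The most common conditions within the query's most-detailed reaction
#' class.
#'
#' @param index a [class_index()].
#' @param class_id the query's class label.
#' @param task one of `"agents"`, `"temperature"`, `"reactant_amount"`,
#'   `"agent_amount"`, `"holistic"`.
#' @param k number of ranked predictions (where applicable).
#' @return task-dependent: `agents` -> list of agent index sets ranked by
#'   frequency; `temperature` -> integer bins ranked by frequency;
#'   `reactant_amount` -> the constant bin containing 1.0 equivalents (a
#'   majority baseline: every reaction has a limiting reactant);
#'   `agent_amount` -> named integer vector, the most frequent bin per
#'   agent seen in the class; `holistic` -> ranked complete
#'   [condition_set()]s. Unseen classes return the marker of
#'   [is_unseen_class()].
#' @export
popularity_predict <- function(index, class_id, task, k = 10L) {
  stopifnot(inherits(index, "class_index"))
  task <- match.arg(task, c("agents", "temperature", "reactant_amount",
                            "agent_amount", "holistic"))
  if (task == "reactant_amount") {
    return(assign_bin(1.0, index$schemes$reactant_amount))
  }
  ci <- index$classes[[class_id]]
  if (is.null(ci)) return(.unseen())
  switch(task,
    agents = {
      keys <- utils::head(.ranked_by_freq(ci$set_keys), k)
      lapply(keys, function(kk) {
        if (!nzchar(kk)) integer(0) else as.integer(strsplit(kk, ",")[[1]])
      })
    },
    temperature = {
      tb <- vapply(ci$conds, `[[`, integer(1), "temperature_bin")
      tb <- tb[!is.na(tb)]
      if (length(tb) == 0L) return(.unseen())
      as.integer(utils::head(.ranked_by_freq(as.character(tb)), k))
    },
    agent_amount = {
      pairs <- do.call(rbind, lapply(ci$conds, function(cs) {
        if (length(cs$agent_bins) == 0L || anyNA(cs$agent_bins)) return(NULL)
        data.frame(agent = names(cs$agent_bins), bin = unname(cs$agent_bins),
                   stringsAsFactors = FALSE)
      }))
      if (is.null(pairs)) return(.unseen())
      out <- vapply(split(pairs$bin, pairs$agent), function(b) {
        as.integer(.ranked_by_freq(as.character(b))[1L])
      }, integer(1))
      out
    },
    holistic = {
      keys <- utils::head(.ranked_by_freq(ci$keys), k)
      lapply(keys, function(kk) ci$conds[[match(kk, ci$keys)]])
    })
}

#' Nearest-neighbor baseline
#'
#' Ranks the training records of the query's class by Tanimoto similarity
#' of reaction fingerprints and adopts their conditions. The reaction
#' fingerprint carries no agent information, so (unlike the learned
#' stages) temperature retrieval cannot condition on agents. Ties in
#' similarity break toward the more frequent condition set, then insertion
#' order.
#'
#' @param index a [class_index()].
#' @param query a [reaction_record()] with a class label.
#' @param k number of ranked predictions.
#' @param task as in [popularity_predict()].
#' @return task-dependent, as in [popularity_predict()] except
#'   `reactant_amount` -> ranked list of sorted bin multisets and
#'   `agent_amount` -> ranked list of named per-agent bin vectors; ranked
#'   by neighbor similarity with duplicates removed.
#' @export
nn_predict <- function(index, query, k = 10L, task = "holistic") {
  stopifnot(inherits(index, "class_index"))
  task <- match.arg(task, c("agents", "temperature", "reactant_amount",
                            "agent_amount", "holistic"))
  ci <- index$classes[[query$class_id]]
  if (is.null(ci)) return(.unseen())
  qfp <- reaction_fingerprint(query, radius = index$radius,
                              n_bits = index$n_bits)
  qnz <- which(qfp == 1L)
  inter <- as.numeric(ci$fp %*% qfp)
  un <- Matrix::rowSums(ci$fp) + length(qnz) - inter
  sim <- ifelse(un == 0, 0, inter / un)
  freq <- table(ci$keys)
  key_freq <- as.integer(freq[ci$keys])
  ord <- order(-sim, -key_freq, seq_along(sim))
  take_distinct <- function(values_key) {
    seen <- character(0); out <- integer(0)
    for (i in ord) {
      kk <- values_key[i]
      if (kk %in% seen) next
      seen <- c(seen, kk); out <- c(out, i)
      if (length(out) >= k) break
    }
    out
  }
  switch(task,
    holistic = {
      rows <- take_distinct(ci$keys)
      res <- lapply(rows, function(i) ci$conds[[i]])
      attr(res, "similarity") <- sim[rows]
      res
    },
    agents = {
      rows <- take_distinct(ci$set_keys)
      lapply(rows, function(i) ci$conds[[i]]$agents)
    },
    temperature = {
      tb <- vapply(ci$conds, `[[`, integer(1), "temperature_bin")
      rows <- take_distinct(as.character(tb))
      out <- tb[rows]
      as.integer(out[!is.na(out)])
    },
    reactant_amount = {
      rb <- vapply(ci$conds, function(cs)
        paste(sort(cs$reactant_bins), collapse = ","), character(1))
      rows <- take_distinct(rb)
      lapply(rows, function(i) sort(ci$conds[[i]]$reactant_bins))
    },
    agent_amount = {
      ab <- vapply(ci$conds, function(cs)
        paste(names(cs$agent_bins), cs$agent_bins, sep = "@", collapse = ","),
        character(1))
      rows <- take_distinct(ab)
      lapply(rows, function(i) ci$conds[[i]]$agent_bins)
    })
}
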