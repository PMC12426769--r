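# Preprocessing: quantity standardization, equivalence ratios, condition-level
# deduplication, quality filters, agent vocabulary and document-level split.

#' Standardize a reported quantity to moles
#'
#' Supports the four unit types that cover structured quantity annotations:
#' mol, mmol, g (requires a molecular weight) and mL (requires a molarity).
#' Anything else errors loudly rather than guessing.
#'
#' @param amount positive numeric amount.
#' @param unit one of `"mol"`, `"mmol"`, `"g"`, `"mL"`.
#' @param molecular_weight g/mol, required for `unit = "g"`.
#' @param molarity mol/L, required for `unit = "mL"`.
#' @return moles as a numeric scalar.
#' @export
to_moles <- function(amount, unit, molecular_weight = NULL, molarity = NULL) {
  stopifnot(is.numeric(amount), length(amount) == 1L)
  if (!is.finite(amount) || amount <= 0) stop("amount must be positive, got ", amount)
  switch(unit,
    mol = amount,
    mmol = amount / 1000,
    g = {
      if (is.null(molecular_weight)) stop("unit 'g' requires molecular_weight")
      amount / molecular_weight
    },
    mL = {
      if (is.null(molarity)) stop("unit 'mL' requires molarity")
      amount / 1000 * molarity
    },
    stop("unsupported unit: ", sQuote(unit),
         " (supported: mol, mmol, g, mL)")
  )
}

#' Index of the limiting reactant
#'
#' The limiting reactant is the reactant with the smallest molar amount;
#' ties break to the lowest index. All equivalence ratios are defined
#' relative to it, so its own ratio is 1.0 by definition.
#'
#' @param record a [reaction_record()] whose reactants all carry moles.
#' @return 1-based reactant index.
#' @export
limiting_reactant <- function(record) {
  moles <- vapply(record$reactants, `[[`, numeric(1), "moles")
  if (anyNA(moles)) {
    stop("limiting reactant undefined: reactant(s) ",
         paste(which(is.na(moles)), collapse = ", "), " lack moles")
  }
  which.min(moles)
}

#' Equivalence ratios of every reactant and agent
#'
#' Ratio of each species' molar amount to the limiting reactant's. Species
#' with no recorded moles get an NA ratio (absent, not zero).
#'
#' @param record a [reaction_record()] whose reactants all carry moles.
#' @return list with numeric vectors `reactants` and `agents` (NA where the
#'   agent's amount was not recorded) and integer `limiting` (the limiting
#'   reactant's index).
#' @export
equivalence_ratios <- function(record) {
  li <- limiting_reactant(record)
  lm <- record$reactants[[li]]$moles
  if (!is.finite(lm) || lm <= 0) stop("limiting reactant moles must be positive")
  r <- vapply(record$reactants, `[[`, numeric(1), "moles") / lm
  a <- if (length(record$agents) == 0L) numeric(0) else
    vapply(record$agents, `[[`, numeric(1), "moles") / lm
  list(reactants = r, agents = a, limiting = li)
}

# Condition-level key: canonical reaction SMILES + sorted agent SMILES +
# temperature bin + sorted reactant amount bins + sorted (agent, bin) pairs.
# Excludes document_id on purpose: the same reaction reported with the same
# conditions in two patents is one condition record.
.condition_key <- function(record, schemes) {
  tb <- if (is.na(record$temperature_c)) "T:NA" else
    paste0("T:", assign_bin(record$temperature_c, schemes$temperature))
  rmoles <- vapply(record$reactants, `[[`, numeric(1), "moles")
  rpart <- if (anyNA(rmoles)) "R:NA" else {
    eq <- equivalence_ratios(record)
    paste0("R:", paste(sort(assign_bin(eq$reactants, schemes$reactant_amount)),
                       collapse = ","))
  }
  asmi <- .side_smiles(record$agents)
  amoles <- if (length(record$agents) == 0L) numeric(0) else
    vapply(record$agents, `[[`, numeric(1), "moles")
  apart <- if (length(asmi) == 0L) "A:" else if (anyNA(rmoles) || anyNA(amoles)) {
    paste0("A:", paste(sort(asmi), collapse = ","), ":NA")
  } else {
    eq <- equivalence_ratios(record)
    bins <- assign_bin(eq$agents, schemes$agent_amount)
    ord <- order(asmi, bins)
    paste0("A:", paste(asmi[ord], bins[ord], sep = "@", collapse = ","))
  }
  rxn <- paste(paste(sort(.side_smiles(record$reactants)), collapse = "."),
               paste(sort(.side_smiles(record$products)), collapse = "."),
               sep = ">>")
  paste(rxn, paste(sort(asmi), collapse = ","), tb, rpart, apart, sep = "|")
}

#' Deduplicate reactions at the condition level
#'
#' Two records are duplicates when they share the reaction (reactants and
#' products), the agent set, the temperature bin and the binned amounts of
#' every species; the document of origin is not part of the key. The first
#' occurrence is kept.
#'
#' @param records list of [reaction_record()]s.
#' @param schemes bin schemes as from [default_bin_schemes()].
#' @return list with `records` (the survivors, original order) and
#'   `n_removed`.
#' @export
deduplicate_records <- function(records, schemes = default_bin_schemes()) {
  keys <- vapply(records, .condition_key, character(1), schemes = schemes)
  keep <- !duplicated(keys)
  list(records = records[keep], n_removed = sum(!keep))
}

#' Quality-filter configuration
#'
#' @param max_heavy_atoms per-molecule heavy atom limit.
#' @param max_reactants,max_agents component-count limits.
#' @param require_parsable reject records with unparsable SMILES instead of
#'   erroring.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_heavy_atoms = 100L, max_reactants = 5L,
                          max_agents = 8L, require_parsable = TRUE) {
  stopifnot(max_heavy_atoms > 0L, max_reactants > 0L, max_agents > 0L)
  structure(list(max_heavy_atoms = as.integer(max_heavy_atoms),
                 max_reactants = as.integer(max_reactants),
                 max_agents = as.integer(max_agents),
                 require_parsable = isTRUE(require_parsable)),
            class = "filter_config")
}

#' Filter out low-quality records
#'
#' A record survives iff every molecule parses, every molecule is at or
#' under the heavy-atom limit, the reactant count is between 1 and
#' `max_reactants`, the agent count is at most `max_agents`, and there is at
#' least one product. Rejections are counted per rule, not raised.
#'
#' @param records list of [reaction_record()]s (SMILES not necessarily
#'   canonical; parsability is itself a filter).
#' @param cfg a [filter_config()].
#' @return list with `records` (retained) and `rejections` (named integer
#'   vector: parsability, molecular_size, component_count).
#' @export
filter_records <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  reasons <- c(parsability = 0L, molecular_size = 0L, component_count = 0L)
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    smis <- c(.side_smiles(rec$reactants), .side_smiles(rec$agents),
              .side_smiles(rec$products))
    ok <- tryCatch({ canonicalize_smiles(smis); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      reasons["parsability"] <- reasons["parsability"] + 1L
      next
    }
    if (any(heavy_atom_count(smis) > cfg$max_heavy_atoms)) {
      reasons["molecular_size"] <- reasons["molecular_size"] + 1L
      next
    }
    n_r <- length(rec$reactants); n_a <- length(rec$agents)
    if (n_r < 1L || n_r > cfg$max_reactants || n_a > cfg$max_agents ||
        length(rec$products) < 1L) {
      reasons["component_count"] <- reasons["component_count"] + 1L
      next
    }
    keep[i] <- TRUE
  }
  list(records = records[keep], rejections = reasons)
}

#' Build the agent vocabulary from a corpus
#'
#' Counts occurrences of each canonical agent SMILES among agents that carry
#' a recorded quantity (agents that only ever appear without measurable
#' quantities are excluded), keeps those at or above `min_count`, and orders
#' by descending count then lexicographically so indices are reproducible.
#'
#' @param records list of [reaction_record()]s.
#' @param min_count minimum occurrence count (default 50).
#' @return an [agent_vocabulary()].
#' @export
build_vocabulary <- function(records, min_count = 50L) {
  counted <- unlist(lapply(records, function(rec) {
    if (length(rec$agents) == 0L) return(character(0))
    moles <- vapply(rec$agents, `[[`, numeric(1), "moles")
    .side_smiles(rec$agents)[!is.na(moles)]
  }))
  if (length(counted) == 0L) stop("no agents with measurable quantities in corpus")
  tab <- table(counted)
  keep <- tab[tab >= min_count]
  if (length(keep) == 0L) {
    stop("empty vocabulary: no agent reaches min_count = ", min_count)
  }
  ord <- order(-as.integer(keep), names(keep))
  agent_vocabulary(names(keep)[ord])
}

#' Document-level train/validation/test split
#'
#' Documents are shuffled with a seeded RNG and partitioned by cumulative
#' fractions; all records of a document share a split, so end-to-end
#' evaluation is on held-out documents. Deterministic for a fixed seed.
#'
#' @param records list of [reaction_record()]s.
#' @param fractions train/val/test fractions summing to 1
#'   (default `c(0.75, 0.05, 0.20)`).
#' @param seed integer RNG seed.
#' @return list with `assignment` (named character vector document_id ->
#'   "train"/"val"/"test") and `split` (character vector, one entry per
#'   record).
#' @export
document_split <- function(records, fractions = c(0.75, 0.05, 0.20),
                           seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  docs <- unique(vapply(records, `[[`, character(1), "document_id"))
  if (length(docs) < 3L) stop("need at least 3 documents to split, got ", length(docs))
  docs <- sort(docs)
  shuffled <- docs[with_seed(seed, sample.int(length(docs)))]
  n <- length(docs)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_train <- min(n_train, n - 2L)
  if (n_train + n_val > n - 1L) n_val <- n - 1L - n_train
  lab <- rep("test", n)
  lab[seq_len(n_train)] <- "train"
  if (n_val > 0L) lab[n_train + seq_len(n_val)] <- "val"
  assignment <- stats::setNames(lab, shuffled)
  split <- unname(assignment[vapply(records, `[[`, character(1), "document_id")])
  list(assignment = assignment, split = split)
}

#' Does the vocabulary cover a record's agent set?
#'
#' TRUE when every agent of the record (possibly none) is a vocabulary
#' member. Training, baseline indexing and exact-match evaluation are all
#' restricted to covered records: a condition set containing an
#' out-of-vocabulary agent is not expressible by any model or baseline
#' sharing the vocabulary.
#'
#' @param record a [reaction_record()].
#' @param vocab an [agent_vocabulary()].
#' @return logical scalar.
#' @export
vocab_covers <- function(record, vocab) {
  asmi <- .side_smiles(record$agents)
  length(asmi) == 0L ||
    !anyNA(vocab_index(vocab, asmi, strict = FALSE))
}

#' Stage-specific training examples
#'
#' Each stage trains on the subset of records that carries the labels the
#' stage needs: stage 1 requires a nonempty in-vocabulary agent set; stage 2
#' additionally requires a temperature; stage 3 requires all reactant moles;
#' stage 4 requires all agent moles.
#'
#' @param records list of [reaction_record()]s.
#' @param vocab an [agent_vocabulary()].
#' @param stage integer 1-4.
#' @return the eligible subset of `records`.
#' @export
stage_filter <- function(records, vocab, stage) {
  stopifnot(stage %in% 1:4)
  Filter(function(rec) {
    asmi <- .side_smiles(rec$agents)
    if (length(asmi) == 0L) return(FALSE)
    if (anyNA(vocab_index(vocab, asmi, strict = FALSE))) return(FALSE)
    if (stage == 2L && is.na(rec$temperature_c)) return(FALSE)
    if (stage >= 3L) {
      rmoles <- vapply(rec$reactants, `[[`, numeric(1), "moles")
      if (anyNA(rmoles)) return(FALSE)
    }
    if (stage == 4L) {
      amoles <- vapply(rec$agents, `[[`, numeric(1), "moles")
      if (anyNA(amoles)) return(FALSE)
    }
    TRUE
  }, records)
}
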