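# Autoregressive set decoding and end-to-end candidate construction.
#
# Agent identity is trained as multi-label completion but decoded as a
# sequence: one agent at a time, conditioned on the partial set, until the
# end-of-set symbol. Orders are interchangeable, so hypotheses that reach
# the same unordered set are merged by summing their joint probabilities --
# both while partial (the model only sees the set) and when complete.

#' Beam-search decoding of agent sets
#'
#' Standard breadth-limited search over decoding steps. At each step every
#' live hypothesis is extended with each non-member agent (probability =
#' the model's output for that agent given the partial set) or terminated
#' with the end-of-set symbol. Hypotheses with the same unordered agent set
#' are merged by summing their joint probabilities, which makes the search
#' exact (equal to exhaustive enumeration over all decoding orders)
#' whenever the width retains every reachable set. Deterministic; ties in
#' the final ranking break toward smaller sets, then lexicographic indices.
#'
#' @param model a stage-1 `stage_model`, or a function
#'   `f(agent_multihot_matrix)` returning a `k x (V+1)` matrix of
#'   probabilities (a stub for testing); in the latter case `vocab_size`
#'   must be given.
#' @param reaction_fp reaction fingerprint (ignored for a function model).
#' @param class_onehot class one-hot (ignored for a function model).
#' @param width beam width (>= 1).
#' @param max_len maximum agent-set size.
#' @param vocab_size vocabulary size |V| when `model` is a function.
#' @param normalize `"sigmoid"` uses the per-agent outputs as conditional
#'   selection probabilities directly; `"softmax"` renormalizes over
#'   non-members plus EOS at each step. Defaults to the model's head (or
#'   sigmoid for stubs).
#' @return ranked list of hypotheses `list(agents = sorted indices,
#'   probability = merged joint probability, complete = TRUE)`.
#' @export
beam_search_agents <- function(model, reaction_fp = NULL,
                               class_onehot = NULL, width = 10L,
                               max_len = 6L, vocab_size = NULL,
                               normalize = NULL) {
  if (width < 1L) stop("beam width must be >= 1")
  if (is.function(model)) {
    if (is.null(vocab_size)) stop("vocab_size required for a function model")
    V <- as.integer(vocab_size)
    prob_fn <- model
    if (is.null(normalize)) normalize <- "sigmoid"
  } else {
    stopifnot(inherits(model, "stage_model"), model$stage == 1L)
    V <- length(model$vocab)
    if (is.null(normalize)) normalize <- model$head
    prob_fn <- function(am) {
      p <- stage_predict(model, list(reaction_fp = reaction_fp,
                                     class_onehot = class_onehot,
                                     agent_multihot = am))
      if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
      p
    }
  }
  eos <- V + 1L
  key_of <- function(idx) paste0("s", paste(idx, collapse = ","))

  live <- list(list(agents = integer(0), prob = 1))
  completed <- new.env(parent = emptyenv())
  for (step in 0:max_len) {
    if (length(live) == 0L) break
    am <- matrix(0, nrow = length(live), ncol = V)
    for (i in seq_along(live)) am[i, live[[i]]$agents] <- 1
    P <- prob_fn(am)
    if (!is.matrix(P) || ncol(P) != eos) {
      stop("stage-1 model must emit ", eos, " probabilities per hypothesis")
    }
    nxt <- new.env(parent = emptyenv())
    for (i in seq_along(live)) {
      hyp <- live[[i]]
      p <- P[i, ]
      allowed <- setdiff(seq_len(V), hyp$agents)
      if (normalize == "softmax") {
        z <- sum(p[c(allowed, eos)])
        if (z > 0) p <- p / z
      }
      k <- key_of(hyp$agents)
      prev <- completed[[k]]
      completed[[k]] <- (if (is.null(prev)) 0 else prev) + hyp$prob * p[eos]
      if (step < max_len) {
        for (a in allowed) {
          newset <- sort(c(hyp$agents, a))
          nk <- key_of(newset)
          cur <- nxt[[nk]]
          if (is.null(cur)) {
            nxt[[nk]] <- list(agents = newset, prob = hyp$prob * p[a])
          } else {
            cur$prob <- cur$prob + hyp$prob * p[a]
            nxt[[nk]] <- cur
          }
        }
      }
    }
    cand <- as.list(nxt)
    if (length(cand) > width) {
      probs <- vapply(cand, `[[`, numeric(1), "prob")
      cand <- cand[order(-probs)][seq_len(width)]
    }
    live <- unname(cand)
  }
  keys <- ls(completed)
  sets <- lapply(keys, function(k) {
    body <- substring(k, 2L)
    if (!nzchar(body)) integer(0) else as.integer(strsplit(body, ",")[[1]])
  })
  probs <- vapply(keys, function(k) completed[[k]], numeric(1))
  sizes <- lengths(sets)
  lex <- vapply(sets, function(s) paste(sprintf("%06d", s), collapse = ""),
                character(1))
  ord <- order(-probs, sizes, lex)
  lapply(ord, function(i) list(agents = sets[[i]], probability = probs[i],
                               complete = TRUE))
}

#' Top-m joint bin assignments over independent components
#'
#' Given one probability simplex per component (e.g. one per reactant), the
#' joint probability of an assignment is the product over components. A
#' per-component beam of width `m` returns the `m` best joint assignments;
#' this is exact for `m <= 2`.
#'
#' @param dists list of numeric probability vectors (one per component).
#' @param m number of joint assignments to return.
#' @return ranked list of `list(bins = integer vector, probability =)`.
#'   With zero components, a single empty assignment of probability 1.
#' @export
top_m_joint_assignment <- function(dists, m = 2L) {
  stopifnot(m >= 1L)
  if (any(vapply(dists, length, integer(1)) == 0L)) {
    stop("empty component distribution")
  }
  partial <- list(list(bins = integer(0), probability = 1))
  for (d in dists) {
    top <- order(-d)[seq_len(min(m, length(d)))]
    ext <- list()
    for (p in partial) {
      for (b in top) {
        ext[[length(ext) + 1L]] <- list(bins = c(p$bins, b),
                                        probability = p$probability * d[b])
      }
    }
    probs <- vapply(ext, `[[`, numeric(1), "probability")
    partial <- ext[order(-probs)][seq_len(min(m, length(ext)))]
  }
  partial
}

#' Weighted geometric-mean confidence of a condition set
#'
#' @param confidences the four stage confidences, each in (0, 1].
#' @param weights non-negative weights, not all zero.
#' @return `exp(sum(w * log(c)) / sum(w))`, in (0, 1]. Monotone in every
#'   confidence and invariant to rescaling all weights.
#' @export
confidence_score <- function(confidences, weights = c(1, 1, 1, 1)) {
  stopifnot(length(confidences) == length(weights))
  if (any(confidences <= 0)) stop("stage confidences must be in (0, 1]")
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop("weights must be finite and non-negative")
  }
  sw <- sum(weights)
  if (sw == 0) stop("weights must not all be zero")
  exp(sum(weights * log(confidences)) / sw)
}

#' Combine stage outputs into ranked end-to-end candidates
#'
#' Takes the per-agent-set stage outputs of a query and enumerates the
#' Cartesian combinations: top `counts[1]` agent sets x top `counts[2]`
#' temperature bins x top `counts[3]` joint reactant assignments x top
#' `counts[4]` joint agent-amount assignments (at the default counts
#' 10 x 2 x 2 x 2 = 80 candidates). Each candidate is scored by
#' [confidence_score()] with stage confidences (merged set probability,
#' chosen temperature bin probability, joint reactant probability, joint
#' agent-amount probability) and the candidates are ranked by descending
#' score.
#'
#' @param stage_outputs list with one element per candidate agent set, each
#'   `list(agents =, c1 =, temperature_dist =, reactant_dists = list,
#'   agent_amount_dists = list aligned to agents)`; see
#'   [predict_conditions()] for the construction from trained models.
#' @param counts integer vector (agent sets, temperatures, reactant
#'   assignments, agent assignments).
#' @param weights confidence weights.
#' @return ranked list of [condition_set()]s.
#' @export
combine_conditions <- function(stage_outputs, counts = c(10L, 2L, 2L, 2L),
                               weights = c(1, 1, 1, 1)) {
  stopifnot(length(counts) == 4L, all(counts >= 1L))
  sets <- utils::head(stage_outputs, counts[1])
  out <- list()
  for (so in sets) {
    t_top <- order(-so$temperature_dist)[seq_len(min(counts[2],
                                                     length(so$temperature_dist)))]
    r_joint <- top_m_joint_assignment(so$reactant_dists, m = counts[3])
    a_joint <- if (length(so$agent_amount_dists) == 0L) {
      list(list(bins = integer(0), probability = 1))
    } else {
      top_m_joint_assignment(so$agent_amount_dists, m = counts[4])
    }
    for (tb in t_top) {
      for (rj in r_joint) {
        for (aj in a_joint) {
          conf <- c(so$c1, so$temperature_dist[tb], rj$probability,
                    aj$probability)
          out[[length(out) + 1L]] <- condition_set(
            agents = so$agents,
            temperature_bin = tb,
            reactant_bins = rj$bins,
            agent_bins = aj$bins,
            confidences = conf,
            score = confidence_score(conf, weights))
        }
      }
    }
  }
  scores <- vapply(out, `[[`, numeric(1), "score")
  out[order(-scores)]
}

#' Select confidence weights on a validation set
#'
#' Grid search over a weight lattice: for every lattice point the
#' end-to-end candidates of every validation query are re-ranked with those
#' weights and the weights maximizing top-`k` exact-match accuracy are
#' returned (ties break to the first lattice point in order).
#'
#' @param validation list of `list(stage_outputs =, truth =)` per query,
#'   where `stage_outputs` is as in [combine_conditions()] and `truth` a
#'   [condition_set()].
#' @param grid numeric matrix with 4 columns (one row per lattice point);
#'   default lattice `{0.25, 0.5, 1, 2}^4`.
#' @param counts candidate counts, as in [combine_conditions()].
#' @param top_k accuracy horizon (default 10).
#' @return list with `weights` (numeric length 4) and `accuracy`.
#' @export
fit_confidence_weights <- function(validation, grid = NULL,
                                   counts = c(10L, 2L, 2L, 2L),
                                   top_k = 10L) {
  if (is.null(grid)) {
    lattice <- c(0.25, 0.5, 1, 2)
    grid <- as.matrix(expand.grid(w1 = lattice, w2 = lattice,
                                  w3 = lattice, w4 = lattice))
  }
  grid <- as.matrix(grid)
  if (nrow(grid) == 0L) stop("empty weight grid")
  stopifnot(ncol(grid) == 4L)
  best_acc <- -1; best_w <- NULL
  for (g in seq_len(nrow(grid))) {
    w <- as.numeric(grid[g, ])
    hits <- vapply(validation, function(q) {
      cands <- utils::head(combine_conditions(q$stage_outputs, counts, w),
                           top_k)
      any(vapply(cands, function(cs) {
        end_to_end_correct(cs, q$truth)$overall
      }, logical(1)))
    }, logical(1))
    acc <- mean(hits)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best_w <- w
    }
  }
  list(weights = best_w, accuracy = best_acc)
}
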