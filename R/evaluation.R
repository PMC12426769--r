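# Metrics: relaxed/strict agent-set accuracy, off-by-N and bin MAE,
# reaction-level amount categories, end-to-end exact match, and pairwise
# win rates with confidence intervals.

#' Relaxed agent-set equality (water-insensitive)
#'
#' Agent sets are compared as unordered sets of canonical SMILES,
#' disregarding the presence or absence of water ("O"), whose reporting in
#' reaction data is inconsistent.
#'
#' @param pred,truth character vectors of canonical agent SMILES.
#' @return logical.
#' @export
relaxed_set_equal <- function(pred, truth) {
  setequal(setdiff(pred, "O"), setdiff(truth, "O"))
}

#' Top-k accuracy of ranked predictions
#'
#' @param predictions list (one element per query) of ranked prediction
#'   lists.
#' @param truths list of ground truths, aligned with `predictions`.
#' @param k horizon (>= 1).
#' @param matcher function `(prediction, truth) -> logical`.
#' @return fraction of queries whose truth matches any of the first `k`
#'   predictions. Nondecreasing in `k`.
#' @export
topk_accuracy <- function(predictions, truths, k, matcher) {
  if (k < 1L) stop("k must be >= 1")
  stopifnot(length(predictions) == length(truths))
  hits <- vapply(seq_along(predictions), function(i) {
    preds <- utils::head(predictions[[i]], k)
    any(vapply(preds, matcher, logical(1), truths[[i]]))
  }, logical(1))
  mean(hits)
}

#' Off-by-N accuracy and bin MAE
#'
#' Ordinal metrics for binned predictions: the fraction of predictions
#' within `N` bins of the true bin, and the mean absolute bin distance.
#'
#' @param pred,true integer bin vectors of equal length.
#' @param N tolerance in bins (0 = exact bin).
#' @return `off_by_n_accuracy`: fraction in \[0, 1\]; `bin_mae`: mean
#'   absolute error in bins.
#' @export
off_by_n_accuracy <- function(pred, true, N) {
  if (length(pred) != length(true)) {
    stop("length mismatch: ", length(pred), " vs ", length(true))
  }
  mean(bin_distance(pred, true) <= N)
}

#' @rdname off_by_n_accuracy
#' @export
bin_mae <- function(pred, true) {
  if (length(pred) != length(true)) {
    stop("length mismatch: ", length(pred), " vs ", length(true))
  }
  mean(bin_distance(pred, true))
}

#' Reaction-level amount category
#'
#' Groups per-component bin predictions of one reaction into three
#' mutually exclusive buckets: `exact` (every component in the correct
#' bin), `off_by_one` (all within one bin, excluding exact matches) and
#' `major` (at least one component off by more than one bin).
#'
#' @param pred,true aligned integer bin vectors (one entry per component).
#' @return one of `"exact"`, `"off_by_one"`, `"major"`.
#' @export
reaction_level_category <- function(pred, true) {
  if (length(pred) != length(true)) {
    stop("misaligned components: ", length(pred), " vs ", length(true))
  }
  d <- bin_distance(pred, true)
  if (all(d == 0L)) "exact"
  else if (all(d <= 1L)) "off_by_one"
  else "major"
}

#' End-to-end exact-match verdict
#'
#' Stage 1 requires agent-set equality at index level (no water
#' relaxation); stage 2 the same temperature bin; stage 3 equality of the
#' reactant-bin frequency distributions (multisets -- no reactant-to-bin
#' correspondence is enforced, because holistic baselines cannot assign a
#' bin to a specific reactant; the same criterion is applied to models and
#' baselines alike); stage 4 the same agent set and, for every agent, the
#' same amount bin. Overall correct iff all four stages are.
#'
#' @param pred,truth [condition_set()]s over the same vocabulary and bin
#'   schemes.
#' @return list with logicals `stage1`..`stage4`, `overall`, and
#'   `amount_category` (the [reaction_level_category()] of the sorted
#'   reactant bins, or `"major"` when the counts differ).
#' @export
end_to_end_correct <- function(pred, truth) {
  stopifnot(inherits(pred, "condition_set"), inherits(truth, "condition_set"))
  s1 <- identical(sort(pred$agents), sort(truth$agents))
  s2 <- !is.na(pred$temperature_bin) && !is.na(truth$temperature_bin) &&
    pred$temperature_bin == truth$temperature_bin
  s3 <- length(pred$reactant_bins) == length(truth$reactant_bins) &&
    identical(sort(pred$reactant_bins), sort(truth$reactant_bins))
  s4 <- s1 && length(pred$agent_bins) == length(truth$agent_bins) &&
    !anyNA(pred$agent_bins) && !anyNA(truth$agent_bins) &&
    all(unname(pred$agent_bins) == unname(truth$agent_bins))
  cat3 <- if (length(pred$reactant_bins) == length(truth$reactant_bins)) {
    reaction_level_category(sort(pred$reactant_bins),
                            sort(truth$reactant_bins))
  } else "major"
  list(stage1 = s1, stage2 = isTRUE(s2), stage3 = s3, stage4 = s4,
       overall = s1 && isTRUE(s2) && s3 && s4,
       amount_category = cat3)
}

# Wilson score interval (no continuity correction); accepts fractional
# success counts (ties contribute half a win).
.wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Pairwise win rate of two methods with confidence intervals
#'
#' For each query, method A "wins" when A has a correct condition set in
#' its top `top_k` and B does not (and vice versa); queries where both are
#' correct count as a split tie (half a win each, the default) and queries
#' where neither is correct are excluded. The win rate is A's wins over
#' the counted queries with a 95\% Wilson score interval; a method's
#' advantage is significant when the interval's lower bound exceeds 0.5.
#'
#' @param preds_A,preds_B lists (per query) of ranked [condition_set()]s.
#' @param truths list of ground-truth [condition_set()]s.
#' @param grouping optional character vector of group labels per query
#'   (e.g. a reaction-class tier); NULL pools all queries.
#' @param top_k horizon for "has a correct prediction".
#' @param ties `"half"` (both-correct queries count 0.5 win for each) or
#'   `"exclude"`.
#' @param conf confidence level for the Wilson interval.
#' @return data.frame with one row per group: `group`, `n` (counted
#'   queries), `wins_a`, `win_rate`, `lower`, `upper`. Groups with zero
#'   counted queries are absent.
#' @export
win_rate <- function(preds_A, preds_B, truths, grouping = NULL,
                     top_k = 10L, ties = c("half", "exclude"),
                     conf = 0.95) {
  ties <- match.arg(ties)
  stopifnot(length(preds_A) == length(truths),
            length(preds_B) == length(truths))
  if (is.null(grouping)) grouping <- rep("all", length(truths))
  has_correct <- function(preds, truth) {
    if (is_unseen_class(preds) || length(preds) == 0L) return(FALSE)
    any(vapply(utils::head(preds, top_k), function(cs) {
      end_to_end_correct(cs, truth)$overall
    }, logical(1)))
  }
  ok_a <- vapply(seq_along(truths), function(i)
    has_correct(preds_A[[i]], truths[[i]]), logical(1))
  ok_b <- vapply(seq_along(truths), function(i)
    has_correct(preds_B[[i]], truths[[i]]), logical(1))
  rows <- list()
  for (g in unique(grouping)) {
    sel <- grouping == g
    a <- ok_a[sel]; b <- ok_b[sel]
    counted <- a | b
    if (ties == "exclude") counted <- counted & !(a & b)
    n <- sum(counted)
    if (n == 0L) next
    wins <- sum(a[counted] & !b[counted]) +
      if (ties == "half") 0.5 * sum(a[counted] & b[counted]) else 0
    ci <- .wilson_interval(wins, n, conf)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n = n, wins_a = wins, win_rate = wins / n,
      lower = ci[["lower"]], upper = ci[["upper"]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(group = character(0), n = integer(0),
                      wins_a = numeric(0), win_rate = numeric(0),
                      lower = numeric(0), upper = numeric(0)))
  }
  do.call(rbind, rows)
}
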