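# ConditionSet: one complete condition prediction (or ground truth).

#' Construct a condition set
#'
#' The unit of end-to-end prediction: an agent index set, a temperature
#' bin, per-reactant amount bins (aligned to the reactant order of the
#' query record), per-agent amount bins (aligned to the agent index set),
#' the four stage confidences and a combined score.
#'
#' @param agents sorted integer vector of vocabulary indices (possibly
#'   empty).
#' @param temperature_bin integer temperature bin.
#' @param reactant_bins integer vector of reactant amount bins.
#' @param agent_bins integer vector of agent amount bins, exactly covering
#'   `agents` (same length and order).
#' @param confidences numeric vector c1..c4 in (0, 1].
#' @param score combined confidence score.
#' @return an object of class `condition_set`.
#' @export
condition_set <- function(agents, temperature_bin = NA_integer_,
                          reactant_bins = integer(0),
                          agent_bins = integer(0),
                          confidences = c(1, 1, 1, 1), score = NA_real_) {
  agents <- as.integer(agents)
  if (is.unsorted(agents)) agents <- sort(agents)
  if (anyDuplicated(agents)) stop("duplicate agents in condition set")
  if (length(agent_bins) != length(agents)) {
    stop("agent_bins (", length(agent_bins), ") must exactly cover the agent set (",
         length(agents), ")")
  }
  stopifnot(length(confidences) == 4L)
  structure(list(agents = agents,
                 temperature_bin = as.integer(temperature_bin),
                 reactant_bins = as.integer(reactant_bins),
                 agent_bins = stats::setNames(as.integer(agent_bins),
                                              names(agent_bins)),
                 confidences = as.numeric(confidences),
                 score = as.numeric(score)),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("Condition set: agents {", paste(x$agents, collapse = ","),
      "} T-bin ", x$temperature_bin,
      " reactant bins (", paste(x$reactant_bins, collapse = ","),
      ") agent bins (", paste(x$agent_bins, collapse = ","),
      ") score ", signif(x$score, 4), "\n", sep = "")
  invisible(x)
}

#' Render a condition set as a human-readable record
#'
#' Bins are reported by their in-bin representative values rather than as
#' intervals (the 0-10 degC bin reads as 5 degC; the bin containing 1.0
#' equivalents reads as 1.0).
#'
#' @param cs a [condition_set()].
#' @param vocab the [agent_vocabulary()] the indices refer to.
#' @param schemes bin schemes, as from [default_bin_schemes()].
#' @return a list with `agents` (SMILES), `temperature_c`,
#'   `reactant_equivalents`, `agent_equivalents` (named by agent SMILES),
#'   `score`.
#' @export
describe_prediction <- function(cs, vocab, schemes = default_bin_schemes()) {
  stopifnot(inherits(cs, "condition_set"), inherits(vocab, "agent_vocabulary"))
  agents <- if (length(cs$agents) == 0L) "(no agents)" else
    vocab$agents[cs$agents]
  list(
    agents = agents,
    temperature_c = if (is.na(cs$temperature_bin)) NA_real_ else
      bin_representative(schemes$temperature, cs$temperature_bin),
    reactant_equivalents = if (length(cs$reactant_bins) == 0L) numeric(0) else
      bin_representative(schemes$reactant_amount, cs$reactant_bins),
    agent_equivalents = if (length(cs$agent_bins) == 0L) numeric(0) else
      stats::setNames(bin_representative(schemes$agent_amount, cs$agent_bins),
                      vocab$agents[cs$agents]),
    score = cs$score)
}
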