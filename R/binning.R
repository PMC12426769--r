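# Discretization schemes for temperature and equivalence ratios.
#
# All three prediction targets beyond agent identity are binned classification
# problems: regression fits the highly irregular empirical distributions of
# temperatures and equivalence ratios poorly, while bins centered on the
# values chemists actually use (1.0, 1.5, 2.0, 2.5 equivalents; catalytic,
# stoichiometric and solvent-scale agent loadings) match usage patterns.
# Bins are half-open [lo, hi); out-of-range values clip to the first/last bin
# because extreme solvent-scale ratios are expected in real data.

#' Construct a bin scheme
#'
#' @param edges strictly increasing numeric boundaries; the last may be
#'   `Inf`. Bins are half-open `[edges[i], edges[i+1])`.
#' @param representative one value per bin, reported to users in place of the
#'   interval (e.g. the 20-30 degC bin is reported as 25 degC); must lie
#'   inside its bin. Defaults to midpoints (finite bins only).
#' @return object of class `bin_scheme` with fields `edges`, `n_bins`,
#'   `representative`.
#' @export
bin_scheme <- function(edges, representative = NULL) {
  edges <- as.numeric(edges)
  stopifnot(length(edges) >= 2L)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  n <- length(edges) - 1L
  if (is.null(representative)) {
    representative <- (edges[-length(edges)] + edges[-1]) / 2
    if (!is.finite(representative[n])) {
      representative[n] <- edges[n] + 1
    }
    if (!is.finite(representative[1])) {
      representative[1] <- edges[2] - 1
    }
  }
  representative <- as.numeric(representative)
  stopifnot(length(representative) == n)
  inside <- representative >= edges[-length(edges)] & representative < edges[-1]
  if (!all(inside)) {
    stop("representative value(s) outside their bin: index ",
         paste(which(!inside), collapse = ", "))
  }
  structure(list(edges = edges, n_bins = n, representative = representative),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("Bin scheme:", x$n_bins, "half-open bins over [",
      x$edges[1], ",", x$edges[length(x$edges)], ")\n")
  invisible(x)
}

#' Default temperature bins: 30 uniform 10 degC bins over -100 to 200 degC
#'
#' @return a [bin_scheme()] with 30 bins; bin `[20, 30)` is the room
#'   temperature bin and is reported as 25 degC.
#' @export
temperature_bins <- function() {
  bin_scheme(seq(-100, 200, by = 10), seq(-95, 195, by = 10))
}

#' Default reactant equivalence-ratio bins (15 bins)
#'
#' Narrow dedicated bins around the empirically dominant equivalence ratios
#' 1.0, 1.5, 2.0 and 2.5, with wider bins elsewhere. The limiting reactant
#' always falls in the bin containing 1.0.
#'
#' @param edges,representative optional overrides (retraining with
#'   alternative bin definitions needs no code change).
#' @return a [bin_scheme()] with 15 bins by default.
#' @export
reactant_amount_bins <- function(edges = NULL, representative = NULL) {
  if (is.null(edges)) {
    edges <- c(0, 0.5, 0.95, 1.05, 1.15, 1.35, 1.55, 1.95, 2.05, 2.45,
               2.55, 3.5, 5, 7.5, 15, Inf)
    if (is.null(representative)) {
      representative <- c(0.25, 0.75, 1.0, 1.1, 1.25, 1.5, 1.75, 2.0, 2.25,
                          2.5, 3.0, 4.0, 6.0, 10.0, 20.0)
    }
  }
  bin_scheme(edges, representative)
}

#' Default agent equivalence-ratio bins (27 bins)
#'
#' Agents span catalytic (substoichiometric), stoichiometric and
#' solvent-scale (superstoichiometric) regimes, so the bins cover roughly
#' 1e-4 to 1e3 equivalents with a resolution that tracks the empirical
#' peaks in each regime.
#'
#' @param edges,representative optional overrides.
#' @return a [bin_scheme()] with 27 bins by default.
#' @export
agent_amount_bins <- function(edges = NULL, representative = NULL) {
  if (is.null(edges)) {
    edges <- c(0, 1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
               0.8, 0.95, 1.05, 1.25, 1.55, 2.05, 2.55, 3.5, 5, 7.5, 10,
               20, 50, 100, 300, 1000, Inf)
    if (is.null(representative)) {
      representative <- c(5e-5, 2e-4, 6e-4, 2e-3, 5e-3, 0.015, 0.03, 0.075,
                          0.15, 0.3, 0.6, 0.9, 1.0, 1.1, 1.5, 2.0, 2.5, 3.0,
                          4.0, 6.0, 8.0, 15, 30, 75, 200, 500, 1500)
    }
  }
  bin_scheme(edges, representative)
}

#' Assign values to bins
#'
#' Half-open convention: `x` in `[edges[i], edges[i+1])` maps to bin `i`.
#' Values below the first edge clip to bin 1; values at or above the last
#' finite edge clip to the last bin.
#'
#' @param x numeric vector of finite values.
#' @param scheme a [bin_scheme()].
#' @return integer vector of 1-based bin indices.
#' @export
assign_bin <- function(x, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (any(!is.finite(x))) stop("cannot bin non-finite value(s)")
  idx <- findInterval(x, scheme$edges, left.open = FALSE, rightmost.closed = FALSE)
  pmin(pmax(idx, 1L), scheme$n_bins)
}

#' Distance between two bin indices, in bins
#'
#' The unit in which off-by-N accuracy and bin MAE are measured.
#'
#' @param i,j bin indices (vectors recycle).
#' @return non-negative integer vector `|i - j|`.
#' @export
bin_distance <- function(i, j) {
  abs(as.integer(i) - as.integer(j))
}

#' Representative value of bins
#'
#' @param scheme a [bin_scheme()].
#' @param idx integer bin indices.
#' @return numeric vector of in-bin representative values.
#' @export
bin_representative <- function(scheme, idx) {
  stopifnot(inherits(scheme, "bin_scheme"))
  stopifnot(all(idx >= 1L & idx <= scheme$n_bins))
  scheme$representative[idx]
}

#' Serialize a bin scheme to a YAML file
#'
#' @param scheme a [bin_scheme()].
#' @param path output path.
#' @export
write_bin_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "bin_scheme"))
  edges <- scheme$edges
  edges_chr <- ifelse(is.infinite(edges), ifelse(edges > 0, ".inf", "-.inf"),
                      as.character(edges))
  yaml::write_yaml(list(edges = edges_chr,
                        representative = scheme$representative), path)
  invisible(path)
}

#' Read a bin scheme from a YAML file
#'
#' @param path path to a file written by [write_bin_scheme()].
#' @return a [bin_scheme()].
#' @export
read_bin_scheme <- function(path) {
  obj <- yaml::read_yaml(path)
  edges <- vapply(obj$edges, function(e) {
    if (identical(e, ".inf")) Inf
    else if (identical(e, "-.inf")) -Inf
    else as.numeric(e)
  }, numeric(1))
  bin_scheme(edges, as.numeric(obj$representative))
}

#' The three default bin schemes as a named list
#'
#' @return list with elements `temperature`, `reactant_amount`,
#'   `agent_amount`.
#' @export
default_bin_schemes <- function() {
  list(temperature = temperature_bins(),
       reactant_amount = reactant_amount_bins(),
       agent_amount = agent_amount_bins())
}
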