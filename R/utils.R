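# Seed discipline shared by every randomized step in the package.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so package functions never perturb the user's random
#' stream. All randomness in this package flows through this helper.
#'
#' @param seed integer seed (< 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a base seed and a label
#'
#' Deterministically maps `(seed, label)` to a new seed in `[0, 2^31)`, so
#' independent pipeline steps (world generation, sampling, each stage's
#' training) get distinct but reproducible random streams from one master
#' seed. Cheap polynomial rolling hash (not cryptographic); all
#' intermediates stay below 2^53, so the arithmetic is exact in doubles.
#'
#' @param seed integer master seed.
#' @param label character label naming the consumer.
#' @return an integer seed suitable for [with_seed()].
#' @export
derive_seed <- function(seed, label) {
  h <- 17
  for (b in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 69069 + b + 1) %% 2147483563
  }
  as.integer(h %% 2147483647)
}
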