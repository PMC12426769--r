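# Minimal feed-forward network engine used by the four stage models.
#
# A deliberately small, fully deterministic MLP (ReLU hidden layers, Adam,
# seeded minibatch shuffling) written on top of base matrix algebra, with
# sparse-input support via the Matrix package: reaction fingerprints are
# 0/1 vectors with a few dozen set bits, so training matrices are stored
# sparse and the first-layer products exploit that.
#
# Three loss heads cover the four stages:
#   bce        independent sigmoid + binary cross-entropy per output
#              (multi-label agent prediction)
#   ce         softmax cross-entropy over one bin axis (temperature,
#              reactant amount)
#   masked_ce  a (vocabulary x bins) grid of logits; each PRESENT agent
#              contributes the cross-entropy of its own bin softmax,
#              absent agents contribute zero loss and zero gradient
#              (agent amount)

.relu <- function(x) x * (x > 0)

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# He-initialized network. `sizes` = c(input, hidden..., output).
#' @keywords internal
mlp_new <- function(sizes, seed = 1L) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  with_seed(seed, {
    layers <- vector("list", length(sizes) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- sizes[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                                sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = sizes[l + 1L]),
        b = rep(0, sizes[l + 1L]))
    }
    structure(list(sizes = sizes, layers = layers), class = "condrec_mlp")
  })
}

# Forward pass; returns final logits and (optionally) hidden activations.
#' @keywords internal
mlp_forward <- function(net, X, keep_activations = FALSE) {
  acts <- list(X)
  A <- X
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    Z <- as.matrix(A %*% net$layers[[l]]$W)
    Z <- sweep(Z, 2L, net$layers[[l]]$b, "+")
    A <- if (l < nl) .relu(Z) else Z
    if (keep_activations) acts[[l + 1L]] <- A
  }
  if (keep_activations) list(logits = A, acts = acts) else A
}

# ---- losses -----------------------------------------------------------

# Binary cross-entropy with logits; Y is a 0/1 matrix. Mean over entries.
.loss_bce <- function(logits, Y) {
  p <- .sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(Y * log(p + eps) + (1 - Y) * log(1 - p + eps))
  grad <- (p - Y) / length(Y)
  list(loss = loss, grad = grad)
}

# Softmax cross-entropy; y is an integer label vector. Mean over rows.
.loss_ce <- function(logits, y) {
  p <- .softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(p[idx] + 1e-12))
  grad <- p
  grad[idx] <- grad[idx] - 1
  list(loss = loss, grad = grad / n)
}

#' Masked per-agent softmax cross-entropy
#'
#' The agent-amount head emits a `(vocabulary x n_bins)` grid of logits per
#' example. Each agent present in the example contributes the cross-entropy
#' of the softmax over its own bin row; absent agents contribute exactly
#' zero loss and zero gradient, which is what restricts the head to
#' relevant agents.
#'
#' @param logits numeric matrix `n x (V * n_bins)`, row-major by agent:
#'   columns `((v-1)*n_bins + 1):(v*n_bins)` belong to agent `v`.
#' @param labels integer matrix `n x V`; entry `(i, v)` is agent `v`'s true
#'   bin in example `i`, or 0 when the agent is absent.
#' @param n_bins number of amount bins per agent.
#' @return list with `loss` (scalar; mean over present agents) and `grad`
#'   (same shape as `logits`; zero on absent-agent columns).
#' @export
masked_softmax_loss <- function(logits, labels, n_bins) {
  n <- nrow(logits)
  V <- ncol(labels)
  stopifnot(ncol(logits) == V * n_bins)
  grad <- matrix(0, nrow = n, ncol = ncol(logits))
  total <- 0
  n_present <- sum(labels > 0L)
  if (n_present == 0L) stop("no present agents in batch")
  for (v in seq_len(V)) {
    rows <- which(labels[, v] > 0L)
    if (length(rows) == 0L) next
    cols <- (v - 1L) * n_bins + seq_len(n_bins)
    z <- logits[rows, cols, drop = FALSE]
    p <- .softmax_rows(z)
    idx <- cbind(seq_along(rows), labels[rows, v])
    total <- total - sum(log(p[idx] + 1e-12))
    g <- p
    g[idx] <- g[idx] - 1
    grad[rows, cols] <- g / n_present
  }
  list(loss = total / n_present, grad = grad)
}

.loss_dispatch <- function(loss, logits, target, n_bins = NULL) {
  switch(loss,
    bce = .loss_bce(logits, target),
    ce = .loss_ce(logits, target),
    masked_ce = masked_softmax_loss(logits, target, n_bins),
    stop("unknown loss: ", loss))
}

# ---- training ---------------------------------------------------------

# Adam on minibatches with a seeded shuffle. `target` is a matrix (bce,
# masked_ce) or integer vector (ce). Returns the trained net with a
# `history` attribute (mean epoch loss).
#' @keywords internal
mlp_train <- function(net, X, target, loss = c("bce", "ce", "masked_ce"),
                      epochs = 20L, lr = 1e-3, batch_size = 256L,
                      seed = 1L, n_bins = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  n <- nrow(X)
  stopifnot(n >= 1L)
  adam <- lapply(net$layers, function(l) list(
    mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
    mb = rep(0, length(l$b)), vb = rep(0, length(l$b))))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        tb <- if (is.matrix(target)) target[idx, , drop = FALSE] else target[idx]
        fw <- mlp_forward(net, Xb, keep_activations = TRUE)
        lg <- .loss_dispatch(loss, fw$logits, tb, n_bins)
        ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1L
        # backward
        delta <- lg$grad
        nl <- length(net$layers)
        for (l in rev(seq_len(nl))) {
          A_prev <- fw$acts[[l]]
          gW <- as.matrix(Matrix::crossprod(A_prev, delta))
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(net$layers[[l]]$W)
            delta <- delta * (fw$acts[[l]] > 0)
          }
          t_step <- t_step + 1L
          st <- adam[[l]]
          st$mW <- b1 * st$mW + (1 - b1) * gW
          st$vW <- b2 * st$vW + (1 - b2) * gW^2
          st$mb <- b1 * st$mb + (1 - b1) * gb
          st$vb <- b2 * st$vb + (1 - b2) * gb^2
          corr1 <- 1 - b1^ceiling(t_step / nl)
          corr2 <- 1 - b2^ceiling(t_step / nl)
          net$layers[[l]]$W <- net$layers[[l]]$W -
            lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
          net$layers[[l]]$b <- net$layers[[l]]$b -
            lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
          adam[[l]] <- st
        }
      }
      history[ep] <- ep_loss / n_batches
      if (verbose) message("epoch ", ep, " loss ", signif(history[ep], 5))
    }
  })
  attr(net, "history") <- history
  net
}
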