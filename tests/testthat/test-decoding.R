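test_that("beam search merges duplicate orders and ranks by probability", {
  # hand-checkable stub over V = 2: fixed conditionals regardless of state
  stub <- function(am) {
    matrix(rep(c(0.6, 0.3, 0.5), nrow(am)), ncol = 3, byrow = TRUE)
  }
  hyps <- beam_search_agents(stub, width = 10L, max_len = 2L,
                             vocab_size = 2L)
  probs <- vapply(hyps, `[[`, numeric(1), "probability")
  sets <- lapply(hyps, `[[`, "agents")
  get <- function(s) probs[vapply(sets, function(x)
    identical(x, as.integer(s)), logical(1))]
  expect_equal(get(integer(0)), 0.5)                       # stop immediately
  expect_equal(get(1L), 0.6 * 0.5)                         # pick 1, stop
  expect_equal(get(2L), 0.3 * 0.5)
  # {1,2} reachable by two orders, merged, then terminated by EOS
  expect_equal(get(c(1L, 2L)), (0.6 * 0.3 + 0.3 * 0.6) * 0.5)
  expect_identical(probs, sort(probs, decreasing = TRUE))
  expect_true(all(lengths(sets) <= 2L))
})

test_that("a narrow beam still returns at most width * depth sets, ranked", {
  set.seed(3)
  V <- 5L
  tab <- matrix(runif(2^V * (V + 1L), 0.05, 0.95), nrow = 2^V)
  stub <- function(am) {
    keys <- as.integer(am %*% 2^(seq_len(ncol(am)) - 1L)) + 1L
    tab[keys, , drop = FALSE]
  }
  hyps <- beam_search_agents(stub, width = 3L, max_len = 4L, vocab_size = V)
  probs <- vapply(hyps, `[[`, numeric(1), "probability")
  expect_identical(probs, sort(probs, decreasing = TRUE))
  keys <- vapply(hyps, function(h) paste(h$agents, collapse = ","),
                 character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("top-m joint assignments agree with brute force for m = 2", {
  set.seed(5)
  for (rep in 1:10) {
    dists <- lapply(1:3, function(i) {
      d <- runif(4); d / sum(d)
    })
    got <- top_m_joint_assignment(dists, m = 2L)
    grid <- expand.grid(1:4, 1:4, 1:4)
    joint <- apply(grid, 1, function(b)
      dists[[1]][b[1]] * dists[[2]][b[2]] * dists[[3]][b[3]])
    ord <- order(-joint)
    expect_equal(got[[1]]$probability, joint[ord[1]], tolerance = 1e-12)
    expect_equal(got[[2]]$probability, joint[ord[2]], tolerance = 1e-12)
    expect_identical(got[[1]]$bins, as.integer(grid[ord[1], ]))
  }
  empty <- top_m_joint_assignment(list(), m = 2L)
  expect_identical(length(empty), 1L)
  expect_identical(empty[[1]]$bins, integer(0))
  expect_identical(empty[[1]]$probability, 1)
})

test_that("confidence score is a weighted geometric mean", {
  cs <- c(0.9, 0.5, 0.8, 0.7)
  expect_equal(confidence_score(cs), prod(cs)^(1 / 4), tolerance = 1e-12)
  w <- c(2, 1, 1, 0.5)
  expect_equal(confidence_score(cs, w), confidence_score(cs, w * 10),
               tolerance = 1e-12)
  expect_gt(confidence_score(c(0.99, cs[-1])), confidence_score(cs))
  expect_error(confidence_score(c(0, 0.5, 0.5, 0.5)), "in \\(0, 1\\]")
  expect_error(confidence_score(cs, c(0, 0, 0, 0)), "not all be zero")
})

test_that("combine_conditions enumerates, scores and ranks candidates", {
  set.seed(2)
  mk_so <- function(agents, c1) {
    t_dist <- runif(30); t_dist <- t_dist / sum(t_dist)
    r_dists <- lapply(1:2, function(i) { d <- runif(15); d / sum(d) })
    a_dists <- lapply(agents, function(a) { d <- runif(27); d / sum(d) })
    list(agents = agents, c1 = c1, temperature_dist = t_dist,
         reactant_dists = r_dists, agent_amount_dists = a_dists)
  }
  sos <- lapply(1:10, function(i) mk_so(sort(sample.int(8L, 2L)),
                                        c1 = runif(1, 0.1, 0.9)))
  out <- combine_conditions(sos, counts = c(10L, 2L, 2L, 2L))
  expect_identical(length(out), 80L)
  scores <- vapply(out, `[[`, numeric(1), "score")
  expect_identical(scores, sort(scores, decreasing = TRUE))
  for (cs in out[1:5]) {
    expect_s3_class(cs, "condition_set")
    expect_identical(length(cs$agent_bins), length(cs$agents))
    expect_equal(cs$score, confidence_score(cs$confidences),
                 tolerance = 1e-12)
  }
})

test_that("weight fitting picks the lattice point that ranks truths first", {
  set.seed(9)
  # stage confidences where only stage-2 confidence identifies the truth:
  # the correct temperature bin has high probability, everything else is
  # noise, so upweighting w2 maximizes top-1 accuracy.
  validation <- lapply(1:12, function(i) {
    agents <- c(1L, 2L)
    t_true <- sample.int(30L, 1L)
    t_dist <- rep(0.01, 30); t_dist[t_true] <- 0.9
    t_dist <- t_dist / sum(t_dist)
    r_dists <- lapply(1:2, function(j) { d <- runif(15); d / sum(d) })
    a_dists <- lapply(1:2, function(j) { d <- runif(27); d / sum(d) })
    so <- list(list(agents = agents, c1 = 0.8, temperature_dist = t_dist,
                    reactant_dists = r_dists, agent_amount_dists = a_dists))
    truth <- condition_set(
      agents = agents, temperature_bin = t_true,
      reactant_bins = vapply(r_dists, which.max, integer(1)),
      agent_bins = vapply(a_dists, which.max, integer(1)))
    list(stage_outputs = so, truth = truth)
  })
  fit <- fit_confidence_weights(validation, counts = c(1L, 2L, 2L, 2L),
                                top_k = 1L)
  expect_length(fit$weights, 4L)
  expect_gte(fit$accuracy, 0.9)
})
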