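test_that("relaxed set equality ignores water only", {
  expect_true(relaxed_set_equal(c("CCO", "O"), "CCO"))
  expect_true(relaxed_set_equal("CCO", c("O", "CCO")))
  expect_true(relaxed_set_equal("O", character(0)))
  expect_false(relaxed_set_equal(c("CCO", "CO"), "CCO"))
  expect_false(relaxed_set_equal("CCO", "CO"))
})

test_that("top-k accuracy is the fraction with a hit in the first k", {
  preds <- list(list("a", "b"), list("b", "a"), list("c"))
  truths <- list("a", "a", "a")
  acc <- function(k) topk_accuracy(preds, truths, k, identical)
  expect_equal(acc(1), 1 / 3)
  expect_equal(acc(2), 2 / 3)
  expect_gte(acc(2), acc(1))   # nondecreasing in k
  expect_error(topk_accuracy(preds, truths, 0L, identical), ">= 1")
})

test_that("off-by-N and MAE agree with direct computation", {
  set.seed(13)
  pred <- sample.int(30L, 1000L, replace = TRUE)
  true <- sample.int(30L, 1000L, replace = TRUE)
  expect_equal(bin_mae(pred, true), mean(abs(pred - true)))
  prev <- -1
  for (N in 0:5) {
    got <- off_by_n_accuracy(pred, true, N)
    expect_equal(got, mean(abs(pred - true) <= N))
    expect_gte(got, prev)   # monotone in N
    prev <- got
  }
  expect_error(bin_mae(pred, true[1:10]), "mismatch")
})

test_that("reaction-level categories partition the outcomes", {
  expect_identical(reaction_level_category(c(3L, 5L), c(3L, 5L)), "exact")
  expect_identical(reaction_level_category(c(3L, 5L), c(3L, 6L)), "off_by_one")
  expect_identical(reaction_level_category(c(3L, 5L), c(3L, 8L)), "major")
  set.seed(14)
  for (i in 1:200) {
    k <- sample.int(3L, 1L)
    pred <- sample.int(15L, k, replace = TRUE)
    true <- sample.int(15L, k, replace = TRUE)
    cat3 <- reaction_level_category(pred, true)
    d <- abs(pred - true)
    # exactly one category fires, and it is the right one
    expect_identical(cat3, if (all(d == 0)) "exact"
                           else if (all(d <= 1)) "off_by_one" else "major")
  }
})

test_that("end-to-end verdicts decompose by stage", {
  truth <- condition_set(agents = c(2L, 5L), temperature_bin = 13L,
                         reactant_bins = c(3L, 8L),
                         agent_bins = c(10L, 20L))
  same <- condition_set(agents = c(2L, 5L), temperature_bin = 13L,
                        reactant_bins = c(8L, 3L),   # multiset equality
                        agent_bins = c(10L, 20L))
  v <- end_to_end_correct(same, truth)
  expect_true(v$stage1); expect_true(v$stage2)
  expect_true(v$stage3); expect_true(v$stage4); expect_true(v$overall)
  expect_identical(v$amount_category, "exact")

  wrong_t <- same; wrong_t$temperature_bin <- 14L
  v2 <- end_to_end_correct(wrong_t, truth)
  expect_false(v2$stage2); expect_false(v2$overall); expect_true(v2$stage1)

  wrong_agents <- condition_set(agents = c(2L, 6L), temperature_bin = 13L,
                                reactant_bins = c(3L, 8L),
                                agent_bins = c(10L, 20L))
  v3 <- end_to_end_correct(wrong_agents, truth)
  expect_false(v3$stage1); expect_false(v3$stage4)

  off_r <- same; off_r$reactant_bins <- c(3L, 9L)
  v4 <- end_to_end_correct(off_r, truth)
  expect_false(v4$stage3)
  expect_identical(v4$amount_category, "off_by_one")
})

test_that("win rate counts wins, splits ties and excludes double losses", {
  mk <- function(t_bin) condition_set(agents = 1L, temperature_bin = t_bin,
                                      reactant_bins = 3L, agent_bins = 10L)
  truth <- replicate(6, mk(5L), simplify = FALSE)
  right <- list(mk(5L)); wrong <- list(mk(6L))
  # A right on 1-3, B right on 3-4; 5-6 both wrong (excluded)
  preds_A <- list(right, right, right, wrong, wrong, wrong)
  preds_B <- list(wrong, wrong, right, right, wrong, wrong)
  wr <- win_rate(preds_A, preds_B, truth, top_k = 1L)
  expect_identical(wr$n, 4L)
  expect_equal(wr$wins_a, 2 + 0.5)
  expect_equal(wr$win_rate, 2.5 / 4)
  expect_true(wr$lower <= wr$win_rate && wr$win_rate <= wr$upper)
  wr2 <- win_rate(preds_A, preds_B, truth, top_k = 1L, ties = "exclude")
  expect_identical(wr2$n, 3L)
  expect_equal(wr2$wins_a, 2)
  # grouping splits rows
  wrg <- win_rate(preds_A, preds_B, truth, top_k = 1L,
                  grouping = c("x", "x", "y", "y", "y", "y"))
  expect_setequal(wrg$group, c("x", "y"))
  expect_identical(wrg$n[wrg$group == "x"], 2L)
})

test_that("the Wilson interval matches known reference values", {
  # prop.test without continuity correction computes the Wilson interval
  for (x in c(1, 5, 8)) {
    ci <- condrec:::.wilson_interval(x, 10, 0.95)
    ref <- stats::prop.test(x, 10, correct = FALSE)$conf.int
    expect_equal(unname(ci["lower"]), ref[1], tolerance = 1e-9)
    expect_equal(unname(ci["upper"]), ref[2], tolerance = 1e-9)
  }
  ci0 <- condrec:::.wilson_interval(0, 10, 0.95)
  expect_equal(unname(ci0["lower"]), 0)
  expect_gt(unname(ci0["upper"]), 0)
})
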