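test_that("partition augmentation enumerates subset/remainder pairs", {
  eos <- 7L
  p0 <- enumerate_partitions(integer(0), eos)
  expect_identical(length(p0), 1L)
  expect_identical(p0[[1]]$target, eos)

  p1 <- enumerate_partitions(4L, eos)
  expect_identical(length(p1), 2L)

  A <- c(2L, 5L, 3L)
  p3 <- enumerate_partitions(A, eos)
  expect_identical(length(p3), 8L)
  for (p in p3) {
    expect_true(all(p$input %in% A))
    if (identical(sort(p$input), sort(A))) {
      expect_identical(p$target, eos)
    } else {
      expect_setequal(p$target, setdiff(A, p$input))
    }
  }
  expect_null(enumerate_partitions(1:7, eos = 30L, cap = 6L))
})

test_that("class one-hot degrades gracefully on unseen classes", {
  classes <- c("1.1.1", "2.2.2")
  expect_identical(class_onehot("2.2.2", classes), c(0, 1))
  expect_identical(class_onehot("9.9.9", classes), c(0, 0))
  expect_identical(class_onehot(NA_character_, classes), c(0, 0))
})

test_that("trained stage models emit well-formed distributions", {
  models <- fx_models()
  vocab <- fx_world_vocab()
  rec <- fx_records()[[1]]
  fp <- reaction_fingerprint(rec)
  am <- encode_agent_set(.side_smiles(rec$agents), vocab)

  p1 <- stage_predict(models$stage1,
                      list(reaction_fp = fp,
                           class_onehot = class_onehot(rec$class_id,
                                                       models$stage1$classes),
                           agent_multihot = numeric(length(vocab))))
  expect_length(p1, length(vocab) + 1L)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # batch scoring of several partial sets at once
  amm <- rbind(numeric(length(vocab)), am)
  p1b <- stage_predict(models$stage1,
                       list(reaction_fp = fp,
                            class_onehot = class_onehot(rec$class_id,
                                                        models$stage1$classes),
                            agent_multihot = amm))
  expect_identical(dim(p1b), c(2L, length(vocab) + 1L))
  expect_equal(p1b[1, ], p1, tolerance = 1e-12)

  p2 <- stage_predict(models$stage2, list(reaction_fp = fp,
                                          agent_multihot = am))
  expect_length(p2, 30L)
  expect_equal(sum(p2), 1, tolerance = 1e-9)

  rfp <- molecule_fingerprint(rec$reactants[[1]]$smiles)
  p3 <- stage_predict(models$stage3, list(reaction_fp = fp,
                                          agent_multihot = am,
                                          reactant_fp = rfp))
  expect_length(p3, 15L)
  expect_equal(sum(p3), 1, tolerance = 1e-9)

  p4 <- stage_predict(models$stage4, list(reaction_fp = fp,
                                          agent_multihot = am))
  expect_identical(length(p4), sum(am))
  expect_setequal(names(p4), decode_agent_set(am, vocab))
  for (d in p4) {
    expect_length(d, 27L)
    expect_equal(sum(d), 1, tolerance = 1e-9)
  }
})

test_that("stage models save, load and check compatibility", {
  models <- fx_models()
  path <- withr::local_tempfile(fileext = ".rds")
  save_stage_model(models$stage2, path)
  back <- load_stage_model(path)
  expect_equal(back$net$layers, models$stage2$net$layers)
  expect_silent(check_model_compatible(back, vocab = fx_world_vocab(),
                                       scheme = temperature_bins()))
  expect_error(check_model_compatible(back, vocab = fx_vocab()),
               "different agent vocabulary")
  expect_error(check_model_compatible(back, scheme = reactant_amount_bins()),
               "different bin scheme")
})

test_that("training is reproducible for a fixed config", {
  recs <- stage_filter(fx_records()[1:40], fx_world_vocab(), 2L)
  tc <- train_config(hidden = 16L, epochs = 2L, seed = 9L)
  a <- train_stage2(recs, fx_world_vocab(), tc)
  b <- train_stage2(recs, fx_world_vocab(), tc)
  expect_equal(a$net$layers, b$net$layers)
})
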