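# A tiny hand-built corpus with known frequencies for baseline tests.
bl_vocab <- function() fx_vocab()

bl_record <- function(doc, agents_moles, temp, class_id = "1.1.1",
                      reactants = list(list(smiles = "CCO", moles = 0.01),
                                       list(smiles = "CC(=O)O", moles = 0.02))) {
  fx_record(doc = doc, reactants = reactants,
            agents = lapply(names(agents_moles), function(s)
              list(smiles = s, moles = agents_moles[[s]])),
            temperature_c = temp, class_id = class_id)
}

bl_corpus <- function() {
  list(
    bl_record("d1", list(`C1CCOC1` = 0.1), 25),
    bl_record("d2", list(`C1CCOC1` = 0.1), 25),
    bl_record("d3", list(`C1CCOC1` = 0.1), 25),
    bl_record("d4", list(CO = 0.15, O = 0.2), 60),
    bl_record("d5", list(CO = 0.15, O = 0.2), 60),
    bl_record("d6", list(`CN(C)C=O` = 0.12), -20, class_id = "2.2.2",
              reactants = list(list(smiles = "CO", moles = 0.005),
                               list(smiles = "CCO", moles = 0.0055))))
}

test_that("record_condition_set bins the recorded conditions", {
  vocab <- bl_vocab()
  schemes <- default_bin_schemes()
  cs <- record_condition_set(bl_corpus()[[4]], vocab, schemes)
  expect_identical(cs$agents, sort(vocab_index(vocab, c("CO", "O"))))
  expect_identical(cs$temperature_bin, assign_bin(60, schemes$temperature))
  expect_identical(sort(cs$reactant_bins),
                   sort(assign_bin(c(1, 2), schemes$reactant_amount)))
  # agent bins are named by and aligned to the sorted agent indices
  expect_identical(names(cs$agent_bins), vocab$agents[cs$agents])
  eq_by_smiles <- c(CO = 15, O = 20)
  expect_identical(unname(cs$agent_bins),
                   assign_bin(unname(eq_by_smiles[names(cs$agent_bins)]),
                              schemes$agent_amount))
})

test_that("popularity ranks by in-class frequency", {
  vocab <- bl_vocab()
  idx <- class_index(bl_corpus(), vocab)
  sets <- popularity_predict(idx, "1.1.1", "agents")
  expect_identical(sets[[1]], vocab_index(vocab, "C1CCOC1"))       # 3 of 5
  expect_identical(sets[[2]], sort(vocab_index(vocab, c("CO", "O"))))
  temps <- popularity_predict(idx, "1.1.1", "temperature")
  expect_identical(temps[1], assign_bin(25, temperature_bins()))
  # reactant-amount popularity is the constant 1.0-equivalent bin
  expect_identical(popularity_predict(idx, "1.1.1", "reactant_amount"),
                   assign_bin(1.0, reactant_amount_bins()))
  hol <- popularity_predict(idx, "1.1.1", "holistic")
  expect_identical(hol[[1]]$agents, vocab_index(vocab, "C1CCOC1"))
  ab <- popularity_predict(idx, "1.1.1", "agent_amount")
  thf <- canonicalize_smiles("C1CCOC1")
  expect_identical(unname(ab[[thf]]), assign_bin(10, agent_amount_bins()))
})

test_that("unseen classes return the marker, not an error", {
  idx <- class_index(bl_corpus(), bl_vocab())
  for (task in c("agents", "temperature", "agent_amount", "holistic")) {
    p <- popularity_predict(idx, "9.9.9", task)
    expect_true(is_unseen_class(p))
  }
  q <- bl_corpus()[[1]]
  q$class_id <- "9.9.9"
  expect_true(is_unseen_class(nn_predict(idx, q)))
})

test_that("nearest neighbor retrieves the most similar record's conditions", {
  vocab <- bl_vocab()
  corpus <- bl_corpus()
  idx <- class_index(corpus, vocab)
  # the query reaction is identical to every class-1.1.1 record, so all
  # similarities are 1 and ties break to the most frequent condition set
  q <- bl_record("q", list(CO = 1), 999)   # conditions ignored for retrieval
  hol <- nn_predict(idx, q, k = 3L)
  truth1 <- record_condition_set(corpus[[1]], vocab)
  expect_identical(hol[[1]]$agents, truth1$agents)
  expect_identical(hol[[1]]$temperature_bin, truth1$temperature_bin)
  sims <- attr(hol, "similarity")
  expect_identical(sims, sort(sims, decreasing = TRUE))
  expect_equal(sims[1], 1)   # exact same reaction present in the index
  # distinct condition keys only
  ag <- nn_predict(idx, q, k = 5L, task = "agents")
  keys <- vapply(ag, paste, character(1), collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("the fixture-world NN baseline is internally consistent", {
  recs <- fx_records()
  vocab <- fx_world_vocab()
  idx <- class_index(recs[1:200], vocab)
  hits <- vapply(201:240, function(i) {
    p <- nn_predict(idx, recs[[i]], k = 1L)
    truth <- record_condition_set(recs[[i]], vocab)
    end_to_end_correct(p[[1]], truth)$overall
  }, logical(1))
  # noiseless world: retrieval from the same family reproduces conditions
  expect_gte(mean(hits), 0.9)
})
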