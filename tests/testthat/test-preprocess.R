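test_that("to_moles converts the four supported units and refuses others", {
  expect_identical(to_moles(2, "mol"), 2)
  expect_identical(to_moles(500, "mmol"), 0.5)
  expect_identical(to_moles(18, "g", molecular_weight = 18), 1)
  expect_identical(to_moles(250, "mL", molarity = 2), 0.5)
  expect_error(to_moles(1, "g"), "molecular_weight")
  expect_error(to_moles(1, "mL"), "molarity")
  expect_error(to_moles(1, "kg"), "unsupported")
  expect_error(to_moles(-1, "mol"), "positive")
})

test_that("limiting reactant is the smallest amount, ties to lowest index", {
  rec <- fx_record(reactants = list(list(smiles = "CCO", moles = 0.02),
                                    list(smiles = "CC(=O)O", moles = 0.01)))
  expect_identical(limiting_reactant(rec), 2L)
  tie <- fx_record(reactants = list(list(smiles = "CCO", moles = 0.01),
                                    list(smiles = "CC(=O)O", moles = 0.01)))
  expect_identical(limiting_reactant(tie), 1L)
  na <- fx_record(reactants = list(list(smiles = "CCO"),
                                   list(smiles = "CC(=O)O", moles = 0.01)))
  expect_error(limiting_reactant(na), "lack moles")
})

test_that("equivalence ratios are relative to the limiting reactant", {
  rec <- fx_record(reactants = list(list(smiles = "CCO", moles = 0.01),
                                    list(smiles = "CC(=O)O", moles = 0.025)),
                   agents = list(list(smiles = "C1CCOC1", moles = 0.2)))
  eq <- equivalence_ratios(rec)
  expect_identical(eq$limiting, 1L)
  expect_equal(eq$reactants, c(1.0, 2.5))
  expect_equal(eq$agents, 20)
})

test_that("deduplication keys on conditions, not the document", {
  a <- fx_record(doc = "docA")
  b <- fx_record(doc = "docB")                 # same conditions, other doc
  c <- fx_record(doc = "docC", temperature_c = 60)  # other temperature bin
  d <- fx_record(doc = "docD", temperature_c = 26)  # same bin as a
  out <- deduplicate_records(list(a, b, c, d))
  expect_identical(out$n_removed, 2L)
  expect_identical(vapply(out$records, `[[`, character(1), "document_id"),
                   c("docA", "docC"))
})

test_that("quality filters reject and count by reason", {
  big <- paste(rep("C", 120), collapse = "")
  recs <- list(
    fx_record(),
    fx_record(reactants = list(list(smiles = big, moles = 0.01),
                               list(smiles = "CCO", moles = 0.02))),
    fx_record(reactants = lapply(1:6, function(i)
      list(smiles = paste(rep("C", i), collapse = ""), moles = 0.01))),
    reaction_record("d", list(list(smiles = "C((", moles = 0.01)),
                    products = list("CCO"), canonicalize = FALSE))
  out <- filter_records(recs)
  expect_identical(length(out$records), 1L)
  expect_identical(out$rejections[["molecular_size"]], 1L)
  expect_identical(out$rejections[["component_count"]], 1L)
  expect_identical(out$rejections[["parsability"]], 1L)
})

test_that("vocabulary building counts, thresholds and orders agents", {
  mk <- function(agent, n, moles = 0.1) {
    lapply(seq_len(n), function(i)
      fx_record(doc = paste0("d", agent, i),
                agents = list(list(smiles = agent, moles = moles))))
  }
  recs <- c(mk("CCO", 3), mk("CO", 3), mk("C1CCOC1", 2),
            # agent without recorded quantity: never counted
            list(fx_record(doc = "dx", agents = list(list(smiles = "O")))))
  vocab <- build_vocabulary(recs, min_count = 3L)
  # count ties break lexicographically; below-threshold agents are dropped
  expect_identical(vocab$agents, canonicalize_smiles(c("CCO", "CO")))
  expect_error(build_vocabulary(recs, min_count = 100L), "empty vocabulary")
})

test_that("document split is document-level, exhaustive and seeded", {
  recs <- fx_records()
  spl <- document_split(recs, seed = 7L)
  expect_identical(length(spl$split), length(recs))
  expect_setequal(unique(spl$split), c("train", "val", "test"))
  # no document straddles two splits
  docs <- vapply(recs, `[[`, character(1), "document_id")
  expect_true(all(vapply(split(spl$split, docs), function(s)
    length(unique(s)) == 1L, logical(1))))
  expect_identical(spl, document_split(recs, seed = 7L))
  expect_false(identical(spl$assignment, document_split(recs, seed = 8L)$assignment))
})

test_that("stage filters demand exactly the labels each stage needs", {
  vocab <- fx_vocab()
  full <- fx_record()
  no_temp <- fx_record(temperature_c = NA_real_)
  no_agents <- fx_record(agents = list())
  oov <- fx_record(agents = list(list(smiles = "c1ccccc1", moles = 0.1)))
  no_amounts <- fx_record(agents = list(list(smiles = "C1CCOC1")))
  recs <- list(full, no_temp, no_agents, oov, no_amounts)
  expect_identical(length(stage_filter(recs, vocab, 1L)), 3L)
  expect_identical(length(stage_filter(recs, vocab, 2L)), 2L)
  expect_identical(length(stage_filter(recs, vocab, 3L)), 3L)
  expect_identical(length(stage_filter(recs, vocab, 4L)), 2L)
})
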