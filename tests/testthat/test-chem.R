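test_that("canonicalization is idempotent and spelling-invariant", {
  can <- canonicalize_smiles("OCC")
  expect_identical(canonicalize_smiles(can), can)
  expect_identical(can, canonicalize_smiles("CCO"))
  expect_identical(canonicalize_smiles("C(C)O"), can)
})

test_that("canonicalization errors loudly on malformed input", {
  expect_error(canonicalize_smiles("C(("), "cannot parse")
  expect_error(canonicalize_smiles(""), "cannot parse")
  expect_error(canonicalize_smiles("not a smiles!"), "cannot parse")
  expect_error(canonicalize_smiles("C)("), "cannot parse")
  expect_error(canonicalize_smiles(c("CCO", "C((")), "cannot parse")
})

test_that("multi-fragment and charged SMILES parse", {
  expect_no_error(canonicalize_smiles(c("[Li+].[Cl-]", "O=[Mn]=O",
                                        "CC(=O)O[Pd]OC(C)=O", "[Zn]")))
})

test_that("heavy atom counts ignore hydrogens and count halogens once", {
  expect_identical(heavy_atom_count("CCO"), 3L)
  expect_identical(heavy_atom_count("ClC(Cl)Cl"), 4L)
  expect_identical(heavy_atom_count("Br"), 1L)
  expect_identical(heavy_atom_count("c1ccccc1"), 6L)
  expect_identical(heavy_atom_count("[Na+]"), 1L)
  expect_identical(heavy_atom_count("[2H]O[2H]"), 1L)
})

test_that("molecule fingerprints are binary, fixed-length and canonical", {
  fp <- molecule_fingerprint("CCO")
  expect_length(fp, 2048L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_gt(sum(fp), 0)
  expect_identical(fp, molecule_fingerprint("OCC"))
  expect_identical(molecule_fingerprint("CCO", n_bits = 1024L) |> length(),
                   1024L)
})

test_that("reaction fingerprints concatenate OR-ed sides, order-invariantly", {
  fp <- reaction_fingerprint(c("CCO", "CC(=O)O"), "CCOC(C)=O")
  expect_length(fp, 4096L)
  expect_identical(fp, reaction_fingerprint(c("CC(=O)O", "CCO"), "CCOC(C)=O"))
  # the reactant block is the OR of the individual fingerprints
  a <- molecule_fingerprint("CCO"); b <- molecule_fingerprint("CC(=O)O")
  expect_identical(fp[1:2048], as.integer(a | b))
})

test_that("tanimoto similarity has the expected extremes and bounds", {
  a <- molecule_fingerprint("CCO")
  b <- molecule_fingerprint("c1ccccc1")
  expect_identical(tanimoto(a, a), 1)
  expect_identical(tanimoto(numeric(8), numeric(8)), 0)
  expect_identical(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  s <- tanimoto(a, b)
  expect_gte(s, 0); expect_lte(s, 1)
  expect_identical(s, tanimoto(b, a))
  expect_error(tanimoto(a, b[1:10]), "mismatch")
})

test_that("agent vocabulary indexes, encodes and decodes round-trip", {
  vocab <- fx_vocab()
  expect_identical(length(vocab), 6L)
  expect_identical(vocab$eos_index, 7L)
  expect_error(agent_vocabulary(c("CCO", "OCC")), "duplicate")

  idx <- vocab_index(vocab, c("CCO", "O"))
  expect_identical(vocab$agents[idx], canonicalize_smiles(c("CCO", "O")))
  expect_error(vocab_index(vocab, "c1ccccc1"), "not in vocabulary")
  expect_identical(vocab_index(vocab, "c1ccccc1", strict = FALSE),
                   NA_integer_)

  mh <- encode_agent_set(c("CCO", "O"), vocab)
  expect_identical(sum(mh), 2L)
  expect_setequal(decode_agent_set(mh, vocab),
                  canonicalize_smiles(c("CCO", "O")))
  expect_identical(decode_agent_set(encode_agent_set(character(0), vocab),
                                    vocab), character(0))
})
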