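test_that("world generation is deterministic and structurally sound", {
  world <- fx_world()
  cfg <- world$cfg
  expect_identical(length(world$rules), cfg$n_classes)
  expect_identical(length(world$vocab), cfg$vocab_size)
  for (cl in world$rules) {
    sets <- lapply(cl$families, function(f) sort(f$agents))
    expect_identical(length(cl$families), cfg$families_per_class)
    # families of one class always differ in their agent sets
    expect_identical(anyDuplicated(vapply(sets, paste, character(1),
                                          collapse = "|")), 0L)
    for (f in cl$families) {
      expect_gte(length(f$agents), 2L)
      expect_lte(length(f$agents), 4L)
      expect_true(all(f$agents %in% world$vocab$agents))
      expect_true(f$temperature_mean %in% c(-78, 0, 25, 85, 115))
      expect_true(f$coreactant_eq_target %in% c(1.1, 1.5, 2.0, 2.5))
    }
  }
  # same config, same world
  again <- generate_world(world$cfg)
  expect_equal(again$vocab$agents, world$vocab$agents)
  expect_equal(again$rules, world$rules)
})

test_that("families of one class use different scaffold cores", {
  world <- fx_world()
  sc <- world$scaffolds
  for (cl in unique(sc$class)) {
    fams <- split(sc$reactant[sc$class == cl], sc$family[sc$class == cl])
    expect_identical(length(intersect(fams[[1]], fams[[2]])), 0L)
  }
})

test_that("sampling is seeded and documents are contiguous blocks", {
  world <- fx_world()
  a <- sample_records(world, 23L, seed = 9L)
  b <- sample_records(world, 23L, seed = 9L)
  expect_equal(a, b)
  expect_false(identical(sample_records(world, 23L, seed = 10L), a))
  docs <- vapply(a, `[[`, character(1), "document_id")
  expect_identical(length(unique(docs)),
                   as.integer(ceiling(23 / world$cfg$records_per_document)))
  expect_true(all(rle(docs)$lengths[seq_len(4)] ==
                    world$cfg$records_per_document))
})

test_that("noiseless records reproduce their rule's binned conditions", {
  world <- fx_world()   # all noise rates zero
  recs <- fx_records()
  schemes <- default_bin_schemes()
  vocab <- world$vocab
  for (rec in recs[seq_len(60)]) {
    truth <- world_ground_truth(world, rec, schemes)
    got <- record_condition_set(rec, vocab, schemes)
    expect_identical(got$agents, truth$agents)
    expect_identical(got$temperature_bin, truth$temperature_bin)
    expect_identical(sort(got$reactant_bins), sort(truth$reactant_bins))
    expect_identical(got$agent_bins, truth$agent_bins)
  }
})

test_that("with noise enabled, conditions deviate at roughly the set rates", {
  cfg <- world_config(n_classes = 2L, agent_swap_prob = 0.3,
                      temperature_jitter_sd = 12, amount_jitter_frac = 0,
                      seed = 42L)
  world <- generate_world(cfg)
  recs <- sample_records(world, 400L, seed = 3L)
  schemes <- default_bin_schemes()
  swapped <- vapply(recs, function(rec) {
    truth <- world_ground_truth(world, rec, schemes)
    got <- sort(unique(vocab_index(world$vocab, .side_smiles(rec$agents),
                                   strict = FALSE)))
    !identical(got, truth$agents)
  }, logical(1))
  expect_gt(mean(swapped), 0.15); expect_lt(mean(swapped), 0.45)
  temp_dev <- vapply(recs, function(rec) {
    truth <- world_ground_truth(world, rec, schemes)
    abs(assign_bin(rec$temperature_c, schemes$temperature) -
          truth$temperature_bin)
  }, numeric(1))
  expect_gt(mean(temp_dev > 0), 0.2)
})

test_that("equivalence-ratio mass concentrates at 1.0 and the co-targets", {
  world <- fx_world()
  recs <- sample_records(world, 1000L, seed = 21L)
  schemes <- default_bin_schemes()
  eq <- unlist(lapply(recs, function(r) equivalence_ratios(r)$reactants))
  bins <- assign_bin(eq, schemes$reactant_amount)
  allowed <- assign_bin(c(1.0, 1.1, 1.5, 2.0, 2.5), schemes$reactant_amount)
  expect_gte(mean(bins %in% allowed), 0.999)
  # the limiting reactant's bin holds half of all reactant slots
  expect_equal(mean(bins == assign_bin(1.0, schemes$reactant_amount)), 0.5,
               tolerance = 0.01)
})

test_that("foreign records are rejected by the ground-truth oracle", {
  world <- fx_world()
  alien <- fx_record()
  expect_error(world_ground_truth(world, alien), "foreign")
})
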