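# End-to-end inference and the orchestrated workflow:
# simulate -> preprocess -> train (x4) -> recommend -> evaluate.

#' End-to-end condition prediction for one query reaction
#'
#' Stage 1 decodes candidate agent sets by beam search; each candidate's
#' agent multi-hot is then fed (with the reaction encoding) to stages 2-4,
#' which run independently of each other; finally the per-stage top
#' predictions are combined and ranked by [combine_conditions()]. Note the
#' asymmetry with training: stages 2-4 are trained with ground-truth
#' agents (teacher forcing) but consume predicted agents here.
#'
#' @param models list with elements `stage1`..`stage4` (trained
#'   [train_stage1()].. [train_stage4()] models sharing one vocabulary).
#' @param record the query [reaction_record()] (conditions not required).
#' @param counts candidate counts per stage, default `c(10, 2, 2, 2)`.
#' @param weights confidence weights for ranking.
#' @param beam_width stage-1 beam width.
#' @param max_len maximum agent-set size.
#' @param return_stage_outputs also return the per-agent-set stage outputs
#'   (used for confidence-weight fitting).
#' @return ranked list of [condition_set()]s (at most
#'   `prod(counts)` = 80 by default); with `return_stage_outputs = TRUE`, a
#'   list `list(conditions =, stage_outputs =)`.
#' @export
predict_conditions <- function(models, record, counts = c(10L, 2L, 2L, 2L),
                               weights = c(1, 1, 1, 1), beam_width = 10L,
                               max_len = 6L,
                               return_stage_outputs = FALSE) {
  m1 <- models$stage1
  stopifnot(inherits(m1, "stage_model"))
  for (s in c("stage2", "stage3", "stage4")) {
    check_model_compatible(models[[s]], vocab = m1$vocab)
  }
  vocab <- m1$vocab
  fp <- reaction_fingerprint(record, radius = m1$radius, n_bits = m1$n_bits)
  co <- class_onehot(record$class_id, m1$classes)
  hyps <- beam_search_agents(m1, reaction_fp = fp, class_onehot = co,
                             width = max(beam_width, counts[1]),
                             max_len = max_len)
  hyps <- utils::head(hyps, counts[1])
  r_smiles <- .side_smiles(record$reactants)
  rfp <- .fingerprint_matrix(r_smiles, radius = m1$radius, n_bits = m1$n_bits)
  stage_outputs <- lapply(hyps, function(h) {
    am <- numeric(length(vocab)); am[h$agents] <- 1
    t_dist <- stage_predict(models$stage2,
                            list(reaction_fp = fp, agent_multihot = am))
    r_dists <- lapply(seq_along(r_smiles), function(j) {
      stage_predict(models$stage3,
                    list(reaction_fp = fp, agent_multihot = am,
                         reactant_fp = rfp[j, ]))
    })
    a_dists <- if (length(h$agents) == 0L) list() else
      stage_predict(models$stage4,
                    list(reaction_fp = fp, agent_multihot = am))
    list(agents = h$agents, c1 = h$probability,
         temperature_dist = t_dist, reactant_dists = r_dists,
         agent_amount_dists = a_dists)
  })
  conditions <- combine_conditions(stage_outputs, counts = counts,
                                   weights = weights)
  if (return_stage_outputs) {
    list(conditions = conditions, stage_outputs = stage_outputs)
  } else {
    conditions
  }
}

#' Run configuration for the full workflow
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; every random step derives its own stream from
#'   it.
#' @param world a [world_config()] (its own seed is overridden by `seed`).
#' @param n_train,n_val,n_test record counts sampled for each split role.
#' @param train a [train_config()] shared by the four stages.
#' @param min_vocab_count vocabulary frequency threshold.
#' @param counts,beam_width,max_len inference settings.
#' @param fit_weights fit confidence weights on the validation sample
#'   (otherwise equal weights).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, world = world_config(),
                       n_train = 2000L, n_val = 200L, n_test = 500L,
                       train = train_config(hidden = 256L, epochs = 8L),
                       min_vocab_count = 1L,
                       counts = c(10L, 2L, 2L, 2L), beam_width = 10L,
                       max_len = 6L, fit_weights = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), world = world,
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), train = train,
                 min_vocab_count = as.integer(min_vocab_count),
                 counts = as.integer(counts),
                 beam_width = as.integer(beam_width),
                 max_len = as.integer(max_len),
                 fit_weights = isTRUE(fit_weights)),
            class = "run_config")
}

.config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg[setdiff(names(cfg), "out_dir")]),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", derive_seed(0L, as.character(js)))
}

#' Run the full synthetic-world workflow
#'
#' Simulates a corpus, preprocesses it (filters, condition-level dedup,
#' vocabulary, document split), trains the four stages on the training
#' documents, predicts end-to-end conditions for the test documents,
#' evaluates against the popularity and nearest-neighbor baselines, and
#' writes all artifacts (records, vocabulary, models, predictions,
#' evaluation report) under `cfg$out_dir`. Every artifact is stamped with
#' the config hash and master seed; a rerun with the same config
#' reproduces the identical report.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return the evaluation report (invisibly also written to
#'   `report.json`).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[condrec] ", ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = .config_hash(cfg), seed = cfg$seed)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------
  say("simulating world")
  world <- step("simulate", {
    wc <- cfg$world; wc$seed <- derive_seed(cfg$seed, "world")
    generate_world(wc)
  })
  n_total <- cfg$n_train + cfg$n_val + cfg$n_test
  records <- step("simulate", sample_records(
    world, n_total, seed = derive_seed(cfg$seed, "records")))
  write_reactions_jsonl(records, file.path(cfg$out_dir, "synth.jsonl"))

  # -- preprocess -------------------------------------------------------
  say("preprocessing ", length(records), " records")
  schemes <- default_bin_schemes()
  flt <- step("preprocess", filter_records(records))
  ded <- step("preprocess", deduplicate_records(flt$records, schemes))
  kept <- ded$records
  vocab <- step("preprocess", build_vocabulary(kept, cfg$min_vocab_count))
  writeLines(vocab$agents, file.path(cfg$out_dir, "vocab.txt"))
  spl <- step("preprocess", document_split(
    kept, seed = derive_seed(cfg$seed, "split")))
  train_recs <- kept[spl$split == "train"]
  # condition sets with out-of-vocabulary agents are not expressible by
  # any method sharing the vocabulary; evaluation is on covered records
  covered <- vapply(kept, vocab_covers, logical(1), vocab = vocab)
  val_recs <- kept[spl$split == "val" & covered]
  test_recs <- kept[spl$split == "test" & covered]
  write_reactions_jsonl(kept, file.path(cfg$out_dir, "processed.jsonl"))
  say("split: ", length(train_recs), " train / ", length(val_recs),
      " val / ", length(test_recs), " test (",
      ded$n_removed, " duplicates removed, ",
      sum(flt$rejections), " filtered)")

  # -- train ------------------------------------------------------------
  models <- list()
  for (s in 1:4) {
    say("training stage ", s, " (", length(stage_filter(train_recs, vocab, s)),
        " records)")
    tc <- cfg$train; tc$seed <- derive_seed(cfg$seed, paste0("stage", s))
    recs_s <- stage_filter(train_recs, vocab, s)
    models[[paste0("stage", s)]] <- step(paste0("train-stage", s),
      switch(s,
        train_stage1(recs_s, vocab, tc),
        train_stage2(recs_s, vocab, tc),
        train_stage3(recs_s, vocab, tc),
        train_stage4(recs_s, vocab, tc)))
    save_stage_model(models[[paste0("stage", s)]],
                     file.path(cfg$out_dir, sprintf("stage%d.rds", s)))
  }

  # -- confidence weights ----------------------------------------------
  weights <- c(1, 1, 1, 1)
  if (cfg$fit_weights && length(val_recs) > 0L) {
    say("fitting confidence weights on ", length(val_recs), " validation records")
    validation <- lapply(val_recs, function(rec) {
      so <- predict_conditions(models, rec, counts = cfg$counts,
                               beam_width = cfg$beam_width,
                               max_len = cfg$max_len,
                               return_stage_outputs = TRUE)$stage_outputs
      list(stage_outputs = so,
           truth = record_condition_set(rec, vocab, schemes))
    })
    lattice <- c(0.5, 1, 2)
    grid <- as.matrix(expand.grid(lattice, lattice, lattice, lattice))
    weights <- step("fit-weights",
                    fit_confidence_weights(validation, grid,
                                           counts = cfg$counts))$weights
  }

  # -- recommend --------------------------------------------------------
  say("predicting conditions for ", length(test_recs), " test records")
  preds <- step("recommend", lapply(test_recs, function(rec) {
    predict_conditions(models, rec, counts = cfg$counts, weights = weights,
                       beam_width = cfg$beam_width, max_len = cfg$max_len)
  }))
  pred_lines <- vapply(seq_along(test_recs), function(i) {
    top <- utils::head(preds[[i]], 3L)
    jsonlite::toJSON(list(
      rxn_smiles = reaction_smiles(test_recs[[i]]),
      predictions = lapply(top, describe_prediction, vocab = vocab,
                           schemes = schemes)),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(pred_lines, file.path(cfg$out_dir, "preds.jsonl"))

  # -- evaluate ---------------------------------------------------------
  say("evaluating against baselines")
  index <- step("evaluate", class_index(train_recs, vocab, schemes))
  report <- step("evaluate", evaluate_methods(
    models, index, preds, test_recs, vocab, schemes,
    counts = cfg$counts, weights = weights))
  report$stamp <- stamp
  report$sizes <- list(train = length(train_recs), val = length(val_recs),
                       test = length(test_recs))
  report$weights <- weights
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Stage-wise and end-to-end evaluation of model vs baselines
#'
#' Computes the standard report: stage-wise metrics with teacher-forced
#' inputs (stage 1 relaxed top-1/top-5 accuracy; stage 2 bin MAE and
#' off-by-1; stage 3 reaction-level categories; stage 4 per-agent bin
#' accuracy), end-to-end top-1/top-10 exact-match accuracy for the model
#' and the two holistic baselines, and the pairwise win rate of the model
#' against the nearest-neighbor baseline.
#'
#' @param models the four stage models.
#' @param index a [class_index()] built on the training records.
#' @param preds precomputed ranked [condition_set()]s per test record (as
#'   from [predict_conditions()]).
#' @param test_recs test [reaction_record()]s with full condition labels.
#' @param vocab,schemes shared vocabulary and bin schemes.
#' @param counts,weights inference settings (used for reporting only).
#' @return a nested list report.
#' @export
evaluate_methods <- function(models, index, preds, test_recs, vocab,
                             schemes, counts = c(10L, 2L, 2L, 2L),
                             weights = c(1, 1, 1, 1)) {
  truths <- lapply(test_recs, record_condition_set, vocab = vocab,
                   schemes = schemes)
  truth_smiles <- lapply(truths, function(cs) vocab$agents[cs$agents])

  # stage 1: relaxed top-k (model sets from the ranked predictions'
  # distinct leading agent sets; baselines per task)
  model_sets <- lapply(preds, function(pl) {
    seen <- character(0); out <- list()
    for (cs in pl) {
      kk <- paste(cs$agents, collapse = ",")
      if (kk %in% seen) next
      seen <- c(seen, kk)
      out[[length(out) + 1L]] <- vocab$agents[cs$agents]
    }
    out
  })
  pop_sets <- lapply(test_recs, function(rec) {
    p <- popularity_predict(index, rec$class_id, "agents")
    if (is_unseen_class(p)) list() else
      lapply(p, function(idx) vocab$agents[idx])
  })
  nn_sets <- lapply(test_recs, function(rec) {
    p <- nn_predict(index, rec, k = 10L, task = "agents")
    if (is_unseen_class(p)) list() else
      lapply(p, function(idx) vocab$agents[idx])
  })
  stage1 <- list(
    model = list(top1 = topk_accuracy(model_sets, truth_smiles, 1L,
                                      relaxed_set_equal),
                 top5 = topk_accuracy(model_sets, truth_smiles, 5L,
                                      relaxed_set_equal)),
    popularity = list(top1 = topk_accuracy(pop_sets, truth_smiles, 1L,
                                           relaxed_set_equal),
                      top5 = topk_accuracy(pop_sets, truth_smiles, 5L,
                                           relaxed_set_equal)),
    nearest_neighbor = list(top1 = topk_accuracy(nn_sets, truth_smiles, 1L,
                                                 relaxed_set_equal),
                            top5 = topk_accuracy(nn_sets, truth_smiles, 5L,
                                                 relaxed_set_equal)))

  # stage 2: teacher-forced temperature bins
  with_temp <- which(vapply(truths, function(cs)
    !is.na(cs$temperature_bin), logical(1)))
  t_true <- vapply(truths[with_temp], `[[`, integer(1), "temperature_bin")
  t_model <- vapply(with_temp, function(i) {
    am <- encode_agent_set(truth_smiles[[i]], vocab)
    fp <- reaction_fingerprint(test_recs[[i]], radius = models$stage2$radius,
                               n_bits = models$stage2$n_bits)
    which.max(stage_predict(models$stage2,
                            list(reaction_fp = fp, agent_multihot = am)))
  }, integer(1))
  t_pop <- vapply(with_temp, function(i) {
    p <- popularity_predict(index, test_recs[[i]]$class_id, "temperature")
    if (is_unseen_class(p) || length(p) == 0L) NA_integer_ else p[1L]
  }, integer(1))
  t_nn <- vapply(with_temp, function(i) {
    p <- nn_predict(index, test_recs[[i]], k = 1L, task = "temperature")
    if (is_unseen_class(p) || length(p) == 0L) NA_integer_ else p[1L]
  }, integer(1))
  mae_of <- function(pred) {
    ok <- !is.na(pred)
    list(bin_mae = if (any(ok)) bin_mae(pred[ok], t_true[ok]) else NA_real_,
         off_by_1 = if (any(ok)) off_by_n_accuracy(pred[ok], t_true[ok], 1L)
                    else NA_real_)
  }
  stage2 <- list(model = mae_of(t_model), popularity = mae_of(t_pop),
                 nearest_neighbor = mae_of(t_nn))

  # stage 3: teacher-forced reactant bins, reaction-level categories
  cat_count <- function(cats) {
    as.list(table(factor(cats, levels = c("exact", "off_by_one", "major"))))
  }
  model_cats <- vapply(seq_along(test_recs), function(i) {
    rec <- test_recs[[i]]
    am <- encode_agent_set(truth_smiles[[i]], vocab)
    fp <- reaction_fingerprint(rec, radius = models$stage3$radius,
                               n_bits = models$stage3$n_bits)
    rfp <- .fingerprint_matrix(.side_smiles(rec$reactants),
                               radius = models$stage3$radius,
                               n_bits = models$stage3$n_bits)
    pred <- vapply(seq_len(nrow(rfp)), function(j) {
      which.max(stage_predict(models$stage3,
                              list(reaction_fp = fp, agent_multihot = am,
                                   reactant_fp = rfp[j, ])))
    }, integer(1))
    reaction_level_category(pred, truths[[i]]$reactant_bins)
  }, character(1))
  pop_bin_1eq <- popularity_predict(index, NA_character_, "reactant_amount")
  pop_cats <- vapply(seq_along(test_recs), function(i) {
    pred <- rep(pop_bin_1eq, length(truths[[i]]$reactant_bins))
    reaction_level_category(pred, truths[[i]]$reactant_bins)
  }, character(1))
  stage3 <- list(model = cat_count(model_cats),
                 popularity = cat_count(pop_cats))

  # stage 4: teacher-forced per-agent bin accuracy
  agent_hits <- function(pred_bins, truth_cs) {
    smis <- names(truth_cs$agent_bins)
    vapply(seq_along(smis), function(j) {
      pb <- pred_bins[[smis[j]]]
      !is.null(pb) && !is.na(pb) && pb == truth_cs$agent_bins[[j]]
    }, logical(1))
  }
  m4 <- unlist(lapply(seq_along(test_recs), function(i) {
    if (length(truths[[i]]$agent_bins) == 0L) return(logical(0))
    am <- encode_agent_set(names(truths[[i]]$agent_bins), vocab)
    fp <- reaction_fingerprint(test_recs[[i]], radius = models$stage4$radius,
                               n_bits = models$stage4$n_bits)
    dists <- stage_predict(models$stage4,
                           list(reaction_fp = fp, agent_multihot = am))
    agent_hits(lapply(dists, which.max), truths[[i]])
  }))
  p4 <- unlist(lapply(seq_along(test_recs), function(i) {
    if (length(truths[[i]]$agent_bins) == 0L) return(logical(0))
    p <- popularity_predict(index, test_recs[[i]]$class_id, "agent_amount")
    if (is_unseen_class(p)) return(rep(FALSE, length(truths[[i]]$agent_bins)))
    agent_hits(as.list(p), truths[[i]])
  }))
  stage4 <- list(model = list(agent_accuracy = mean(m4)),
                 popularity = list(agent_accuracy = mean(p4)))

  # end to end
  pop_hol <- lapply(test_recs, function(rec)
    popularity_predict(index, rec$class_id, "holistic"))
  nn_hol <- lapply(test_recs, function(rec)
    nn_predict(index, rec, k = 10L, task = "holistic"))
  e2e_match <- function(pred, truth) end_to_end_correct(pred, truth)$overall
  hol_acc <- function(pred_lists, k) {
    clean <- lapply(pred_lists, function(p) if (is_unseen_class(p)) list() else p)
    topk_accuracy(clean, truths, k, e2e_match)
  }
  end_to_end <- list(
    model = list(top1 = hol_acc(preds, 1L), top10 = hol_acc(preds, 10L)),
    popularity = list(top1 = hol_acc(pop_hol, 1L),
                      top10 = hol_acc(pop_hol, 10L)),
    nearest_neighbor = list(top1 = hol_acc(nn_hol, 1L),
                            top10 = hol_acc(nn_hol, 10L)))

  wr <- win_rate(preds, nn_hol, truths,
                 grouping = vapply(test_recs, `[[`, character(1), "class_id"))

  list(stage1 = stage1, stage2 = stage2, stage3 = stage3, stage4 = stage4,
       end_to_end = end_to_end,
       win_rate_model_vs_nn = wr,
       counts = counts)
}
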