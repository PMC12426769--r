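# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fx_smiles <- function() c("O", "CO", "CCO", "CC(=O)O", "C1CCOC1", "CN(C)C=O")

fx_vocab <- function() {
  if (is.null(.fx$vocab)) .fx$vocab <- agent_vocabulary(fx_smiles())
  .fx$vocab
}

# A minimal complete record with controllable conditions.
fx_record <- function(doc = "doc-1",
                      reactants = list(list(smiles = "CCO", moles = 0.01),
                                       list(smiles = "CC(=O)O", moles = 0.02)),
                      agents = list(list(smiles = "C1CCOC1", moles = 0.1)),
                      products = list(list(smiles = "CCOC(C)=O")),
                      temperature_c = 25, class_id = "1.1.1") {
  reaction_record(document_id = doc, reactants = reactants, agents = agents,
                  products = products, temperature_c = temperature_c,
                  class_id = class_id)
}

# Noiseless 2-class world + records, shared across test files.
fx_world <- function() {
  if (is.null(.fx$world)) {
    cfg <- world_config(n_classes = 2L, agent_swap_prob = 0,
                        temperature_jitter_sd = 0, amount_jitter_frac = 0,
                        seed = 42L)
    .fx$world <- generate_world(cfg)
  }
  .fx$world
}

fx_records <- function() {
  if (is.null(.fx$records)) {
    .fx$records <- sample_records(fx_world(), 240L, seed = 17L)
  }
  .fx$records
}

fx_world_vocab <- function() {
  if (is.null(.fx$wvocab)) {
    .fx$wvocab <- build_vocabulary(fx_records(), min_count = 1L)
  }
  .fx$wvocab
}

# Small trained stage models on the noiseless fixture world (shared by the
# stage, decoding and pipeline tests).
fx_models <- function() {
  if (is.null(.fx$models)) {
    recs <- fx_records()
    vocab <- fx_world_vocab()
    tc <- train_config(hidden = 48L, epochs = 12L, seed = 5L)
    .fx$models <- list(
      stage1 = train_stage1(stage_filter(recs, vocab, 1L), vocab, tc),
      stage2 = train_stage2(stage_filter(recs, vocab, 2L), vocab, tc),
      stage3 = train_stage3(stage_filter(recs, vocab, 3L), vocab, tc),
      stage4 = train_stage4(stage_filter(recs, vocab, 4L), vocab, tc))
  }
  .fx$models
}

# Exhaustive ordered-decode oracle for beam-search equivalence: enumerates
# every ordered sequence of distinct agents of length <= max_len followed
# by EOS, accumulating joint probability per unordered set.
oracle_set_probs <- function(prob_fn, V, max_len, normalize = "sigmoid") {
  eos <- V + 1L
  acc <- new.env(parent = emptyenv())
  add <- function(set, p) {
    # "s" prefix: the empty set's key "" is not a legal env variable name
    k <- paste0("s", paste(sort(set), collapse = ","))
    prev <- acc[[k]]
    acc[[k]] <- (if (is.null(prev)) 0 else prev) + p
  }
  step_probs <- function(set) {
    am <- matrix(0, nrow = 1L, ncol = V)
    am[1L, set] <- 1
    p <- prob_fn(am)[1L, ]
    if (normalize == "softmax") {
      allowed <- c(setdiff(seq_len(V), set), eos)
      z <- sum(p[allowed])
      if (z > 0) p <- p / z
    }
    p
  }
  recurse <- function(set, joint) {
    p <- step_probs(set)
    add(set, joint * p[eos])
    if (length(set) < max_len) {
      for (a in setdiff(seq_len(V), set)) {
        recurse(c(set, a), joint * p[a])
      }
    }
  }
  recurse(integer(0), 1)
  keys <- ls(acc)
  probs <- vapply(keys, function(k) acc[[k]], numeric(1))
  names(probs) <- substring(keys, 2L)
  probs
}
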