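# The four condition-prediction stages as fingerprint-FFN classifiers.
#
# Stage 1 (agent identity): multi-label head over the vocabulary plus an
#   end-of-set symbol, trained with partition augmentation so the model can
#   complete any partial agent set regardless of order.
# Stage 2 (temperature): 30-way softmax over 10 degC bins.
# Stage 3 (reactant amount): 15-way softmax per reactant, conditioned on
#   that reactant's own fingerprint.
# Stage 4 (agent amount): a (vocabulary x 27) logit grid; the input agent
#   vector masks the loss and the predictions to agents actually present.
# Stages 2-4 are trained with teacher forcing: their training inputs carry
# the ground-truth agent multi-hot, never stage-1 predictions. At inference
# the pipeline feeds them predicted agents instead.
#
# The fingerprint encoder is one pluggable choice of input encoder; the
# training entry points accept any encoder that maps a record to a fixed-
# length numeric vector (see `fingerprint_encoder()`).

#' Training configuration for stage models
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed seed controlling weight init and shuffling.
#' @param head stage-1 output semantics: `"sigmoid"` (independent
#'   multi-label probabilities, the default) or `"softmax"` (step-normalized
#'   over non-members plus EOS at decode time).
#' @return a `train_config` list.
#' @export
train_config <- function(hidden = c(1024L, 512L), lr = 1e-3, epochs = 20L,
                         batch_size = 256L, seed = 1L,
                         head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  stopifnot(all(hidden >= 1L), lr > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(hidden = as.integer(hidden), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), head = head),
            class = "train_config")
}

#' Fingerprint reaction encoder
#'
#' The default reaction encoder: the concatenated reactant/product circular
#' fingerprint of [reaction_fingerprint()]. Alternative encoders (e.g. a
#' learned graph encoder) can be supplied to the training functions as any
#' object with the same interface: `encoder$dim` and
#' `encoder$encode(records)` returning a `n x dim` (possibly sparse)
#' matrix.
#'
#' @param radius,n_bits fingerprint parameters.
#' @return an encoder object.
#' @export
fingerprint_encoder <- function(radius = 2L, n_bits = 2048L) {
  force(radius); force(n_bits)
  list(
    name = "fingerprint_ffn",
    dim = 2L * n_bits,
    radius = radius,
    n_bits = n_bits,
    encode = function(records) {
      nz_list <- lapply(records, function(rec) {
        which(reaction_fingerprint(rec, radius = radius,
                                   n_bits = n_bits) == 1L)
      })
      lens <- lengths(nz_list)
      Matrix::sparseMatrix(i = rep.int(seq_along(records), lens),
                           j = unlist(nz_list), x = 1,
                           dims = c(length(records), 2L * n_bits))
    },
    encode_molecules = function(smiles) {
      m <- .fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
      Matrix::Matrix(m, sparse = TRUE)
    })
}

#' Enumerate partition-augmentation training pairs of an agent set
#'
#' Every subset S of the true agent set A yields one training pair: input S,
#' target A \ S when nonempty, or the end-of-set symbol when S = A. An
#' agent set of size k yields exactly `2^k` pairs, which trains the model
#' to complete any partial agent set regardless of decoding order.
#'
#' @param agent_idx integer vector of vocabulary indices (the true set A).
#' @param eos_index index of the end-of-set symbol.
#' @param cap maximum |A| before the set is skipped (the pair count grows as
#'   `2^|A|`); returns NULL above the cap.
#' @return list of `list(input =, target =)` index vectors, where a target
#'   equal to `eos_index` means "the set is complete"; or NULL if capped.
#' @export
enumerate_partitions <- function(agent_idx, eos_index, cap = 6L) {
  agent_idx <- sort(unique(as.integer(agent_idx)))
  k <- length(agent_idx)
  if (k > cap) return(NULL)
  if (k == 0L) return(list(list(input = integer(0), target = eos_index)))
  out <- vector("list", 2^k)
  for (m in 0:(2^k - 1L)) {
    in_set <- agent_idx[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    target <- setdiff(agent_idx, in_set)
    if (length(target) == 0L) target <- eos_index
    out[[m + 1L]] <- list(input = in_set, target = target)
  }
  out
}

# --- shared builders ----------------------------------------------------

.true_agent_indices <- function(rec, vocab) {
  sort(unique(vocab_index(vocab, .side_smiles(rec$agents))))
}

.class_table <- function(records) {
  sort(unique(stats::na.omit(vapply(records, `[[`, character(1), "class_id"))))
}

#' One-hot encoding of a reaction class
#'
#' Classes unseen at training time yield an all-zero vector (graceful
#' degradation) rather than an error.
#'
#' @param class_id a class label string.
#' @param classes the model's ordered class table.
#' @return numeric 0/1 vector of length `length(classes)`.
#' @export
class_onehot <- function(class_id, classes) {
  v <- numeric(length(classes))
  if (!is.na(class_id)) {
    hit <- match(class_id, classes)
    if (!is.na(hit)) v[hit] <- 1
  }
  v
}

.new_stage_model <- function(stage, net, encoder, vocab, classes = NULL,
                             scheme = NULL, cfg = NULL) {
  structure(list(stage = stage, net = net,
                 encoder_name = encoder$name,
                 radius = encoder$radius, n_bits = encoder$n_bits,
                 vocab = vocab, classes = classes, scheme = scheme,
                 head = if (!is.null(cfg)) cfg$head else "sigmoid",
                 cfg = cfg),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat("Stage", x$stage, "model (", x$encoder_name, "encoder ), layers:",
      paste(x$net$sizes, collapse = " -> "), "\n")
  invisible(x)
}

# cbind a sparse fp block with dense side blocks, staying sparse
.stage_design <- function(fp_block, ...) {
  blocks <- list(fp_block, ...)
  blocks <- Filter(function(b) !is.null(b) && ncol(b) > 0L, blocks)
  out <- do.call(cbind, blocks)
  methods::as(out, "CsparseMatrix")
}

# --- stage 1 ------------------------------------------------------------

#' Train the stage-1 agent-identity model
#'
#' Expands every record into its partition-augmentation pairs and trains a
#' multi-label head (independent binary cross-entropy over |V|+1 outputs)
#' on input = reaction encoding, class one-hot and the pair's input agent
#' multi-hot; target = multi-hot of the pair's target set.
#'
#' @param records training [reaction_record()]s with nonempty in-vocabulary
#'   agent sets.
#' @param vocab an [agent_vocabulary()].
#' @param cfg a [train_config()].
#' @param encoder reaction encoder (default [fingerprint_encoder()]).
#' @param classes class table; defaults to classes seen in `records`.
#' @param partition_cap maximum agent-set size for augmentation.
#' @return a `stage_model`.
#' @export
train_stage1 <- function(records, vocab, cfg = train_config(),
                         encoder = fingerprint_encoder(),
                         classes = NULL, partition_cap = 6L) {
  if (length(records) == 0L) stop("empty training set")
  if (is.null(classes)) classes <- .class_table(records)
  V <- length(vocab)
  fp <- encoder$encode(records)
  acc <- list(rows_fp = vector("list", length(records)),
              rows_class = vector("list", length(records)),
              in_j = vector("list", length(records)),
              in_len = vector("list", length(records)),
              y_j = vector("list", length(records)),
              y_len = vector("list", length(records)))
  n_skipped <- 0L
  for (r in seq_along(records)) {
    rec <- records[[r]]
    A <- .true_agent_indices(rec, vocab)
    pairs <- enumerate_partitions(A, vocab$eos_index, cap = partition_cap)
    if (is.null(pairs)) { n_skipped <- n_skipped + 1L; next }
    cls <- match(rec$class_id, classes)
    acc$rows_fp[[r]] <- rep.int(r, length(pairs))
    acc$rows_class[[r]] <- rep.int(if (is.na(cls)) 0L else cls, length(pairs))
    acc$in_j[[r]] <- unlist(lapply(pairs, `[[`, "input"))
    acc$in_len[[r]] <- vapply(pairs, function(p) length(p$input), integer(1))
    acc$y_j[[r]] <- unlist(lapply(pairs, `[[`, "target"))
    acc$y_len[[r]] <- vapply(pairs, function(p) length(p$target), integer(1))
  }
  rows_fp <- unlist(acc$rows_fp)
  rows_class <- unlist(acc$rows_class)
  row <- length(rows_fp)
  if (row == 0L) stop("no usable training pairs (all agent sets above cap?)")
  in_len <- unlist(acc$in_len); y_len <- unlist(acc$y_len)
  in_i <- rep.int(seq_len(row), in_len)
  in_j <- as.integer(unlist(acc$in_j))
  y_i <- rep.int(seq_len(row), y_len)
  y_j <- as.integer(unlist(acc$y_j))
  if (n_skipped > 0L) {
    message("partition augmentation skipped ", n_skipped,
            " record(s) with agent sets larger than ", partition_cap)
  }
  C <- length(classes)
  cls_mat <- Matrix::sparseMatrix(
    i = which(rows_class > 0L), j = rows_class[rows_class > 0L], x = 1,
    dims = c(row, max(C, 1L)))
  agent_mat <- Matrix::sparseMatrix(i = in_i, j = in_j, x = 1,
                                    dims = c(row, V))
  X <- .stage_design(fp[rows_fp, , drop = FALSE],
                     if (C > 0L) cls_mat else NULL, agent_mat)
  Y <- matrix(0, nrow = row, ncol = V + 1L)
  Y[cbind(y_i, y_j)] <- 1
  net <- mlp_new(c(ncol(X), cfg$hidden, V + 1L), seed = cfg$seed)
  net <- mlp_train(net, X, Y, loss = "bce", epochs = cfg$epochs,
                   lr = cfg$lr, batch_size = cfg$batch_size, seed = cfg$seed)
  .new_stage_model(1L, net, encoder, vocab, classes = classes, cfg = cfg)
}

# --- stage 2 ------------------------------------------------------------

#' Train the stage-2 temperature model
#'
#' 30-way softmax over temperature bins; input = reaction encoding and the
#' ground-truth agent multi-hot (teacher forcing).
#'
#' @inheritParams train_stage1
#' @param scheme temperature [bin_scheme()].
#' @return a `stage_model`.
#' @export
train_stage2 <- function(records, vocab, cfg = train_config(),
                         encoder = fingerprint_encoder(),
                         scheme = temperature_bins()) {
  if (length(records) == 0L) stop("empty training set")
  temps <- vapply(records, `[[`, numeric(1), "temperature_c")
  stopifnot(!anyNA(temps))
  y <- assign_bin(temps, scheme)
  fp <- encoder$encode(records)
  agent_mat <- .agent_multihot_matrix(records, vocab)
  X <- .stage_design(fp, agent_mat)
  net <- mlp_new(c(ncol(X), cfg$hidden, scheme$n_bins), seed = cfg$seed)
  net <- mlp_train(net, X, y, loss = "ce", epochs = cfg$epochs, lr = cfg$lr,
                   batch_size = cfg$batch_size, seed = cfg$seed)
  .new_stage_model(2L, net, encoder, vocab, scheme = scheme, cfg = cfg)
}

.agent_multihot_matrix <- function(records, vocab) {
  idx_list <- lapply(records, .true_agent_indices, vocab = vocab)
  lens <- lengths(idx_list)
  Matrix::sparseMatrix(i = rep.int(seq_along(records), lens),
                       j = unlist(idx_list), x = 1,
                       dims = c(length(records), length(vocab)))
}

# --- stage 3 ------------------------------------------------------------

#' Train the stage-3 reactant-amount model
#'
#' One training row per (reaction, reactant): 15-way softmax over
#' equivalence-ratio bins; input = reaction encoding, ground-truth agent
#' multi-hot (teacher forcing) and the fingerprint of the single reactant
#' whose amount is being predicted.
#'
#' @inheritParams train_stage1
#' @param scheme reactant-amount [bin_scheme()].
#' @return a `stage_model`.
#' @export
train_stage3 <- function(records, vocab, cfg = train_config(),
                         encoder = fingerprint_encoder(),
                         scheme = reactant_amount_bins()) {
  if (length(records) == 0L) stop("empty training set")
  fp <- encoder$encode(records)
  agent_mat <- .agent_multihot_matrix(records, vocab)
  per_rec <- lapply(seq_along(records), function(i) {
    eq <- equivalence_ratios(records[[i]])
    smis <- .side_smiles(records[[i]]$reactants)
    list(rec = rep.int(i, length(smis)), smiles = smis,
         y = assign_bin(eq$reactants, scheme))
  })
  rows_rec <- unlist(lapply(per_rec, `[[`, "rec"))
  r_smiles <- unlist(lapply(per_rec, `[[`, "smiles"))
  y <- unlist(lapply(per_rec, `[[`, "y"))
  rfp <- encoder$encode_molecules(r_smiles)
  X <- .stage_design(fp[rows_rec, , drop = FALSE],
                     agent_mat[rows_rec, , drop = FALSE], rfp)
  net <- mlp_new(c(ncol(X), cfg$hidden, scheme$n_bins), seed = cfg$seed)
  net <- mlp_train(net, X, y, loss = "ce", epochs = cfg$epochs, lr = cfg$lr,
                   batch_size = cfg$batch_size, seed = cfg$seed)
  .new_stage_model(3L, net, encoder, vocab, scheme = scheme, cfg = cfg)
}

# --- stage 4 ------------------------------------------------------------

#' Train the stage-4 agent-amount model
#'
#' Emits a `(vocabulary x 27)` grid of logits; the loss is the mean over
#' PRESENT agents of each agent's 27-way softmax cross-entropy
#' ([masked_softmax_loss()]), so absent agents contribute zero loss and
#' zero gradient. Teacher forcing: the input agent multi-hot is the ground
#' truth.
#'
#' @inheritParams train_stage1
#' @param scheme agent-amount [bin_scheme()].
#' @return a `stage_model`.
#' @export
train_stage4 <- function(records, vocab, cfg = train_config(),
                         encoder = fingerprint_encoder(),
                         scheme = agent_amount_bins()) {
  if (length(records) == 0L) stop("empty training set")
  V <- length(vocab)
  fp <- encoder$encode(records)
  agent_mat <- .agent_multihot_matrix(records, vocab)
  labels <- matrix(0L, nrow = length(records), ncol = V)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    eq <- equivalence_ratios(rec)
    asmis <- .side_smiles(rec$agents)
    idx <- vocab_index(vocab, asmis)
    stopifnot(!anyNA(eq$agents))
    bins <- assign_bin(eq$agents, scheme)
    # duplicate agents keep the first occurrence's bin
    first <- !duplicated(idx)
    labels[i, idx[first]] <- bins[first]
  }
  X <- .stage_design(fp, agent_mat)
  net <- mlp_new(c(ncol(X), cfg$hidden, V * scheme$n_bins), seed = cfg$seed)
  net <- mlp_train(net, X, labels, loss = "masked_ce", epochs = cfg$epochs,
                   lr = cfg$lr, batch_size = cfg$batch_size, seed = cfg$seed,
                   n_bins = scheme$n_bins)
  .new_stage_model(4L, net, encoder, vocab, scheme = scheme, cfg = cfg)
}

# --- prediction ---------------------------------------------------------

#' Predict with a stage model
#'
#' @param model a `stage_model`.
#' @param input a list with the components the stage needs:
#'   `reaction_fp` (length `2 * n_bits`), `class_onehot` (stage 1),
#'   `agent_multihot` (length |V|; a matrix of such rows is accepted for
#'   stage 1 to score many partial sets at once), `reactant_fp` (stage 3).
#' @return stage 1: numeric vector (or matrix) of |V|+1 probabilities, each
#'   in \[0,1\] (independent sigmoids under the default head); stages 2 and
#'   3: a probability simplex over bins; stage 4: a named list of 27-bin
#'   simplexes, one per agent set in `agent_multihot`.
#' @export
stage_predict <- function(model, input) {
  stopifnot(inherits(model, "stage_model"))
  fp <- input$reaction_fp
  if (length(fp) != 2L * model$n_bits) {
    stop("reaction_fp has length ", length(fp), ", expected ",
         2L * model$n_bits)
  }
  V <- length(model$vocab)
  if (model$stage == 1L) {
    am <- input$agent_multihot
    if (is.null(am)) am <- numeric(V)
    if (!is.matrix(am)) am <- matrix(am, nrow = 1L)
    if (ncol(am) != V) stop("agent_multihot has ", ncol(am),
                            " columns, expected ", V)
    co <- input$class_onehot
    C <- length(model$classes)
    if (is.null(co)) co <- numeric(C)
    if (length(co) != C) stop("class_onehot has length ", length(co),
                              ", expected ", C)
    k <- nrow(am)
    X <- cbind(matrix(rep(fp, each = k), nrow = k),
               matrix(rep(co, each = k), nrow = k), am)
    logits <- mlp_forward(model$net, X)
    out <- if (model$head == "sigmoid") .sigmoid(logits)
           else .softmax_rows(logits)
    if (k == 1L) out[1L, ] else out
  } else if (model$stage %in% c(2L, 3L)) {
    am <- as.numeric(input$agent_multihot)
    if (length(am) != V) stop("agent_multihot has length ", length(am),
                              ", expected ", V)
    x <- c(fp, am)
    if (model$stage == 3L) {
      rfp <- input$reactant_fp
      if (length(rfp) != model$n_bits) {
        stop("reactant_fp has length ", length(rfp), ", expected ",
             model$n_bits)
      }
      x <- c(x, rfp)
    }
    logits <- mlp_forward(model$net, matrix(x, nrow = 1L))
    as.numeric(.softmax_rows(logits))
  } else {
    am <- as.numeric(input$agent_multihot)
    if (length(am) != V) stop("agent_multihot has length ", length(am),
                              ", expected ", V)
    logits <- mlp_forward(model$net, matrix(c(fp, am), nrow = 1L))
    K <- model$scheme$n_bins
    present <- which(am == 1)
    out <- lapply(present, function(v) {
      z <- logits[1L, (v - 1L) * K + seq_len(K)]
      as.numeric(.softmax_rows(matrix(z, nrow = 1L)))
    })
    names(out) <- model$vocab$agents[present]
    out
  }
}

#' Save / load a stage model
#'
#' Checkpoints embed the vocabulary and bin scheme they were trained with;
#' [check_model_compatible()] verifies both before a model is used against
#' a dataset.
#'
#' @param model a `stage_model`.
#' @param path file path (RDS).
#' @export
save_stage_model <- function(model, path) {
  stopifnot(inherits(model, "stage_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_stage_model
#' @export
load_stage_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "stage_model")) stop("not a stage model: ", path)
  model
}

#' Verify that a model matches a vocabulary and bin scheme
#'
#' @param model a `stage_model`.
#' @param vocab an [agent_vocabulary()] (or NULL to skip).
#' @param scheme a [bin_scheme()] (or NULL to skip).
#' @return TRUE invisibly; errors on mismatch.
#' @export
check_model_compatible <- function(model, vocab = NULL, scheme = NULL) {
  stopifnot(inherits(model, "stage_model"))
  if (!is.null(vocab) && !identical(model$vocab$agents, vocab$agents)) {
    stop("model was trained with a different agent vocabulary")
  }
  if (!is.null(scheme) && !is.null(model$scheme) &&
      !identical(model$scheme$edges, scheme$edges)) {
    stop("model was trained with a different bin scheme")
  }
  invisible(TRUE)
}
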