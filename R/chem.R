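# Molecular and reaction representation shared by all stages and baselines.
#
# Molecules are represented throughout the package as canonical SMILES strings;
# `canonicalize_smiles()` is the constructor and the single place where parse
# failure is detected. Fingerprints are circular (Morgan-family / ECFP)
# fingerprints computed through OpenBabel and folded to a fixed bit length.

.chem_cache <- new.env(parent = emptyenv())

# Syntactic screen applied before handing a string to OpenBabel, whose SMILES
# reader is permissive and will silently truncate some malformed inputs.
.smiles_syntax_ok <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[[:space:]]", s)) return(FALSE)
  if (!grepl("^[A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]+$", s, perl = TRUE)) {
    return(FALSE)
  }
  chars <- strsplit(s, "")[[1]]
  depth_paren <- cumsum((chars == "(") - (chars == ")"))
  depth_brack <- cumsum((chars == "[") - (chars == "]"))
  all(depth_paren >= 0) && all(depth_brack >= 0) &&
    depth_paren[length(chars)] == 0L && depth_brack[length(chars)] == 0L
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the OpenBabel canonical form. Canonicalization is
#' idempotent, so canonical SMILES are usable as dictionary keys (vocabulary
#' lookups, fingerprint caches, deduplication keys). Parse failures are
#' raised immediately, naming the offending input.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles("OCC")  # "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- !vapply(smiles, .smiles_syntax_ok, logical(1))
  if (any(bad)) {
    stop("cannot parse SMILES: ", paste(sQuote(smiles[bad]), collapse = ", "))
  }
  key <- paste0("can:", smiles)
  out <- character(length(smiles))
  hit <- vapply(key, function(k) !is.null(.chem_cache[[k]]), logical(1))
  out[hit] <- vapply(key[hit], function(k) .chem_cache[[k]], character(1))
  todo <- unique(smiles[!hit])
  if (length(todo) > 0L) {
    raw <- ChemmineOB::convertFormat("SMI", "CAN", paste(todo, collapse = "\n"))
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
    lines <- sub("\t.*$", "", lines)
    lines <- trimws(lines)
    if (length(lines) != length(todo) || any(!nzchar(lines))) {
      # the batch desynced or produced empties: find offenders one by one
      for (s in todo) {
        one <- trimws(sub("\t.*$", "", ChemmineOB::convertFormat("SMI", "CAN", s)))
        if (length(one) != 1L || !nzchar(one)) {
          stop("cannot parse SMILES: ", sQuote(s))
        }
        .chem_cache[[paste0("can:", s)]] <- one
      }
    } else {
      for (i in seq_along(todo)) .chem_cache[[paste0("can:", todo[i])]] <- lines[i]
    }
    out[!hit] <- vapply(key[!hit], function(k) .chem_cache[[k]], character(1))
  }
  out
}

#' Count heavy (non-hydrogen) atoms in a SMILES string
#'
#' Token-level count used by the quality filters; operates on the SMILES
#' text itself (organic-subset symbols plus bracket atoms, excluding
#' explicit hydrogens).
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector of heavy-atom counts.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    n <- 0L
    i <- 1L
    chars <- strsplit(s, "")[[1]]
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "[") {
        j <- i
        while (j <= length(chars) && chars[j] != "]") j <- j + 1L
        token <- paste(chars[i:j], collapse = "")
        if (!grepl("^\\[[0-9]*H[0-9+\\-]*\\]$", token)) n <- n + 1L
        i <- j + 1L
      } else if (ch %in% c("C", "B")) {
        nxt <- if (i < length(chars)) chars[i + 1L] else ""
        if ((ch == "C" && nxt == "l") || (ch == "B" && nxt == "r")) i <- i + 1L
        n <- n + 1L
        i <- i + 1L
      } else if (ch %in% c("N", "O", "P", "S", "F", "I",
                           "b", "c", "n", "o", "p", "s")) {
        n <- n + 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

.fold_bits <- function(v, n_bits) {
  if (length(v) %% n_bits != 0L) {
    stop("fingerprint length ", length(v), " is not a multiple of n_bits = ", n_bits)
  }
  folds <- length(v) / n_bits
  out <- v[seq_len(n_bits)]
  for (k in seq_len(folds - 1L)) {
    out <- out | v[k * n_bits + seq_len(n_bits)]
  }
  as.integer(out)
}

# Fingerprints for a character vector of SMILES, as an n x n_bits 0/1 matrix.
# Memoized on (canonical SMILES, radius, n_bits): reaction corpora reuse a
# modest set of distinct molecules, so the cache removes almost all OpenBabel
# calls after the first pass.
.fingerprint_matrix <- function(smiles, radius = 2L, n_bits = 2048L) {
  can <- canonicalize_smiles(smiles)
  key <- paste0("fp:", radius, ":", n_bits, ":", can)
  miss <- vapply(key, function(k) is.null(.chem_cache[[k]]), logical(1))
  todo <- unique(can[miss])
  if (length(todo) > 0L) {
    fpname <- paste0("ECFP", 2L * radius)
    mols <- ChemmineOB::forEachMol("SMILES", paste(todo, collapse = "\n"), identity)
    raw <- ChemmineOB::fingerprint_OB(mols, fpname)
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
    if (nrow(raw) != length(todo)) {
      stop("fingerprint computation desynced (", nrow(raw), " fingerprints for ",
           length(todo), " molecules)")
    }
    for (i in seq_along(todo)) {
      .chem_cache[[paste0("fp:", radius, ":", n_bits, ":", todo[i])]] <-
        .fold_bits(raw[i, ] > 0, n_bits)
    }
  }
  out <- matrix(0L, nrow = length(can), ncol = n_bits)
  for (i in seq_along(can)) out[i, ] <- .chem_cache[[key[i]]]
  rownames(out) <- can
  out
}

#' Circular fingerprint of a molecule
#'
#' Computes the binary circular (ECFP-style) fingerprint of a molecule,
#' folded to a fixed length. Deterministic: the same molecule always yields
#' the same bit vector regardless of the input SMILES spelling.
#'
#' @param smiles a single SMILES string.
#' @param radius neighborhood radius (default 2, i.e. ECFP4-class).
#' @param n_bits folded fingerprint length (default 2048).
#' @return integer 0/1 vector of length `n_bits`.
#' @export
molecule_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(smiles) == 1L)
  .fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)[1L, ]
}

#' Reaction fingerprint
#'
#' Encodes a reaction as the bitwise OR of its reactant fingerprints (first
#' block) concatenated with the bitwise OR of its product fingerprints
#' (second block); total length `2 * n_bits`. Invariant to the order of
#' reactants and of products.
#'
#' @param reactants character vector of reactant SMILES (at least one), or a
#'   [reaction_record()] (in which case `products` must be missing).
#' @param products character vector of product SMILES (at least one).
#' @param radius,n_bits fingerprint parameters, as in [molecule_fingerprint()].
#' @return integer 0/1 vector of length `2 * n_bits`.
#' @export
reaction_fingerprint <- function(reactants, products, radius = 2L, n_bits = 2048L) {
  if (inherits(reactants, "reaction_record")) {
    rec <- reactants
    reactants <- vapply(rec$reactants, `[[`, character(1), "smiles")
    products <- vapply(rec$products, `[[`, character(1), "smiles")
  }
  stopifnot(length(reactants) >= 1L, length(products) >= 1L)
  rb <- .fingerprint_matrix(reactants, radius, n_bits)
  pb <- .fingerprint_matrix(products, radius, n_bits)
  c(as.integer(colSums(rb) > 0), as.integer(colSums(pb) > 0))
}

#' Tanimoto similarity between binary fingerprints
#'
#' @param a,b binary vectors of equal length.
#' @return similarity |a AND b| / |a OR b| in \[0, 1\]; defined as 0 when both
#'   vectors are all-zero.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

#' Agent vocabulary
#'
#' A fixed ordered set of canonical agent SMILES, the basis of every
#' multi-hot agent encoding. The end-of-set symbol used by autoregressive
#' decoding occupies one extra index past the last agent (`eos_index`).
#'
#' @param agents character vector of agent SMILES (canonicalized on
#'   construction; duplicates after canonicalization are an error).
#' @return an object of class `agent_vocabulary` with fields `agents`
#'   (canonical SMILES in order) and `eos_index` (`length(agents) + 1`).
#' @export
agent_vocabulary <- function(agents) {
  stopifnot(is.character(agents), length(agents) >= 1L)
  can <- canonicalize_smiles(agents)
  if (anyDuplicated(can)) {
    stop("duplicate agents in vocabulary: ",
         paste(unique(can[duplicated(can)]), collapse = ", "))
  }
  idx <- seq_along(can)
  names(idx) <- can
  structure(list(agents = can, index = idx, eos_index = length(can) + 1L),
            class = "agent_vocabulary")
}

#' @export
length.agent_vocabulary <- function(x) length(x$agents)

#' @export
print.agent_vocabulary <- function(x, ...) {
  cat("Agent vocabulary:", length(x$agents), "agents + EOS (index",
      x$eos_index, ")\n")
  show <- utils::head(x$agents, 8L)
  cat("  ", paste(show, collapse = ", "),
      if (length(x$agents) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Look up vocabulary indices of agent SMILES
#'
#' @param vocab an [agent_vocabulary()].
#' @param smiles character vector of agent SMILES (canonicalized first).
#' @param strict error on out-of-vocabulary agents (default); otherwise NA.
#' @return integer vector of indices.
#' @export
vocab_index <- function(vocab, smiles, strict = TRUE) {
  stopifnot(inherits(vocab, "agent_vocabulary"))
  if (length(smiles) == 0L) return(integer(0))
  can <- canonicalize_smiles(smiles)
  idx <- unname(vocab$index[can])
  if (strict && anyNA(idx)) {
    stop("agent not in vocabulary: ",
         paste(sQuote(can[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Multi-hot encoding of an agent set
#'
#' @param agents character vector (a set) of agent SMILES; every agent must
#'   be in the vocabulary.
#' @param vocab an [agent_vocabulary()].
#' @return integer 0/1 vector of length `length(vocab)` with exactly
#'   `length(unique(agents))` bits set.
#' @export
encode_agent_set <- function(agents, vocab) {
  v <- integer(length(vocab))
  if (length(agents) > 0L) {
    v[unique(vocab_index(vocab, agents))] <- 1L
  }
  v
}

#' Decode vocabulary indices (or a multi-hot vector) back to SMILES
#'
#' @param x integer vector of vocabulary indices, or a 0/1 multi-hot vector
#'   of length `length(vocab)`.
#' @param vocab an [agent_vocabulary()].
#' @return character vector of canonical SMILES, sorted.
#' @export
decode_agent_set <- function(x, vocab) {
  stopifnot(inherits(vocab, "agent_vocabulary"))
  if (length(x) == length(vocab) && all(x %in% c(0L, 1L)) &&
      (length(x) == 0L || max(x) <= 1L)) {
    idx <- which(x == 1L)
  } else {
    idx <- as.integer(x)
  }
  if (length(idx) == 0L) return(character(0))
  stopifnot(all(idx >= 1L & idx <= length(vocab)))
  sort(vocab$agents[idx])
}

# Clear the internal canonicalization/fingerprint cache (mainly for tests
# and memory-sensitive callers).
#' @keywords internal
clear_chem_cache <- function() {
  rm(list = ls(.chem_cache), envir = .chem_cache)
  invisible(NULL)
}
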