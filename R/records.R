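# ReactionRecord: one literature-style reaction with species, molar
# quantities, temperature, hierarchical class label and document id.
# Records cross module boundaries as JSON-lines, one object per line.

#' Construct a reaction record
#'
#' @param document_id opaque document identifier (records from one document
#'   always share a data split).
#' @param reactants list of `list(smiles =, moles =)`; `moles` optional
#'   (omitted or NA when the source did not report a quantity). At least one
#'   reactant is required and recorded moles must be strictly positive.
#' @param agents list of `list(smiles =, moles =)`, possibly empty.
#'   "Agent" is role-agnostic: catalysts, reagents and solvents alike.
#' @param products list of `list(smiles =)`; at least one product.
#' @param temperature_c reaction temperature in degrees Celsius, or NA.
#' @param class_id three-tier reaction-class label `"t1.t2.t3"`, or NA.
#' @param canonicalize canonicalize all SMILES on construction (default TRUE).
#' @return an object of class `reaction_record`.
#' @export
reaction_record <- function(document_id, reactants, agents = list(),
                            products, temperature_c = NA_real_,
                            class_id = NA_character_, canonicalize = TRUE) {
  stopifnot(is.character(document_id), length(document_id) == 1L)
  norm_side <- function(side, with_moles = TRUE) {
    lapply(side, function(sp) {
      if (is.character(sp)) sp <- list(smiles = sp)
      smi <- sp$smiles
      stopifnot(is.character(smi), length(smi) == 1L)
      if (canonicalize) smi <- canonicalize_smiles(smi)
      if (!with_moles) return(list(smiles = smi))
      moles <- if (is.null(sp$moles)) NA_real_ else as.numeric(sp$moles)
      if (!is.na(moles) && moles <= 0) {
        stop("recorded moles must be strictly positive (got ", moles,
             " for ", smi, ")")
      }
      list(smiles = smi, moles = moles)
    })
  }
  if (length(reactants) < 1L) stop("a reaction needs at least one reactant")
  if (length(products) < 1L) stop("a reaction needs at least one product")
  structure(list(
    document_id = document_id,
    reactants = norm_side(reactants),
    agents = norm_side(agents),
    products = norm_side(products, with_moles = FALSE),
    temperature_c = as.numeric(temperature_c),
    class_id = as.character(class_id)
  ), class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(reaction_smiles(x), "\n")
  cat("  document:", x$document_id,
      " class:", x$class_id,
      " T:", x$temperature_c, "degC\n")
  invisible(x)
}

.side_smiles <- function(side) vapply(side, `[[`, character(1), "smiles")

#' Reaction SMILES of a record (`reactants>agents>products`)
#'
#' @param record a [reaction_record()].
#' @return a single reaction SMILES string with dot-separated species.
#' @export
reaction_smiles <- function(record) {
  paste(paste(.side_smiles(record$reactants), collapse = "."),
        paste(.side_smiles(record$agents), collapse = "."),
        paste(.side_smiles(record$products), collapse = "."),
        sep = ">")
}

#' Split a reaction SMILES into its three sides
#'
#' @param s reaction SMILES `reactants>agents>products`.
#' @return list with character vectors `reactants`, `agents`, `products`.
#' @export
parse_reaction_smiles <- function(s) {
  parts <- strsplit(s, ">", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    # strsplit drops a trailing empty field: "a>>": c("a","")
    parts <- c(parts, rep("", 3L - length(parts)))
  }
  split_side <- function(p) {
    if (!nzchar(p)) character(0) else strsplit(p, ".", fixed = TRUE)[[1]]
  }
  list(reactants = split_side(parts[1]),
       agents = split_side(parts[2]),
       products = split_side(parts[3]))
}

.record_to_json <- function(rec) {
  obj <- list(
    document_id = rec$document_id,
    rxn_smiles = reaction_smiles(rec),
    reactants = lapply(rec$reactants, function(sp) {
      out <- list(smiles = sp$smiles)
      if (!is.na(sp$moles)) out$moles <- sp$moles
      out
    }),
    agents = lapply(rec$agents, function(sp) {
      out <- list(smiles = sp$smiles)
      if (!is.na(sp$moles)) out$moles <- sp$moles
      out
    }),
    products = lapply(rec$products, function(sp) list(smiles = sp$smiles))
  )
  if (!is.na(rec$temperature_c)) obj$temperature_c <- rec$temperature_c
  if (!is.na(rec$class_id)) obj$class_id <- rec$class_id
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Write reaction records to a JSON-lines file
#'
#' @param records list of [reaction_record()]s.
#' @param path output file path.
#' @export
write_reactions_jsonl <- function(records, path) {
  lines <- vapply(records, .record_to_json, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read reaction records from a JSON-lines file
#'
#' One JSON object per line with fields `document_id`, `reactants`
#' (`[{smiles, moles}]`), `agents`, `products` (`[{smiles}]`),
#' `temperature_c`, `class_id`. SMILES are canonicalized on read.
#'
#' @param path input file path.
#' @param canonicalize canonicalize SMILES while reading (default TRUE).
#' @return list of [reaction_record()]s.
#' @export
read_reactions_jsonl <- function(path, canonicalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    reaction_record(
      document_id = obj$document_id,
      reactants = obj$reactants,
      agents = if (is.null(obj$agents)) list() else obj$agents,
      products = obj$products,
      temperature_c = if (is.null(obj$temperature_c)) NA_real_ else obj$temperature_c,
      class_id = if (is.null(obj$class_id)) NA_character_ else obj$class_id,
      canonicalize = canonicalize
    )
  })
}
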