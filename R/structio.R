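# Core structural data model and file I/O.
#
# A `agg_structure` stores one conformation as a flat atom table
# (data.frame) with 1-based contiguous residue numbering; the original PDB
# numbering is retained as metadata.  An `agg_ensemble` is an ordered list
# of conformations sharing one sequence, with normalized weights.

#' Construct an amino-acid sequence object
#'
#' @param x Character: either a single string of one-letter codes or a
#'   character vector of single letters.
#' @param id Text label.
#' @return An object of class `agg_sequence` with fields `id` and
#'   `residues` (character vector of one-letter codes).
#' @export
as_sequence <- function(x, id = "seq") {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  x <- toupper(x)
  if (length(x) == 0) format_error("empty sequence")
  bad <- which(!(x %in% AA1))
  if (length(bad) > 0) {
    format_error(sprintf(
      "non-canonical residue '%s' at position %d in sequence '%s'",
      x[bad[1]], bad[1], id))
  }
  structure(list(id = id, residues = x), class = "agg_sequence")
}

#' @export
print.agg_sequence <- function(x, ...) {
  cat(sprintf("<agg_sequence> %s (%d residues)\n%s\n",
              x$id, length(x$residues), paste(x$residues, collapse = "")))
  invisible(x)
}

#' @export
length.agg_sequence <- function(x) length(x$residues)

#' Read sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file, strips gaps/whitespace, normalises
#' case, and validates every residue against the canonical 20-letter
#' alphabet.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A list of [as_sequence()] objects, one per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  fa <- tryCatch(bio3d::read.fasta(path, rm.dup = FALSE),
                 error = function(e) format_error(
                   sprintf("cannot parse FASTA '%s': %s", path,
                           conditionMessage(e))))
  ali <- fa$ali
  if (is.null(dim(ali))) ali <- matrix(ali, nrow = 1)
  if (nrow(ali) == 0) format_error(sprintf("no records in '%s'", path))
  out <- vector("list", nrow(ali))
  for (i in seq_len(nrow(ali))) {
    res <- toupper(ali[i, ])
    res <- res[!(res %in% c("-", ".", " ", ""))]
    out[[i]] <- as_sequence(res, id = fa$id[i])
  }
  out
}

# Internal constructor: atoms is a data.frame with columns
# resno, resid, elety, element, x, y, z, occ, radius, orig_resno, chain.
new_structure <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "agg_structure")
}

#' @export
print.agg_structure <- function(x, ...) {
  cat(sprintf("<agg_structure> %s: %d atoms, %d residues\n",
              x$id, nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Per-residue summary of a structure
#'
#' @param structure An `agg_structure`.
#' @return Data frame with `resno`, `resid` (3-letter), `code` (1-letter,
#'   `NA` for non-standard residue names), and `complete` (logical: the
#'   backbone atoms N, CA, C, O are all present).
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  resno <- sort(unique(at$resno))
  resid <- vapply(resno, function(r) at$resid[at$resno == r][1], "")
  complete <- vapply(resno, function(r) {
    all(c("N", "CA", "C", "O") %in% at$elety[at$resno == r])
  }, TRUE)
  data.frame(resno = resno, resid = resid,
             code = unname(AA3_TO_1[resid]),
             complete = complete, stringsAsFactors = FALSE)
}

#' Extract the one-letter sequence of a structure
#'
#' @param structure An `agg_structure`.
#' @return An `agg_sequence`.  Non-standard residue names (e.g. MSE) are
#'   rejected rather than silently mapped.
#' @export
extract_sequence <- function(structure) {
  rt <- residue_table(structure)
  if (nrow(rt) == 0) input_error("structure has no residues")
  if (anyNA(rt$code)) {
    bad <- rt[is.na(rt$code), ][1, ]
    format_error(sprintf("non-standard residue %s at position %d",
                         bad$resid, bad$resno))
  }
  as_sequence(rt$code, id = structure$id)
}

#' Normalize ensemble weights
#'
#' @param w Non-negative numeric vector with positive sum.
#' @return `w / sum(w)`; idempotent.
#' @export
normalize_weights <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) {
    input_error("weights must be finite and non-negative")
  }
  s <- sum(w)
  if (s <= 0) input_error("weights sum to zero")
  w / s
}

#' Construct a conformational ensemble
#'
#' @param structures List of `agg_structure` sharing one residue
#'   composition.
#' @param weights Optional per-conformation weights (default uniform);
#'   normalized to sum to 1.
#' @param id Text label.
#' @return An object of class `agg_ensemble`.
#' @export
as_ensemble <- function(structures, weights = NULL, id = "ensemble") {
  if (length(structures) < 1) input_error("ensemble must have >= 1 conformation")
  seqs <- vapply(structures, function(s) {
    paste(residue_table(s)$resid, collapse = "-")
  }, "")
  if (length(unique(seqs)) != 1) {
    input_error("ensemble conformations differ in residue composition")
  }
  if (is.null(weights)) weights <- rep(1, length(structures))
  if (length(weights) != length(structures)) {
    input_error("one weight per conformation required")
  }
  structure(list(id = id, structures = structures,
                 weights = normalize_weights(weights)),
            class = "agg_ensemble")
}

#' @export
print.agg_ensemble <- function(x, ...) {
  cat(sprintf("<agg_ensemble> %s: %d conformations, %d residues\n",
              x$id, length(x$structures),
              length(unique(x$structures[[1]]$atoms$resno))))
  invisible(x)
}

#' @export
length.agg_ensemble <- function(x) length(x$structures)

guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    e[!nzchar(e)] <- NA
  } else {
    e <- rep(NA_character_, length(elety))
  }
  miss <- is.na(e)
  if (any(miss)) {
    nm <- gsub("[0-9']", "", toupper(elety[miss]))
    e[miss] <- substr(nm, 1, 1)
  }
  e
}

#' Read a structure or ensemble from a PDB file
#'
#' Parses a fixed-column PDB file (via bio3d), keeping protein `ATOM`
#' records only (HETATM and waters are dropped).  Alternate locations are
#' resolved to the highest occupancy (ties broken by file order).
#' Residues are renumbered 1-based and contiguous; the original author
#' numbering is kept in the `orig_resno` column.  Multi-MODEL files become
#' an ensemble with uniform weights.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"all"` (every MODEL, the default) or `"first"`.
#' @param chain Chain identifier to keep; default the first chain present.
#' @param id Label for the returned object (default: file base name).
#' @return An `agg_ensemble` (of size 1 for single-model files).
#' @export
read_pdb <- function(path, model_policy = c("all", "first"), chain = NULL,
                     id = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) format_error(
      sprintf("cannot parse PDB '%s': %s", path, conditionMessage(e))))
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(keep)) format_error(sprintf("no protein ATOM records in '%s'", path))
  if (is.null(chain)) chain <- at$chain[keep][1]
  keep <- keep & (at$chain %in% chain | is.na(at$chain))
  if (!any(keep)) input_error(sprintf("chain '%s' not found in '%s'",
                                      chain, path))
  idx <- which(keep)

  # altloc: within each (residue, atom name) group keep highest occupancy,
  # ties resolved by file order
  alt <- at$alt[idx]
  alt[is.na(alt)] <- ""
  occ <- at$o[idx]
  occ[is.na(occ)] <- 1
  grp <- paste(at$chain[idx], at$resno[idx], at$insert[idx], at$elety[idx],
               sep = "|")
  ord <- order(grp, -occ, seq_along(idx))
  first_in_grp <- !duplicated(grp[ord])
  sel <- sort(idx[ord][first_in_grp])

  elety <- at$elety[sel]
  element <- guess_element(elety, at$elesy[sel])

  # drop hydrogens/deuteriums at read time? keep them; SASA excludes by flag
  resid <- at$resid[sel]
  orig_resno <- at$resno[sel]
  # 1-based contiguous renumbering in order of appearance
  key <- paste(at$chain[sel], orig_resno, at$insert[sel], sep = "|")
  resno <- as.integer(factor(key, levels = unique(key)))

  radius <- unname(ELEMENT_RADII[element])
  if (anyNA(radius)) {
    bad <- unique(element[is.na(radius)])
    format_error(sprintf("no van der Waals radius for element(s): %s",
                         paste(bad, collapse = ", ")))
  }

  base_atoms <- data.frame(
    resno = resno, resid = resid, elety = elety, element = element,
    x = 0, y = 0, z = 0, occ = occ[match(sel, idx)], radius = radius,
    orig_resno = orig_resno, chain = at$chain[sel],
    stringsAsFactors = FALSE)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmodel <- nrow(xyz)
  if (model_policy == "first") nmodel <- 1L
  cols <- bio3d::atom2xyz(sel)
  structures <- vector("list", nmodel)
  for (m in seq_len(nmodel)) {
    atm <- base_atoms
    co <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
    atm$x <- co[, 1]; atm$y <- co[, 2]; atm$z <- co[, 3]
    if (any(!is.finite(co))) format_error(
      sprintf("non-finite coordinates in model %d of '%s'", m, path))
    structures[[m]] <- new_structure(atm, id = sprintf("%s#%d", id, m))
  }
  as_ensemble(structures, id = id)
}

#' Write a structure or ensemble as a (multi-MODEL) PDB file
#'
#' @param x An `agg_structure` or `agg_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "agg_structure")) x <- as_ensemble(list(x), id = x$id)
  if (!inherits(x, "agg_ensemble")) input_error("expected structure or ensemble")
  con <- tryCatch(file(path, "w"),
                  error = function(e) input_error(
                    sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  multi <- length(x$structures) > 1
  serial_fmt <- function(at, i) {
    name <- at$elety[i]
    name <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name, at$resid[i],
            ifelse(is.na(at$chain[i]), "A", at$chain[i]),
            at$orig_resno[i], at$x[i], at$y[i], at$z[i],
            at$occ[i], 0, at$element[i])
  }
  for (m in seq_along(x$structures)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    at <- x$structures[[m]]$atoms
    writeLines(vapply(seq_len(nrow(at)), function(i) serial_fmt(at, i), ""),
               con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a per-residue profile as a TSV table
#'
#' Columns `index`, `code`, `score`; values survive a read-back round trip
#' to at least 1e-6.
#'
#' @param profile An `agg_profile` (see [intrinsic_profile()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  if (!inherits(profile, "agg_profile")) input_error("expected an agg_profile")
  if (length(profile$values) == 0) input_error("empty profile")
  df <- data.frame(index = seq_along(profile$values),
                   code = profile$sequence$residues,
                   score = sprintf("%.9g", profile$values))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) input_error(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Read a profile table written by [write_profile_table()]
#'
#' @param path TSV path with columns `index`, `code`, `score`.
#' @return Data frame with numeric `index`/`score` and character `code`.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("index", "code", "score") %in% names(df))) {
    format_error(sprintf("'%s' lacks index/code/score columns", path))
  }
  df
}

#' Read per-conformation weights from a TSV/plain file
#'
#' One non-negative weight per line, order-matched to the ensemble's
#' conformations; normalized to sum to 1.
#'
#' @param path File path.
#' @param n Expected number of weights (optional check).
#' @return Normalized numeric vector.
#' @export
read_weights <- function(path, n = NULL) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  w <- utils::read.table(path, header = FALSE)[[1]]
  if (!is.numeric(w)) format_error("weights file must be numeric")
  if (!is.null(n) && length(w) != n) {
    input_error(sprintf("expected %d weights, found %d", n, length(w)))
  }
  normalize_weights(w)
}

# Cartesian coordinate matrix (n_atoms x 3) of a structure, optionally
# restricted to an atom-name set.
coords_of <- function(structure, elety = NULL) {
  at <- structure$atoms
  if (!is.null(elety)) at <- at[at$elety %in% elety, ]
  as.matrix(at[, c("x", "y", "z")])
}

# Named coordinate lookup for a single (resno, atom-name); NULL if absent.
atom_coord <- function(structure, resno, elety) {
  at <- structure$atoms
  i <- which(at$resno == resno & at$elety == elety)
  if (length(i) == 0) return(NULL)
  c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
}
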