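# PDB complex parsing and residue-environment extraction.
#
# File parsing is delegated to bio3d::read.pdb; this module layers the
# conventions the predictor needs on top: altloc resolution by occupancy,
# removal of hydrogens and waters, per-residue molecule-kind assignment
# (protein / nucleic acid / other) and validation that the structure is a
# genuine protein-nucleic acid complex.

#' Parse a protein-nucleic acid complex from PDB text or file
#'
#' Reads ATOM/HETATM records, drops hydrogens and waters, resolves
#' alternate locations to the highest-occupancy conformer (ties broken by
#' the alphabetically first altloc id) and classifies every residue as
#' protein, nucleic acid or other. Non-standard (HETATM) residues are kept
#' in the atom table with kind `"other"` but are excluded from signature
#' computation downstream; each excluded residue is reported via a message.
#' Multi-model files are truncated to the first model with a warning.
#'
#' @param x path to a PDB file, or a character scalar/vector of PDB text.
#' @param na_type declared nucleic-acid type: `"RNA"`, `"ssDNA"` or
#'   `"dsDNA"`. Never inferred from the coordinates.
#' @param source_id identifier stored on the result; defaults to the file
#'   name (or `"inline"` for text input).
#' @return an object of class `na_complex`: a list with elements `atoms`
#'   (data frame, one row per retained heavy atom: `elety`, `element`,
#'   `x`, `y`, `z`, `resid`, `resno`, `insert`, `chain`, `kind`, `o`,
#'   `alt`), `chains` (named character vector chain id -> kind),
#'   `na_type` and `source_id`.
#' @export
parse_complex <- function(x, na_type = c("dsDNA", "ssDNA", "RNA"),
                          source_id = NULL) {
  na_type <- match.arg(na_type)
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    source_id <- source_id %||% sub("\\.(pdb|ent)$", "", basename(x))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    source_id <- source_id %||% "inline"
  }
  validate_pdb_lines(lines)

  n_models <- sum(startsWith(lines, "MODEL "))
  if (n_models > 1)
    warnf("multi-model file: using MODEL 1 of %d (%s)", n_models, source_id)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom

  element <- toupper(trimws(at$elesy %||% ""))
  miss <- is.na(element) | element == ""
  element[miss] <- infer_element(at$elety[miss])

  keep <- !(element %in% c("H", "D")) & !(toupper(at$resid) %in% WATER_RESIDUES)
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  if (nrow(at) == 0) stopf("no heavy atoms found in '%s'", source_id)

  atoms <- data.frame(
    elety = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    resid = toupper(trimws(at$resid)),
    resno = at$resno,
    insert = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    o = ifelse(is.na(at$o), 1.0, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    rectype = at$type,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in '%s'", source_id)

  atoms <- resolve_altloc(atoms)
  atoms$kind <- residue_kind(atoms$resid)

  het_other <- unique(paste0(atoms$chain, ":", atoms$resid, atoms$resno)[
    atoms$kind == "other"])
  if (length(het_other) > 0)
    message(sprintf("parse_complex(%s): %d non-standard residue(s) excluded from signatures: %s",
                    source_id, length(het_other),
                    paste(utils::head(het_other, 8), collapse = ", ")))

  chains <- vapply(split(atoms$kind, atoms$chain), function(k) {
    if (any(k == "protein")) "protein"
    else if (any(k == "nucleic_acid")) "nucleic_acid"
    else "other"
  }, character(1))

  if (!any(chains == "protein"))
    stopf("structure '%s' rejected: no protein chain", source_id)
  if (!any(chains == "nucleic_acid"))
    stopf("structure '%s' rejected: no nucleic-acid chain", source_id)

  ord <- order(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL

  structure(list(atoms = atoms, chains = chains, na_type = na_type,
                 source_id = source_id),
            class = "na_complex")
}

# fixed-column sanity scan so malformed records are reported by line number
validate_pdb_lines <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stopf("unparseable ATOM/HETATM record at line %d: record too short", i)
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stopf("unparseable ATOM/HETATM record at line %d: bad coordinate field", i)
  }
  if (length(idx) == 0) stopf("no ATOM/HETATM records found")
  invisible(TRUE)
}

# keep, per residue with alternate locations, the altloc id of highest
# occupancy (summed over the residue's alt atoms; ties -> first id)
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[atoms$alt != ""])) {
    sel <- which(key == k & atoms$alt != "")
    occ <- tapply(atoms$o[sel], atoms$alt[sel], mean)
    best <- names(occ)[order(-occ, names(occ))][1]
    keep[sel[atoms$alt[sel] != best]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

residue_kind <- function(resid) {
  ifelse(resid %in% names(AA3TO1), "protein",
         ifelse(resid %in% NA_RESIDUES, "nucleic_acid", "other"))
}

#' Parse or format a mutation specification
#'
#' The string form is wild-type one-letter code, author residue number, an
#' optional insertion code, then the mutant one-letter code (e.g. `"R273C"`,
#' `"T100AG"` for residue 100 insertion A).
#'
#' @param x mutation string.
#' @param chain chain identifier.
#' @return `mutation_spec`: list with `chain`, `resno`, `insert`, `wt`, `mut`.
#' @examples
#' mutation_spec("R273C", "A")
#' @export
mutation_spec <- function(x, chain) {
  if (inherits(x, "na_mutation")) return(x)
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z]?)([A-Za-z])$", x))[[1]]
  if (length(m) == 0)
    stopf("cannot parse mutation string '%s' (expected e.g. 'R273C')", x)
  wt <- toupper(m[2]); mut <- toupper(m[5])
  if (!wt %in% AA1 || !mut %in% AA1)
    stopf("mutation '%s': residue letters must be standard amino acids", x)
  if (wt == mut)
    stopf("mutation '%s': wild-type and mutant residues are identical", x)
  structure(list(chain = as.character(chain), resno = as.integer(m[3]),
                 insert = toupper(m[4]), wt = wt, mut = mut),
            class = "na_mutation")
}

#' @rdname mutation_spec
#' @param m a `mutation_spec`.
#' @export
format_mutation <- function(m) {
  paste0(m$wt, m$resno, m$insert, m$mut)
}

#' Locate the mutated residue in a parsed complex
#'
#' Finds the residue with the spec's chain, author residue number and
#' insertion code, and verifies the observed residue type matches the
#' declared wild type.
#'
#' @param cx an `na_complex`.
#' @param m a `mutation_spec` (or mutation string, with `chain`).
#' @param chain chain id when `m` is given as a string.
#' @return a residue handle: list with `chain`, `resno`, `insert`, `resid`,
#'   `aa` (one-letter) and `atom_idx` (row indices into `cx$atoms`).
#' @export
locate_residue <- function(cx, m, chain = NULL) {
  stopifnot(inherits(cx, "na_complex"))
  if (is.character(m)) m <- mutation_spec(m, chain)
  at <- cx$atoms
  sel <- which(at$chain == m$chain & at$resno == m$resno & at$insert == m$insert)
  if (length(sel) == 0)
    stopf("residue %s%d%s not found in chain %s of '%s'",
          m$wt, m$resno, m$insert, m$chain, cx$source_id)
  resid <- unique(at$resid[sel])
  if (length(resid) > 1)
    stopf("ambiguous residue identity at %s:%d%s", m$chain, m$resno, m$insert)
  obs <- aa_three_to_one(resid)
  if (is.na(obs))
    stopf("residue at %s:%d%s is %s, not a standard amino acid",
          m$chain, m$resno, m$insert, resid)
  if (obs != m$wt)
    stopf("wild-type mismatch at %s:%d%s: structure has %s (%s), spec says %s",
          m$chain, m$resno, m$insert, resid, obs, m$wt)
  structure(list(chain = m$chain, resno = m$resno, insert = m$insert,
                 resid = resid, aa = obs, atom_idx = sel),
            class = "na_residue")
}

#' Extract the structural environment of a mutation site
#'
#' Returns every protein and nucleic-acid heavy atom lying within `radius`
#' of any atom of the mutated residue (the residue's own atoms included),
#' in deterministic order (chain, residue number, insertion code, atom
#' name). Residues of kind "other" never enter the environment.
#'
#' @param cx an `na_complex`.
#' @param m a `mutation_spec` or a residue handle from [locate_residue()].
#' @param radius cutoff radius in Angstrom (> 0); default 10.
#' @return data frame of atom rows (same columns as `cx$atoms`).
#' @export
extract_environment <- function(cx, m, radius = 10.0) {
  stopifnot(inherits(cx, "na_complex"))
  if (!is.finite(radius) && radius > 0) radius <- Inf
  if (radius <= 0) stopf("radius must be > 0 (got %g)", radius)
  res <- if (inherits(m, "na_residue")) m else locate_residue(cx, m)
  at <- cx$atoms
  cand <- which(at$kind %in% c("protein", "nucleic_acid"))
  ref <- as.matrix(at[res$atom_idx, c("x", "y", "z")])
  xyz <- as.matrix(at[cand, c("x", "y", "z")])
  # min distance from each candidate to the residue's atoms
  mind <- rep(Inf, length(cand))
  for (i in seq_len(nrow(ref))) {
    d2 <- (xyz[, 1] - ref[i, 1])^2 + (xyz[, 2] - ref[i, 2])^2 +
      (xyz[, 3] - ref[i, 3])^2
    mind <- pmin(mind, d2)
  }
  sel <- cand[sqrt(mind) <= radius]
  if (length(sel) == 0) stopf("empty environment at radius %g", radius)
  env <- at[sel, , drop = FALSE]
  env <- env[order(env$chain, env$resno, env$insert, env$elety), , drop = FALSE]
  rownames(env) <- NULL
  env
}

#' @export
print.na_complex <- function(x, ...) {
  cat(sprintf("<na_complex '%s'> %d atoms, %s\n", x$source_id,
              nrow(x$atoms), x$na_type))
  for (ch in names(x$chains))
    cat(sprintf("  chain %s: %s (%d atoms)\n", ch, x$chains[ch],
                sum(x$atoms$chain == ch)))
  invisible(x)
}

#' Serialize a complex back to PDB text
#'
#' Writes the retained heavy atoms in fixed-column PDB format; useful for
#' round-trip checks and for emitting synthetic fixtures.
#'
#' @param cx an `na_complex`.
#' @param path optional output file; when `NULL` the text is returned.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_complex <- function(cx, path = NULL) {
  at <- cx$atoms
  rec <- ifelse(at$kind == "other", "HETATM", "ATOM  ")
  name4 <- vapply(at$elety, function(a)
    if (nchar(a) >= 4) substr(a, 1, 4) else sprintf(" %-3s", a), character(1))
  lines <- sprintf("%s%5d %s%s%-3s%2s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(at)), name4, " ", at$resid,
                   substr(paste0(at$chain, " "), 1, 1),
                   at$resno, substr(paste0(at$insert, " "), 1, 1),
                   at$x, at$y, at$z, at$o, 0, at$element)
  lines <- c(lines, "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
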