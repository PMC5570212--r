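# Pharmacophore atom typing.
#
# Protein atoms carry a set of coarse physicochemical classes (an atom may
# be, e.g., both positively charged and a hydrogen-bond donor) plus a
# single "primary" class used for per-residue composition counts. The
# assignments live in a versioned plain-text table under extdata so the
# typing itself is inspectable and replaceable. Nucleic-acid atoms are
# typed by rule under one of two schemes: by chemical group
# (phosphate / sugar / base, the default) or by base family
# (purine / pyrimidine).

PROTEIN_CLASSES <- c("hydrophobic", "aromatic", "positive", "negative",
                     "hb_donor", "hb_acceptor", "donor_acceptor",
                     "sulfur", "neutral")

NA_CLASSES <- list(NUC_GROUP = c("na_phosphate", "na_sugar", "na_base"),
                   NUC_BASE  = c("na_purine", "na_pyrimidine"))

pharm_env <- new.env(parent = emptyenv())

#' The protein pharmacophore lookup table
#'
#' Reads (and caches) the shipped atom-typing table: one row per canonical
#' heavy atom of each standard residue, with its full class set and its
#' primary class. Charged groups carry their formal charge once, on the
#' group's central atom, as the primary class; the group's terminal N/O
#' atoms keep the charge class in their class set (so signatures see them
#' as charged) but count as donors/acceptors in residue compositions.
#'
#' @param path optional alternative table (TSV: residue, atom, classes,
#'   primary; classes comma-separated).
#' @return data frame with columns `residue`, `atom`, `classes`, `primary`.
#' @export
pharmacophore_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(pharm_env$table)) return(pharm_env$table)
    path <- system.file("extdata", "protein_pharmacophore.tsv",
                        package = "nabind")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    validate_pharm_table(tab)
    pharm_env$table <- tab
    pharm_env$set_lookup <- make_pharm_lookup(tab)
    return(tab)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_pharm_table(tab)
  tab
}

validate_pharm_table <- function(tab) {
  need <- c("residue", "atom", "classes", "primary")
  if (!all(need %in% names(tab)))
    stopf("pharmacophore table must have columns %s", paste(need, collapse = ", "))
  cls <- unlist(strsplit(tab$classes, ","))
  bad <- setdiff(unique(c(cls, tab$primary)), PROTEIN_CLASSES)
  if (length(bad) > 0)
    stopf("pharmacophore table contains unknown classes: %s",
          paste(bad, collapse = ", "))
  invisible(tab)
}

make_pharm_lookup <- function(tab) {
  key <- paste(tab$residue, tab$atom, sep = "|")
  sets <- strsplit(tab$classes, ",", fixed = TRUE)
  names(sets) <- key
  pri <- structure(tab$primary, names = key)
  list(sets = sets, primary = pri)
}

pharm_lookup <- function() {
  if (is.null(pharm_env$set_lookup)) pharmacophore_table()
  pharm_env$set_lookup
}

#' Pharmacophore classes of one protein atom
#'
#' @param residue_name three-letter residue code.
#' @param atom_name PDB atom name (e.g. `"NH1"`).
#' @return character vector of classes; unknown atoms fall back to
#'   `"neutral"` with a warning (terminal OXT is treated as a carboxylate
#'   oxygen).
#' @examples
#' label_protein_atom("ARG", "NH1")
#' @export
label_protein_atom <- function(residue_name, atom_name) {
  residue_name <- toupper(residue_name)
  atom_name <- toupper(trimws(atom_name))
  if (atom_name == "OXT") return(c("negative", "hb_acceptor"))
  lk <- pharm_lookup()
  out <- lk$sets[[paste(residue_name, atom_name, sep = "|")]]
  if (is.null(out)) {
    warnf("unknown protein atom %s:%s typed as neutral",
          residue_name, atom_name)
    out <- "neutral"
  }
  out
}

#' Pharmacophore class of one nucleic-acid atom
#'
#' Under `NUC_GROUP` the nucleotide is divided into phosphate (P, the
#' phosphate oxygens including terminal OP3 and the bridging O5'/O3'),
#' sugar (the primed carbons, O4' and the RNA O2') and base (all remaining
#' ring atoms and exocyclic substituents). Under `NUC_BASE` every atom of
#' the nucleotide is labelled by its base family, purine or pyrimidine.
#' Legacy `*`-primed atom names and O1P/O2P/O3P spellings are accepted.
#'
#' @param residue_name nucleotide residue code (A, C, G, U, T, DA, DC, DG,
#'   DT).
#' @param atom_name PDB atom name.
#' @param scheme `"NUC_GROUP"` (default) or `"NUC_BASE"`.
#' @return a single class label.
#' @examples
#' label_na_atom("DG", "P")               # phosphate
#' label_na_atom("DG", "N9", "NUC_BASE")  # purine
#' @export
label_na_atom <- function(residue_name, atom_name,
                          scheme = c("NUC_GROUP", "NUC_BASE")) {
  scheme <- match.arg(scheme)
  residue_name <- toupper(residue_name)
  if (!residue_name %in% NA_RESIDUES)
    stopf("unknown nucleotide residue '%s'", residue_name)
  atom_name <- toupper(trimws(atom_name))
  atom_name <- gsub("*", "'", atom_name, fixed = TRUE)
  if (scheme == "NUC_BASE") {
    return(if (residue_name %in% NA_PURINES) "na_purine" else "na_pyrimidine")
  }
  phosphate <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P", "O5'", "O3'")
  sugar <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'")
  if (atom_name %in% phosphate) "na_phosphate"
  else if (atom_name %in% sugar) "na_sugar"
  else "na_base"
}

#' Per-residue pharmacophore composition
#'
#' Counts, for the canonical heavy-atom composition of a residue type
#' (structure independent), how many atoms carry each class as their
#' primary class. The counts therefore sum to the residue's heavy-atom
#' count, and a charged residue contributes exactly one count to its
#' charge class.
#'
#' @param aa one-letter amino-acid code.
#' @return named integer vector over all protein classes.
#' @examples
#' residue_pharmacophore_counts("R")["positive"]
#' @export
residue_pharmacophore_counts <- function(aa) {
  aa <- toupper(aa)
  if (!aa %in% AA1) stopf("not a standard amino acid letter: '%s'", aa)
  tab <- pharmacophore_table()
  sub <- tab[tab$residue == AA3[[aa]], ]
  counts <- integer(length(PROTEIN_CLASSES))
  names(counts) <- PROTEIN_CLASSES
  tb <- table(sub$primary)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Pharmacophore change vector of a mutation
#'
#' Difference in per-residue pharmacophore composition, mutant minus wild
#' type. Anti-symmetric by construction: swapping the residues negates the
#' vector. This is the mutation encoding appended to the structural
#' signature.
#'
#' @param wt,mut one-letter amino-acid codes, distinct.
#' @return named integer vector (signed) over all protein classes.
#' @examples
#' pharmacophore_change("D", "K")[c("negative", "positive")]
#' @export
pharmacophore_change <- function(wt, mut) {
  if (toupper(wt) == toupper(mut))
    stopf("wild-type and mutant residues are identical ('%s')", wt)
  residue_pharmacophore_counts(mut) - residue_pharmacophore_counts(wt)
}

# class sets for an atom table (list column), honoring kind and scheme
atom_class_sets <- function(atoms, scheme = "NUC_GROUP",
                            multiclass = TRUE) {
  lk <- pharm_lookup()
  n <- nrow(atoms)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (atoms$kind[i] == "protein") {
      if (multiclass) {
        out[[i]] <- label_protein_atom_quiet(atoms$resid[i], atoms$elety[i], lk)
      } else {
        key <- paste(toupper(atoms$resid[i]), toupper(trimws(atoms$elety[i])),
                     sep = "|")
        pri <- unname(lk$primary[key])
        out[[i]] <- if (is.na(pri)) "neutral" else pri
      }
    } else if (atoms$kind[i] == "nucleic_acid") {
      out[[i]] <- label_na_atom(atoms$resid[i], atoms$elety[i], scheme)
    } else {
      out[[i]] <- character(0)
    }
  }
  out
}

# as label_protein_atom but collecting unknown atoms silently (the caller
# reports once per run instead of once per atom)
label_protein_atom_quiet <- function(residue_name, atom_name, lk) {
  atom_name <- toupper(trimws(atom_name))
  if (atom_name == "OXT") return(c("negative", "hb_acceptor"))
  out <- lk$sets[[paste(toupper(residue_name), atom_name, sep = "|")]]
  if (is.null(out)) out <- "neutral"
  out
}
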