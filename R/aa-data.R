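# Canonical amino-acid and nucleotide reference data.
#
# Heavy-atom compositions follow PDB v3 atom nomenclature. Scalar residue
# properties used by the baseline stability heuristic: Kyte-Doolittle
# hydropathy and Zamyatnin residue volumes. Maximum accessible surface
# areas are the theoretical per-residue maxima of Tien et al. (2013),
# shipped as a plain-text table in extdata so alternative normalisations
# can be swapped in.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
         G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
         P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL")

AA3TO1 <- structure(names(AA3), names = unname(AA3))

# Kyte-Doolittle hydropathy index
AA_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Zamyatnin (1972) residue volumes, cubic Angstrom
AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# canonical side-chain heavy atoms (backbone N/CA/C/O shared by all)
AA_SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB","CG","CD","NE","CZ","NH1","NH2"),
  ASN = c("CB","CG","OD1","ND2"),
  ASP = c("CB","CG","OD1","OD2"),
  CYS = c("CB","SG"),
  GLN = c("CB","CG","CD","OE1","NE2"),
  GLU = c("CB","CG","CD","OE1","OE2"),
  GLY = character(0),
  HIS = c("CB","CG","ND1","CD2","CE1","NE2"),
  ILE = c("CB","CG1","CG2","CD1"),
  LEU = c("CB","CG","CD1","CD2"),
  LYS = c("CB","CG","CD","CE","NZ"),
  MET = c("CB","CG","SD","CE"),
  PHE = c("CB","CG","CD1","CD2","CE1","CE2","CZ"),
  PRO = c("CB","CG","CD"),
  SER = c("CB","OG"),
  THR = c("CB","OG1","CG2"),
  TRP = c("CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
  TYR = c("CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
  VAL = c("CB","CG1","CG2")
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# standard nucleotide residue names (PDB v3 plus legacy single-letter deoxy)
NA_RESIDUES <- c("A","C","G","U","T","DA","DC","DG","DT")
NA_PURINES <- c("A","G","DA","DG")
NA_PYRIMIDINES <- c("C","U","T","DC","DT")

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

# van der Waals radii by element (Bondi), Angstrom; fallback 1.70
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

#' One-letter/three-letter amino-acid code conversion
#'
#' @param x character vector of residue codes.
#' @return converted codes; `NA` for non-standard input.
#' @examples
#' aa_three_to_one("ARG")
#' aa_one_to_three("R")
#' @export
aa_three_to_one <- function(x) unname(AA3TO1[toupper(x)])

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) unname(AA3[toupper(x)])

#' Canonical heavy atoms of a residue type
#'
#' Backbone N, CA, C, O plus the side-chain heavy atoms in PDB v3
#' nomenclature.
#'
#' @param aa3 three-letter residue code.
#' @return character vector of atom names.
#' @export
residue_heavy_atoms <- function(aa3) {
  aa3 <- toupper(aa3)
  if (!aa3 %in% names(AA_SIDECHAIN_ATOMS))
    stopf("not a standard amino acid: '%s'", aa3)
  c(BACKBONE_ATOMS, AA_SIDECHAIN_ATOMS[[aa3]])
}

# element symbol from a PDB atom name when the element column is absent
infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA"), two, one)
}

max_asa_table_env <- new.env(parent = emptyenv())

#' Maximum accessible surface area per residue type
#'
#' Reads the shipped normalisation table (theoretical maxima, square
#' Angstrom) used to convert absolute residue ASA to relative solvent
#' accessibility.
#'
#' @param path optional path to an alternative table (TSV: residue, max_asa).
#' @return named numeric vector keyed by three-letter residue code.
#' @export
max_asa_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(max_asa_table_env$default)) return(max_asa_table_env$default)
    path <- system.file("extdata", "max_asa.tsv", package = "nabind")
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    out <- structure(tab$max_asa, names = toupper(tab$residue))
    max_asa_table_env$default <- out
    return(out)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(tab$max_asa, names = toupper(tab$residue))
}
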