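# shared fixtures and independent oracles

# minimal hand-written PDB: one ALA on chain A, one DG on chain B
toy_pdb <- function(drop_na = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  P   DG  B   1       6.000   0.000   0.000  1.00  0.00           P",
    "ATOM      7  C1' DG  B   1       7.500   1.000   0.000  1.00  0.00           C",
    "ATOM      8  N9  DG  B   1       8.200   2.100   0.500  1.00  0.00           N",
    "END")
  if (drop_na) lines <- lines[1:5]
  paste(lines, collapse = "\n")
}

# random labelled atom cloud for signature oracles
random_atom_cloud <- function(n, seed, classes = c("hydrophobic", "positive",
                                                   "negative", "hb_donor",
                                                   "na_phosphate", "na_base"),
                              box = 10, max_classes = 2) {
  withr::with_seed(seed, {
    atoms <- data.frame(x = runif(n, 0, box), y = runif(n, 0, box),
                        z = runif(n, 0, box))
    labels <- lapply(seq_len(n), function(i)
      sample(classes, sample(max_classes, 1)))
    list(atoms = atoms, labels = labels)
  })
}

# brute-force cutoff scan: triple loop over atom pairs, class pairs, cutoffs
bf_cutoff_scan <- function(atoms, labels, schedule, scheme = "NUC_GROUP") {
  cls <- c(nabind:::PROTEIN_CLASSES, nabind:::NA_CLASSES[[scheme]])
  cuts <- schedule$cutoffs
  pairs <- expand.grid(ia = seq_along(cls), ib = seq_along(cls))
  pairs <- pairs[pairs$ia <= pairs$ib, ]
  key <- paste0(cls[pairs$ia], "|", cls[pairs$ib])
  out <- matrix(0, nrow(pairs), length(cuts),
                dimnames = list(key, format(cuts, trim = TRUE)))
  n <- nrow(atoms)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((atoms[i, c("x", "y", "z")] - atoms[j, c("x", "y", "z")])^2))
      seen <- character(0)
      for (ci in labels[[i]]) for (cj in labels[[j]]) {
        ab <- sort(c(match(ci, cls), match(cj, cls)))
        k <- paste0(cls[ab[1]], "|", cls[ab[2]])
        if (k %in% seen) next
        seen <- c(seen, k)
        out[k, ] <- out[k, ] + as.numeric(d <= cuts + 1e-9)
      }
    }
  }
  out
}

# rigid-body transform of an atom table
rigid_transform <- function(atoms, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  R <- c_ * diag(3) + s_ * rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]),
                                 c(-u[2], u[1], 0)) +
    (1 - c_) * (u %o% u)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# parsed helix fixture shared across files
helix_complex <- function(seed = 7, ...) {
  spec <- fixture_spec(seed = seed, ...)
  parse_complex(paste(generate_complex(spec), collapse = "\n"),
                na_type = spec$na_type)
}

# independently tabulated heavy-atom counts per residue type
HEAVY_ATOM_COUNTS <- c(A = 5, R = 11, N = 8, D = 8, C = 6, Q = 9, E = 9,
                       G = 4, H = 10, I = 8, L = 8, K = 9, M = 8, F = 11,
                       P = 7, S = 6, T = 7, W = 14, Y = 12, V = 7)
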