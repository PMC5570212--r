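# Synthetic fixture generators.
#
# Everything the test-suite and the worked examples need is generated in
# code: toy protein-nucleic acid complexes with controlled geometry
# (idealised, not biophysically realistic — they exercise code paths and
# oracles), feature-level datasets with a planted linear signal, a
# structure-level dataset whose ddG is a planted function of the real
# featurizer's outputs, and a synthetic affinity table emulating the
# composition of the curated training data.

#' Specification of a synthetic complex
#'
#' @param seed integer; the same spec and seed give byte-identical PDB
#'   output.
#' @param n_protein_residues,n_na_residues chain lengths.
#' @param na_type declared nucleic-acid type.
#' @param geometry `"helix_ladder"` (protein helix facing a straight
#'   nucleic-acid ladder), `"random_cloud"` (two adjacent random blobs) or
#'   `"cage"` (a target residue sealed inside a dense atom shell, for
#'   burial tests).
#' @param contact_distance Angstrom; in `helix_ladder` the designated
#'   interface residue's nearest atom sits exactly this far from the
#'   nearest nucleic-acid atom, and no atom pair is closer.
#' @param interface_aa one-letter type of the designated residue (the
#'   last protein residue in `helix_ladder`, the first in `cage`).
#' @param residue_types optional one-letter vector fixing every protein
#'   residue type.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_protein_residues = 12,
                         n_na_residues = 6,
                         na_type = c("dsDNA", "ssDNA", "RNA"),
                         geometry = c("helix_ladder", "random_cloud", "cage"),
                         contact_distance = 3.5,
                         interface_aa = "R",
                         residue_types = NULL) {
  na_type <- match.arg(na_type)
  geometry <- match.arg(geometry)
  if (contact_distance <= 0) stopf("contact_distance must be > 0")
  if (n_protein_residues < 1 || n_na_residues < 1)
    stopf("need at least one residue per chain")
  structure(list(seed = seed, n_protein_residues = n_protein_residues,
                 n_na_residues = n_na_residues, na_type = na_type,
                 geometry = geometry, contact_distance = contact_distance,
                 interface_aa = toupper(interface_aa),
                 residue_types = residue_types),
            class = "fixture_spec")
}

PURINE_BASE_ATOMS <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
PYRIMIDINE_BASE_ATOMS <- c("N1", "C2", "O2", "N3", "C4", "C5", "C6")

nucleotide_atoms <- function(resid) {
  sugar_phos <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                  "O3'", "C2'", "C1'")
  if (resid %in% c("A", "C", "G", "U")) sugar_phos <- c(sugar_phos, "O2'")
  base <- if (resid %in% NA_PURINES) PURINE_BASE_ATOMS else PYRIMIDINE_BASE_ATOMS
  c(sugar_phos, base)
}

# one residue's atoms jittered around a centre, x-extent clamped
residue_atom_block <- function(atom_names, resid, resno, chain, center,
                               jitter = 1.1, xmax = NULL, xmin = NULL) {
  n <- length(atom_names)
  off <- matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  xyz <- sweep(off, 2, center, "+")
  if (!is.null(xmax)) xyz[, 1] <- pmin(xyz[, 1], xmax)
  if (!is.null(xmin)) xyz[, 1] <- pmax(xyz[, 1], xmin)
  data.frame(elety = atom_names, element = infer_element(atom_names),
             x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
             z = round(xyz[, 3], 3),
             resid = resid, resno = resno, insert = "", chain = chain,
             o = 1, alt = "", stringsAsFactors = FALSE)
}

#' Generate a synthetic protein-nucleic acid complex
#'
#' Emits well-formed fixed-column PDB text with one protein chain (A) and
#' one nucleic-acid chain (B; dsDNA adds chain C) that parses with
#' [parse_complex()]. All coordinates are reproducible from the spec's
#' seed.
#'
#' @param spec a [fixture_spec()].
#' @return character vector of PDB lines.
#' @export
generate_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, generate_complex_impl(spec))
}

generate_complex_impl <- function(spec) {
  np <- spec$n_protein_residues
  nn <- spec$n_na_residues
  dc <- spec$contact_distance

  prot_types <- spec$residue_types %||% sample(AA1, np, replace = TRUE)
  prot_types <- toupper(prot_types)
  na_pool <- if (spec$na_type == "RNA") c("A", "C", "G", "U")
             else c("DA", "DC", "DG", "DT")
  na_types <- sample(na_pool, nn, replace = TRUE)

  blocks <- list()
  if (spec$geometry == "helix_ladder") {
    prot_types[np] <- spec$interface_aa
    # protein helix along -x; every atom stays at x <= -0.2 except the
    # designated contact atom placed exactly at the origin
    for (i in seq_len(np)) {
      ang <- 100 * pi / 180 * i
      ctr <- c(-2.6 - 1.5 * (np - i), 2.3 * cos(ang), 2.3 * sin(ang))
      blocks[[i]] <- residue_atom_block(
        residue_heavy_atoms(AA3[[prot_types[i]]]), AA3[[prot_types[i]]],
        i, "A", ctr, xmax = -0.2)
    }
    iface <- blocks[[np]]
    last <- nrow(iface)
    iface[last, c("x", "y", "z")] <- c(0, 0, 0)
    blocks[[np]] <- iface
    # nucleic ladder along z at x >= dc; nearest atom exactly at (dc, 0, 0)
    for (j in seq_len(nn)) {
      ctr <- c(dc + 2.2, 0, 3.4 * (j - (nn + 1) / 2))
      b <- residue_atom_block(nucleotide_atoms(na_types[j]), na_types[j],
                              j, "B", ctr, xmin = dc + 0.2)
      blocks[[np + j]] <- b
    }
    bb <- blocks[[np + 1]]
    bb[bb$elety == "P", c("x", "y", "z")] <- c(dc, 0, 0)
    blocks[[np + 1]] <- bb
    if (spec$na_type == "dsDNA") {
      comp <- c(DA = "DT", DT = "DA", DC = "DG", DG = "DC")
      for (j in seq_len(nn)) {
        ctr <- c(dc + 2.2, 6.5, 3.4 * (j - (nn + 1) / 2))
        blocks[[np + nn + j]] <- residue_atom_block(
          nucleotide_atoms(comp[[na_types[j]]]), comp[[na_types[j]]],
          j, "C", ctr, xmin = dc + 0.2)
      }
    }
  } else if (spec$geometry == "random_cloud") {
    for (i in seq_len(np)) {
      ctr <- c(stats::runif(1, -14, -4), stats::runif(1, -6, 6),
               stats::runif(1, -6, 6))
      blocks[[i]] <- residue_atom_block(
        residue_heavy_atoms(AA3[[prot_types[i]]]), AA3[[prot_types[i]]],
        i, "A", ctr)
    }
    for (j in seq_len(nn)) {
      ctr <- c(stats::runif(1, dc + 2, dc + 12), stats::runif(1, -6, 6),
               stats::runif(1, -6, 6))
      blocks[[np + j]] <- residue_atom_block(
        nucleotide_atoms(na_types[j]), na_types[j], j, "B", ctr,
        xmin = dc + 0.5)
    }
  } else { # cage
    prot_types[1] <- spec$interface_aa
    blocks[[1]] <- residue_atom_block(
      residue_heavy_atoms(AA3[[spec$interface_aa]]),
      AA3[[spec$interface_aa]], 1, "A", c(0, 0, 0), jitter = 0.9)
    shell <- sphere_points(320) * 5.0
    for (s in seq_len(nrow(shell))) {
      blocks[[1 + s]] <- data.frame(
        elety = "CA", element = "C",
        x = round(shell[s, 1], 3), y = round(shell[s, 2], 3),
        z = round(shell[s, 3], 3),
        resid = "GLY", resno = 1 + s, insert = "", chain = "A",
        o = 1, alt = "", stringsAsFactors = FALSE)
    }
    nb <- length(blocks)
    for (j in seq_len(nn)) {
      ctr <- c(30 + 2 * j, 0, 0)
      blocks[[nb + j]] <- residue_atom_block(
        nucleotide_atoms(na_types[j]), na_types[j], j, "B", ctr)
    }
  }

  atoms <- do.call(rbind, blocks)
  atoms$kind <- residue_kind(atoms$resid)
  cx <- structure(list(atoms = atoms,
                       chains = c(A = "protein", B = "nucleic_acid"),
                       na_type = spec$na_type,
                       source_id = sprintf("fixture-%s-%d", spec$geometry,
                                           spec$seed)),
                  class = "na_complex")
  write_complex(cx)
}

#' Generate a feature-level dataset with a planted linear signal
#'
#' Draws a feature matrix with latent-factor correlation structure
#' (signature columns in real data are strongly collinear: cumulative
#' counts share the underlying atom density) and targets
#' `y = X w + eps`, `eps ~ N(0, noise_sd^2)`. With
#' `antisymmetric = TRUE` records come in forward/reverse pairs whose
#' features and noise are exactly negated, so paired targets negate
#' exactly and the dataset mean is exactly zero.
#'
#' @param n_records number of records (even when antisymmetric).
#' @param manifest feature names; defaults to the package's default
#'   signature manifest.
#' @param weights named weight vector over (a subset of) the manifest;
#'   `NULL` plants weights on 10 seeded columns, scaled so the noiseless
#'   signal has standard deviation ~1.5 kcal/mol.
#' @param noise_sd Gaussian noise, kcal/mol.
#' @param antisymmetric build exact forward/reverse pairs.
#' @param n_latent latent factors behind the feature correlation.
#' @param seed integer seed.
#' @return list with `X`, `y`, `weights` (full-length named vector),
#'   `records` (data frame: `id`, `ddg_exp`, `direction`, `partner_id`).
#' @export
generate_planted_dataset <- function(n_records = 500,
                                     manifest = signature_manifest(),
                                     weights = NULL, noise_sd = 0.3,
                                     antisymmetric = FALSE,
                                     n_latent = 6, seed = 1) {
  p <- length(manifest)
  with_seed(seed, {
    n_base <- if (antisymmetric) {
      if (n_records %% 2 != 0) stopf("antisymmetric dataset needs even n_records")
      n_records / 2
    } else n_records
    Z <- matrix(stats::rnorm(n_base * n_latent), n_base, n_latent)
    L <- matrix(stats::rnorm(n_latent * p), n_latent, p)
    X <- Z %*% L + 0.3 * matrix(stats::rnorm(n_base * p), n_base, p)
    colnames(X) <- manifest

    w <- stats::setNames(numeric(p), manifest)
    if (is.null(weights)) {
      idx <- sample(p, min(10, p))
      w[idx] <- stats::rnorm(length(idx))
      s <- as.numeric(X %*% w)
      w <- w * 1.5 / stats::sd(s)
    } else {
      bad <- setdiff(names(weights), manifest)
      if (length(bad) > 0)
        stopf("planted weights name features outside the manifest: %s",
              paste(bad, collapse = ", "))
      w[names(weights)] <- weights
    }
    eps <- stats::rnorm(n_base, sd = noise_sd)
    y <- as.numeric(X %*% w) + eps

    if (antisymmetric) {
      X <- rbind(X, -X)
      y <- c(y, -y)
      direction <- rep(c("forward", "reverse"), each = n_base)
      partner <- c(seq_len(n_base), seq_len(n_base))
    } else {
      direction <- rep("forward", n_base)
      partner <- seq_len(n_base)
    }
    records <- data.frame(id = seq_along(y), ddg_exp = y,
                          direction = direction, partner_id = partner,
                          stringsAsFactors = FALSE)
    list(X = X, y = y, weights = w, records = records)
  })
}

#' Generate a structure-level dataset with a planted signal
#'
#' Builds a set of synthetic complexes, samples mutations on their
#' protein chains, featurizes each mutation with the real pipeline and
#' plants the target as a linear function of named features (by default
#' the pharmacophore-change and stability blocks, which are exactly
#' antisymmetric under wild-type/mutant exchange) plus Gaussian noise.
#' The result exercises the complete parse -> signature -> train -> predict
#' loop with a known ground truth.
#'
#' @param n_complexes number of synthetic complexes.
#' @param muts_per_complex mutations sampled per complex.
#' @param weights named planted weights over manifest features.
#' @param noise_sd Gaussian noise, kcal/mol.
#' @param config an [na_config()].
#' @param seed integer seed.
#' @param na_types nucleic-acid types cycled over the complexes.
#' @return list with `records` (an affinity table), `structures` (named
#'   list of `na_complex`), `X`, `y`, `weights`.
#' @export
generate_structural_dataset <- function(n_complexes = 6,
                                        muts_per_complex = 10,
                                        weights = c(dpharm.positive = 0.9,
                                                    dpharm.hydrophobic = 0.15,
                                                    ddg_stab = 0.6),
                                        noise_sd = 0.2,
                                        config = na_config(),
                                        seed = 1,
                                        na_types = c("dsDNA", "ssDNA", "RNA")) {
  manifest <- signature_manifest(config)
  bad <- setdiff(names(weights), manifest)
  if (length(bad) > 0)
    stopf("planted weights name features outside the manifest: %s",
          paste(bad, collapse = ", "))
  structures <- list()
  rows <- list()
  for (ci in seq_len(n_complexes)) {
    ref <- sprintf("SYN%03d", ci)
    nt <- na_types[(ci - 1) %% length(na_types) + 1]
    spec <- fixture_spec(seed = seed * 1000 + ci, n_protein_residues = 10,
                         n_na_residues = 5, na_type = nt)
    cx <- parse_complex(paste(generate_complex(spec), collapse = "\n"),
                        na_type = nt, source_id = ref)
    structures[[ref]] <- cx
    prot <- cx$atoms[cx$atoms$kind == "protein", ]
    res_tab <- unique(prot[, c("resno", "resid")])
    muts <- with_seed(seed * 1000 + ci + 500, {
      lapply(seq_len(muts_per_complex), function(k) {
        r <- res_tab[sample(nrow(res_tab), 1), ]
        wt <- aa_three_to_one(r$resid)
        mut <- sample(setdiff(AA1, wt), 1)
        list(resno = r$resno, wt = wt, mut = mut)
      })
    })
    for (m in muts)
      rows[[length(rows) + 1]] <- data.frame(
        structure_ref = ref, chain = "A",
        mutation = paste0(m$wt, m$resno, m$mut), na_type = nt,
        ddg_exp = NA_real_, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  records$direction <- "forward"
  records$partner_id <- seq_len(nrow(records))
  records$source <- "train"

  feats <- featurize_records(records, structures, config)
  if (nrow(feats$failures) > 0)
    stopf("featurization failed for %d synthetic records", nrow(feats$failures))
  wfull <- stats::setNames(numeric(length(manifest)), manifest)
  wfull[names(weights)] <- weights
  y0 <- as.numeric(feats$X %*% wfull)
  y <- y0 + with_seed(seed + 77, stats::rnorm(length(y0), sd = noise_sd))
  records$ddg_exp <- y
  list(records = records, structures = structures, X = feats$X, y = y,
       weights = wfull)
}

#' Generate a synthetic affinity table with the study composition
#'
#' Emits a purely synthetic training table whose composition matches the
#' curated study data: 331 forward mutations over 38 distinct complexes,
#' 258 of them reducing affinity; 222 dsDNA mutations over 28 complexes,
#' 42 ssDNA over 6 and 67 RNA over 5 (one complex identifier is shared
#' between the dsDNA and ssDNA strata, which is what reconciles the
#' per-type structure counts with the overall total). Structure
#' references are synthetic identifiers; the table exercises dataset
#' reading, augmentation and fold construction, not featurization.
#'
#' @param seed integer seed.
#' @param n_total,n_reducing,per_type composition knobs; defaults are the
#'   study composition.
#' @return data frame in the dataset schema.
#' @export
generate_training_table <- function(seed = 1, n_total = 331,
                                    n_reducing = 258,
                                    per_type = c(dsDNA = 222, ssDNA = 42,
                                                 RNA = 67),
                                    structures_per_type = c(dsDNA = 28,
                                                            ssDNA = 6,
                                                            RNA = 5)) {
  if (sum(per_type) != n_total)
    stopf("per-type mutation counts must sum to n_total")
  with_seed(seed, {
    refs <- list(
      dsDNA = sprintf("SYND%02d", seq_len(structures_per_type[["dsDNA"]])),
      # first ssDNA id aliases the last dsDNA id: a complex contributing
      # records to both strata
      ssDNA = c(sprintf("SYND%02d", structures_per_type[["dsDNA"]]),
                sprintf("SYNS%02d", seq_len(structures_per_type[["ssDNA"]] - 1))),
      RNA = sprintf("SYNR%02d", seq_len(structures_per_type[["RNA"]])))
    rows <- list()
    for (t in names(per_type)) {
      n <- per_type[[t]]
      ids <- refs[[t]]
      # every complex gets at least one mutation
      assign_ref <- c(ids, sample(ids, n - length(ids), replace = TRUE))
      for (i in seq_len(n)) {
        wt <- sample(AA1, 1)
        mut <- sample(setdiff(AA1, wt), 1)
        rows[[length(rows) + 1]] <- data.frame(
          structure_ref = assign_ref[i], chain = "A",
          mutation = paste0(wt, sample(2:300, 1), mut),
          na_type = t, ddg_exp = NA_real_, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    sign_neg <- sample(nrow(tab), n_reducing)
    ddg <- numeric(nrow(tab))
    ddg[sign_neg] <- -abs(stats::rnorm(n_reducing, 1.2, 0.8)) - 0.01
    ddg[-sign_neg] <- abs(stats::rnorm(nrow(tab) - n_reducing, 0.8, 0.5)) + 0.01
    tab$ddg_exp <- round(ddg, 3)
    tab
  })
}
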