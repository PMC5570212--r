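# Cutoff-scanning structural signatures.
#
# The environment of a mutation site is summarised as cumulative counts of
# pharmacophore-class atom pairs at increasing distance cutoffs: for every
# unordered class pair (c_i, c_j) and cutoff d_k, the number of distinct
# atom pairs at Euclidean distance <= d_k in which one atom carries c_i
# and the other c_j. Complementary per-mutation evidence (pharmacophore
# change vector, relative solvent accessibility, distance to the nucleic
# acid, a protein-stability term and the declared nucleic-acid type) is
# appended to form the model's feature vector.

#' Define a cutoff schedule
#'
#' @param d_min,d_max,step schedule bounds and increment, Angstrom.
#' @return `cutoff_schedule` object; its `cutoffs` element holds the
#'   `floor((d_max - d_min)/step) + 1` thresholds.
#' @examples
#' cutoff_schedule(0, 10, 2)$cutoffs
#' @export
cutoff_schedule <- function(d_min = 0, d_max = 10, step = 2) {
  if (d_min < 0 || d_max <= d_min || step <= 0)
    stopf("invalid cutoff schedule: need d_min >= 0, d_max > d_min, step > 0")
  k <- floor((d_max - d_min) / step + 1e-9)
  structure(list(d_min = d_min, d_max = d_max, step = step,
                 cutoffs = d_min + step * (0:k)),
            class = "cutoff_schedule")
}

#' Run configuration for signature computation
#'
#' Bundles every tunable of the featurizer so a signature run is fully
#' described by one object: the cutoff schedule, environment radius,
#' nucleic-acid typing scheme, whether multi-class atoms contribute to
#' every class pair they realise or only their primary class, and the
#' provider of the protein-stability feature.
#'
#' @param schedule a [cutoff_schedule()].
#' @param radius environment radius, Angstrom.
#' @param scheme nucleic-acid typing scheme, `"NUC_GROUP"` or `"NUC_BASE"`.
#' @param multiclass logical; `FALSE` restricts protein atoms to their
#'   primary class.
#' @param stability_provider `"baseline_heuristic"`, `"external_value"` or
#'   `"zero"` (see [stability_feature()]).
#' @param stability_column dataset column read when the provider is
#'   `"external_value"`.
#' @param stability_coef coefficients of the baseline heuristic.
#' @return a `na_config` list.
#' @export
na_config <- function(schedule = cutoff_schedule(),
                      radius = 10.0,
                      scheme = c("NUC_GROUP", "NUC_BASE"),
                      multiclass = TRUE,
                      stability_provider = c("baseline_heuristic",
                                             "external_value", "zero"),
                      stability_column = "ddg_stability",
                      stability_coef = c(hydropathy = 0.10,
                                         volume = 0.008,
                                         burial = 1.0)) {
  stopifnot(inherits(schedule, "cutoff_schedule"), radius > 0)
  structure(list(schedule = schedule, radius = radius,
                 scheme = match.arg(scheme), multiclass = isTRUE(multiclass),
                 stability_provider = match.arg(stability_provider),
                 stability_column = stability_column,
                 stability_coef = stability_coef),
            class = "na_config")
}

signature_classes <- function(scheme) c(PROTEIN_CLASSES, NA_CLASSES[[scheme]])

# ordered unordered class pairs (c_i <= c_j by inventory position)
signature_class_pairs <- function(scheme) {
  cls <- signature_classes(scheme)
  idx <- which(upper.tri(diag(length(cls)), diag = TRUE), arr.ind = TRUE)
  data.frame(a = cls[idx[, "row"]], b = cls[idx[, "col"]],
             stringsAsFactors = FALSE)
}

#' Feature manifest of a configuration
#'
#' The frozen, ordered feature names a signature run produces: one
#' `pc.<class_i>|<class_j>.<cutoff>` column per class pair and cutoff,
#' followed by the pharmacophore change block (`dpharm.*`), `rsa`,
#' `dist_na`, `ddg_stab` and the nucleic-acid type one-hot block. Models
#' refuse matrices whose manifest differs from the one they were trained
#' with.
#'
#' @param config an [na_config()].
#' @return character vector of feature names.
#' @export
signature_manifest <- function(config = na_config()) {
  pairs <- signature_class_pairs(config$scheme)
  cuts <- config$schedule$cutoffs
  pc <- as.vector(t(outer(paste0("pc.", pairs$a, "|", pairs$b, "."),
                          format(cuts, trim = TRUE), paste0)))
  c(pc,
    paste0("dpharm.", PROTEIN_CLASSES),
    "rsa", "dist_na", "ddg_stab",
    paste0("na.", c("RNA", "ssDNA", "dsDNA")))
}

#' Cumulative pharmacophore pair counts of a labelled atom set
#'
#' For every unordered class pair and every cutoff of the schedule, counts
#' the atom pairs (a, b), a != b, at distance <= cutoff in which a carries
#' one class of the pair and b the other. Each unordered atom pair is
#' counted once per distinct class pair it realises; self-pairs are
#' excluded. Counts are cumulative in the cutoff by construction.
#'
#' @param atoms data frame with `x`, `y`, `z` columns.
#' @param labels list of per-atom class character vectors (parallel to
#'   `atoms`).
#' @param schedule a [cutoff_schedule()].
#' @param scheme nucleic-acid scheme naming the class inventory.
#' @return numeric matrix, rows = class pairs (named `"a|b"`), columns =
#'   cutoffs.
#' @export
cutoff_scan <- function(atoms, labels, schedule = cutoff_schedule(),
                        scheme = "NUC_GROUP") {
  n <- nrow(atoms)
  if (is.null(n) || n == 0) stopf("cutoff_scan: empty atom list")
  if (length(labels) != n)
    stopf("cutoff_scan: %d atoms but %d label sets", n, length(labels))
  cls <- signature_classes(scheme)
  pairs <- signature_class_pairs(scheme)
  cuts <- schedule$cutoffs
  out <- matrix(0, nrow(pairs), length(cuts),
                dimnames = list(paste0(pairs$a, "|", pairs$b),
                                format(cuts, trim = TRUE)))
  if (n == 1) return(out)

  # incidence matrix atoms x classes
  inc <- matrix(FALSE, n, length(cls), dimnames = list(NULL, cls))
  for (i in seq_len(n)) {
    li <- intersect(labels[[i]], cls)
    if (length(li) > 0) inc[i, li] <- TRUE
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  ut <- upper.tri(d)
  dv <- d[ut]
  for (p in seq_len(nrow(pairs))) {
    a <- inc[, pairs$a[p]]
    b <- inc[, pairs$b[p]]
    hit <- (outer(a, b, "&") | outer(b, a, "&"))[ut]
    if (!any(hit)) next
    dd <- dv[hit]
    out[p, ] <- vapply(cuts, function(ck) sum(dd <= ck + 1e-9), numeric(1))
  }
  out
}

#' Build the full signature vector for one mutation
#'
#' Pipeline: locate the residue, extract its environment, label atoms,
#' run the cutoff scan, then append the pharmacophore change vector, the
#' residue's relative solvent accessibility, its minimum distance to the
#' nucleic acid, the stability feature and the declared nucleic-acid type
#' one-hot block. Deterministic for a fixed input and configuration.
#'
#' @param cx an `na_complex`.
#' @param m a `mutation_spec` (or string plus `chain`).
#' @param config an [na_config()].
#' @param chain chain id when `m` is a string.
#' @param stability_value externally supplied stability ddG (kcal/mol),
#'   used when the configured provider is `"external_value"`.
#' @param swap_residue optional residue handle overriding the located
#'   residue; used internally for reverse records evaluated on the
#'   wild-type structure.
#' @return named numeric vector following [signature_manifest()].
#' @export
build_signature <- function(cx, m, config = na_config(), chain = NULL,
                            stability_value = NULL, swap_residue = NULL) {
  stopifnot(inherits(cx, "na_complex"), inherits(config, "na_config"))
  if (is.character(m)) m <- mutation_spec(m, chain)
  res <- swap_residue %||% locate_residue(cx, m)

  env <- extract_environment(cx, res, radius = config$radius)
  labels <- atom_class_sets(env, scheme = config$scheme,
                            multiclass = config$multiclass)
  pc <- cutoff_scan(env, labels, schedule = config$schedule,
                    scheme = config$scheme)
  pc_flat <- as.vector(t(pc))

  dph <- pharmacophore_change(m$wt, m$mut)
  rsa <- relative_solvent_accessibility(cx, res)
  dna <- min_distance_to_na(cx, res)
  stab <- stability_feature(config$stability_provider, cx, m, rsa = rsa,
                            external = stability_value,
                            coef = config$stability_coef)
  onehot <- as.numeric(c("RNA", "ssDNA", "dsDNA") == cx$na_type)

  v <- c(pc_flat, as.numeric(dph), rsa, dna, stab, onehot)
  names(v) <- signature_manifest(config)
  v
}

#' Featurize a set of affinity records
#'
#' Builds one signature per record. Structures are resolved through
#' `structures`: either a named list of parsed `na_complex` objects keyed
#' by `structure_ref`, or a directory containing `<structure_ref>.pdb`
#' files. Reverse records whose `structure_ref` equals their forward
#' partner's (no modelled mutant available) are evaluated on the wild-type
#' structure: the environment is that of the original residue and the
#' mutation-dependent features are computed for the reversed substitution.
#'
#' @param records data frame of affinity records (see [read_dataset()]).
#' @param structures named list of `na_complex` or a directory path.
#' @param config an [na_config()].
#' @return list with `X` (matrix, rows = records), `manifest`, and
#'   `failures` (data frame of row, reason for rows that could not be
#'   featurized; their matrix rows are `NA`).
#' @export
featurize_records <- function(records, structures, config = na_config()) {
  manifest <- signature_manifest(config)
  X <- matrix(NA_real_, nrow(records), length(manifest),
              dimnames = list(NULL, manifest))
  fail_row <- integer(0); fail_why <- character(0)
  cache <- new.env(parent = emptyenv())

  get_cx <- function(ref, na_type) {
    key <- paste0(ref, "|", na_type)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cx <- if (is.list(structures)) {
      if (is.null(structures[[ref]])) stopf("structure '%s' not supplied", ref)
      structures[[ref]]
    } else {
      path <- file.path(structures, paste0(ref, ".pdb"))
      if (!file.exists(path)) stopf("structure file not found: %s", path)
      parse_complex(path, na_type = na_type, source_id = ref)
    }
    cache[[key]] <- cx
    cx
  }

  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    v <- tryCatch({
      cx <- get_cx(rec$structure_ref, rec$na_type)
      m <- mutation_spec(rec$mutation, rec$chain)
      ext <- if (!is.null(rec$ddg_stability)) rec$ddg_stability else NULL
      if (identical(rec$direction, "reverse") && !isTRUE(rec$modeled)) {
        # wild-type structure stands in for the unmodelled mutant: locate
        # via the swapped (forward) residue identity
        fwd <- mutation_spec(paste0(m$mut, m$resno, m$insert, m$wt), m$chain)
        res <- locate_residue(cx, fwd)
        build_signature(cx, m, config, stability_value = ext,
                        swap_residue = res)
      } else {
        build_signature(cx, m, config, stability_value = ext)
      }
    }, error = function(e) e)
    if (inherits(v, "error")) {
      fail_row <- c(fail_row, i); fail_why <- c(fail_why, conditionMessage(v))
    } else X[i, ] <- v
  }
  list(X = X, manifest = manifest,
       failures = data.frame(row = fail_row, reason = fail_why,
                             stringsAsFactors = FALSE))
}

#' Write / read a signature matrix as TSV with a manifest sidecar
#'
#' @param X signature matrix with column names.
#' @param path output TSV; the manifest is written to `<path>.manifest`.
#' @return `write_signatures`: the path, invisibly. `read_signatures`:
#'   list with `X` and `manifest`, validated against the sidecar.
#' @export
write_signatures <- function(X, path) {
  utils::write.table(as.data.frame(X), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(colnames(X), paste0(path, ".manifest"))
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  X <- as.matrix(utils::read.delim(path, check.names = FALSE))
  man_path <- paste0(path, ".manifest")
  manifest <- if (file.exists(man_path)) readLines(man_path) else colnames(X)
  if (!identical(colnames(X), manifest))
    stopf("signature matrix columns disagree with manifest sidecar")
  list(X = X, manifest = manifest)
}
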