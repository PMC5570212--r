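# Evaluation protocol: Pearson correlation, largest-residual outlier
# trimming, per-nucleic-acid-type subsets and distance-to-NA
# stratification.

#' Pearson product-moment correlation
#'
#' @param y_true,y_pred numeric vectors, length >= 3, each with non-zero
#'   variance (zero variance is an error, never a silent NaN).
#' @return correlation coefficient.
#' @export
pearson_r <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("length mismatch: %d vs %d", length(y_true), length(y_pred))
  if (length(y_true) < 3) stopf("need at least 3 observations")
  if (stats::sd(y_true) < 1e-15 || stats::sd(y_pred) < 1e-15)
    stopf("zero variance in input to pearson_r")
  stats::cor(y_true, y_pred)
}

#' Largest-residual outlier trimming
#'
#' Removes the `ceiling(fraction * n)` records with the largest absolute
#' residual `|y_true - y_pred|`; ties are broken by record order (earlier
#' records removed first).
#'
#' @param y_true,y_pred numeric vectors.
#' @param fraction fraction to remove, in \[0, 0.5).
#' @return integer vector of retained indices, in original order.
#' @export
trim_outliers <- function(y_true, y_pred, fraction = 0.10) {
  if (fraction < 0 || fraction >= 0.5)
    stopf("trim fraction must be in [0, 0.5)")
  n <- length(y_true)
  k <- ceiling(fraction * n)
  if (k == 0) return(seq_len(n))
  res <- abs(y_true - y_pred)
  removed <- order(-res, seq_len(n))[seq_len(k)]
  setdiff(seq_len(n), removed)
}

#' Evaluation report
#'
#' Computes the full scoring protocol: Pearson correlation with and
#' without outlier trimming, overall and per subset (typically the
#' nucleic-acid type partition), plus per-record residuals.
#'
#' @param y_true,y_pred numeric vectors.
#' @param subset optional factor/character vector partitioning the
#'   records (e.g. na_type).
#' @param trim_fraction outlier fraction removed for the trimmed
#'   correlation.
#' @return `na_eval` object: list with `n`, `rho_all`, `rho_trimmed`,
#'   `trim_fraction`, `subsets` (data frame name/n/rho_all/rho_trimmed)
#'   and `residuals`.
#' @export
eval_report <- function(y_true, y_pred, subset = NULL,
                        trim_fraction = 0.10) {
  ok <- is.finite(y_true) & is.finite(y_pred)
  y_true <- y_true[ok]; y_pred <- y_pred[ok]
  if (!is.null(subset)) subset <- subset[ok]
  score <- function(yt, yp) {
    if (length(yt) < 3 || stats::sd(yt) < 1e-15 || stats::sd(yp) < 1e-15)
      return(c(rho_all = NA_real_, rho_trimmed = NA_real_))
    keep <- trim_outliers(yt, yp, trim_fraction)
    rt <- if (length(keep) >= 3 && stats::sd(yt[keep]) > 1e-15 &&
              stats::sd(yp[keep]) > 1e-15) pearson_r(yt[keep], yp[keep])
          else NA_real_
    c(rho_all = pearson_r(yt, yp), rho_trimmed = rt)
  }
  overall <- score(y_true, y_pred)
  subsets <- NULL
  if (!is.null(subset)) {
    subsets <- do.call(rbind, lapply(sort(unique(subset)), function(s) {
      sel <- subset == s
      sc <- score(y_true[sel], y_pred[sel])
      data.frame(name = s, n = sum(sel), rho_all = sc["rho_all"],
                 rho_trimmed = sc["rho_trimmed"], row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(n = length(y_true),
                 rho_all = unname(overall["rho_all"]),
                 rho_trimmed = unname(overall["rho_trimmed"]),
                 trim_fraction = trim_fraction,
                 subsets = subsets,
                 residuals = y_true - y_pred),
            class = "na_eval")
}

#' @export
print.na_eval <- function(x, ...) {
  cat(sprintf("evaluation on %d records: rho = %.3f (all), %.3f after %.0f%% outlier removal\n",
              x$n, x$rho_all, x$rho_trimmed, 100 * x$trim_fraction))
  if (!is.null(x$subsets)) {
    for (i in seq_len(nrow(x$subsets)))
      cat(sprintf("  %-6s n = %3d  rho = %6.3f  trimmed = %6.3f\n",
                  x$subsets$name[i], x$subsets$n[i], x$subsets$rho_all[i],
                  x$subsets$rho_trimmed[i]))
  }
  invisible(x)
}

#' Write an evaluation report as TSV plus residuals
#'
#' @param report an `na_eval`.
#' @param path output TSV path; residuals go to `<path>.residuals`.
#' @export
write_eval_report <- function(report, path) {
  rows <- data.frame(name = "all", n = report$n, rho_all = report$rho_all,
                     rho_trimmed = report$rho_trimmed,
                     stringsAsFactors = FALSE)
  if (!is.null(report$subsets)) rows <- rbind(rows, report$subsets)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(residual = report$residuals),
                     paste0(path, ".residuals"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Distance-stratified evaluation
#'
#' Restricts the evaluation to records whose mutation site lies within
#' each distance shell of the nucleic acid (shells are nested: "within
#' 5 A" is a subset of "within 10 A"). Empty or degenerate shells are
#' reported with `n` and `rho = NA`, never raised as errors.
#'
#' @param y_true,y_pred numeric vectors.
#' @param dist_na per-record distance to the nucleic acid, Angstrom.
#' @param shells upper bounds of the nested shells.
#' @return data frame with `shell`, `n`, `rho`.
#' @export
stratify_by_distance <- function(y_true, y_pred, dist_na,
                                 shells = c(5, 10, Inf)) {
  stopifnot(length(y_true) == length(y_pred),
            length(dist_na) == length(y_true))
  do.call(rbind, lapply(shells, function(s) {
    sel <- is.finite(y_true) & is.finite(y_pred) & dist_na <= s
    rho <- if (sum(sel) >= 3 && stats::sd(y_true[sel]) > 1e-15 &&
               stats::sd(y_pred[sel]) > 1e-15)
      pearson_r(y_true[sel], y_pred[sel]) else NA_real_
    data.frame(shell = s, n = sum(sel), rho = rho)
  }))
}
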