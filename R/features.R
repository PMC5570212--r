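# Complementary per-mutation features: relative solvent accessibility,
# minimum distance from the mutation site to the nucleic acid, and a
# pluggable protein-stability term.

#' Relative solvent accessibility of a residue
#'
#' Shrake-Rupley ASA of the residue's heavy atoms divided by the
#' residue-type maximum from the shipped normalisation table, clipped to
#' \[0, 1\]. The ASA is computed on the protein chains alone — the nucleic
#' acid (and any "other" residue) is stripped first — so interface
#' residues are not reported as artificially buried by their binding
#' partner.
#'
#' @param cx an `na_complex`.
#' @param residue a residue handle from [locate_residue()] or a
#'   `mutation_spec`.
#' @param probe probe radius, Angstrom.
#' @param n_points Shrake-Rupley sphere points.
#' @return relative accessibility in \[0, 1\].
#' @export
relative_solvent_accessibility <- function(cx, residue, probe = 1.4,
                                           n_points = 92) {
  stopifnot(inherits(cx, "na_complex"))
  res <- if (inherits(residue, "na_residue")) residue
         else locate_residue(cx, residue)
  prot <- cx$atoms[cx$atoms$kind == "protein", , drop = FALSE]
  if (nrow(prot) == 0) stopf("no protein atoms present")
  sel <- prot$chain == res$chain & prot$resno == res$resno &
    prot$insert == res$insert
  if (!any(sel)) stopf("residue has no heavy atoms on the protein chains")
  asa <- shrake_rupley(prot, probe = probe, n_points = n_points)
  total <- sum(asa[sel])
  max_asa <- max_asa_table()[res$resid]
  if (is.na(max_asa)) stopf("no max-ASA entry for residue type %s", res$resid)
  min(1, max(0, total / max_asa))
}

#' Minimum distance from a residue to the nucleic acid
#'
#' @param cx an `na_complex`.
#' @param residue residue handle or `mutation_spec`.
#' @return minimum Euclidean distance (Angstrom) between any heavy atom of
#'   the residue and any nucleic-acid heavy atom.
#' @export
min_distance_to_na <- function(cx, residue) {
  stopifnot(inherits(cx, "na_complex"))
  res <- if (inherits(residue, "na_residue")) residue
         else locate_residue(cx, residue)
  na_at <- cx$atoms[cx$atoms$kind == "nucleic_acid", , drop = FALSE]
  if (nrow(na_at) == 0) stopf("no nucleic-acid atoms present")
  a <- as.matrix(cx$atoms[res$atom_idx, c("x", "y", "z")])
  b <- as.matrix(na_at[, c("x", "y", "z")])
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Protein-stability feature
#'
#' The predicted stability change upon mutation used as complementary
#' evidence. Three providers:
#' \describe{
#'   \item{`zero`}{always 0 (feature disabled).}
#'   \item{`external_value`}{a value supplied per record (predictions from
#'     a dedicated stability predictor); missing value is an error.}
#'   \item{`baseline_heuristic`}{a transparent stand-in: a linear
#'     combination of the hydropathy change and the residue-volume change,
#'     scaled by the burial of the site,
#'     `(c_h * dHyd + c_v * dVol) * (0.5 + 0.5 * c_b * (1 - rsa))`.
#'     Anti-symmetric in (wt, mut) at fixed rsa.}
#' }
#'
#' @param provider `"baseline_heuristic"`, `"external_value"` or `"zero"`.
#' @param cx an `na_complex` (heuristic only; may be `NULL` otherwise).
#' @param m a `mutation_spec`.
#' @param rsa relative solvent accessibility of the site (heuristic).
#' @param external externally supplied value (kcal/mol).
#' @param coef named coefficients `hydropathy`, `volume`, `burial`.
#' @return stability ddG in kcal/mol.
#' @export
stability_feature <- function(provider = c("baseline_heuristic",
                                           "external_value", "zero"),
                              cx = NULL, m = NULL, rsa = NULL,
                              external = NULL,
                              coef = c(hydropathy = 0.10, volume = 0.008,
                                       burial = 1.0)) {
  provider <- match.arg(provider)
  switch(provider,
    zero = 0.0,
    external_value = {
      if (is.null(external) || is.na(external))
        stopf("stability provider 'external_value' selected but no value supplied")
      as.numeric(external)
    },
    baseline_heuristic = {
      if (is.null(m)) stopf("baseline_heuristic needs a mutation spec")
      if (is.null(rsa)) rsa <- 0.5
      dh <- AA_HYDROPATHY[[m$mut]] - AA_HYDROPATHY[[m$wt]]
      dv <- AA_VOLUME[[m$mut]] - AA_VOLUME[[m$wt]]
      (coef[["hydropathy"]] * dh + coef[["volume"]] * dv) *
        (0.5 + 0.5 * coef[["burial"]] * (1 - rsa))
    })
}
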