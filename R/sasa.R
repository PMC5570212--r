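# Shrake-Rupley accessible surface area.
#
# Classic sphere-point algorithm: each atom is covered with a fixed set of
# points on a sphere of radius (vdW + probe); a point is accessible when
# it lies outside the probe-expanded sphere of every neighbouring atom.
# The per-atom area is the accessible fraction of the sphere surface.
# 92 points and a 1.4 A water probe are the defaults.

# near-uniform points on the unit sphere (golden-section spiral);
# deterministic, no RNG
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' @param atoms data frame of heavy atoms with columns `x`, `y`, `z` and
#'   `element`.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sphere points per atom.
#' @return numeric vector of per-atom accessible areas (square Angstrom).
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 92) {
  n <- nrow(atoms)
  if (n == 0) stopf("shrake_rupley: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- VDW_RADII[toupper(atoms$element)]
  radii[is.na(radii)] <- 1.70
  pts <- sphere_points(n_points)
  area <- numeric(n)
  ext <- radii + probe
  for (i in seq_len(n)) {
    ri <- ext[i]
    # neighbours whose expanded spheres can intersect atom i's shell
    dx <- xyz[, 1] - xyz[i, 1]; dy <- xyz[, 2] - xyz[i, 2]
    dz <- xyz[, 3] - xyz[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    nb <- which(d2 < (ri + ext)^2 & seq_len(n) != i)
    if (length(nb) == 0) { area[i] <- 4 * pi * ri^2; next }
    sp <- sweep(pts * ri, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      rj2 <- ext[j]^2
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 > rj2)
    }
    area[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  area
}
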