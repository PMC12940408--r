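## Shrake-Rupley solvent-accessible surface area.
##
## Test points are placed on each atom's solvent-expanded sphere via a
## golden-section spiral; a point is accessible when it lies outside every
## neighboring atom's expanded sphere. ASA = exposed fraction times the
## expanded-sphere area.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

atom_radius <- function(elety) {
  el <- substr(gsub("^[0-9]+", "", elety), 1, 1)
  r <- VDW_RADII[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' @param xyz numeric matrix (n x 3) of heavy-atom coordinates, Angstrom.
#' @param radii per-atom van der Waals radii, Angstrom.
#' @param probe probe radius, default 1.4 Angstrom (water).
#' @param n_points test points per atom sphere.
#' @return Numeric vector of per-atom ASA in square Angstrom.
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 92) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  pts <- sphere_points(n_points)
  er <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * er[i], 2, xyz[i, ], `+`)
    dx <- xyz[, 1] - xyz[i, 1]; dy <- xyz[, 2] - xyz[i, 2]
    dz <- xyz[, 3] - xyz[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    nb <- which(d2 < (er + er[i])^2 & d2 > 0)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > er[j]^2
      if (!any(free)) break
    }
    out[i] <- sum(free) / n_points * 4 * pi * er[i]^2
  }
  out
}

#' Relative accessible surface area per residue
#'
#' Residue ASA in the context of the full structure divided by the ASA of
#' the same atoms computed in isolation (fully exposed reference). This
#' self-normalizing reference works identically for full-atom models and
#' the reduced synthetic representation.
#'
#' @param model a [state_model()].
#' @param probe probe radius in Angstrom.
#' @return Named numeric vector (one value in \[0, 1\] per residue).
#' @export
residue_rel_asa <- function(model, probe = 1.4) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- atom_radius(a$elety)
  asa <- sasa_atoms(xyz, radii, probe = probe)
  res <- model$residues
  out <- numeric(length(res))
  for (i in seq_along(res)) {
    sel <- a$resno == res[i]
    ref <- sasa_atoms(xyz[sel, , drop = FALSE], radii[sel], probe = probe)
    out[i] <- sum(asa[sel]) / sum(ref)
  }
  names(out) <- res
  pmin(out, 1)
}
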