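# Numeric solvent-accessible surface area (Shrake-Rupley style): each heavy
# atom is inflated by the probe radius and sampled with a deterministic
# Fibonacci sphere; sample points buried inside any other inflated atom are
# discarded and the free fraction scales the sphere area.

# van der Waals radii (A) by element; unknown elements fall back to carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

#' Maximum residue solvent accessibility
#'
#' Per-residue-type maximum accessible surface areas (Å²) used to normalize
#' raw SASA into relative accessibility, after Rost & Sander (1994).
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
MAX_ACC <- c(A = 106, R = 248, N = 157, D = 163, C = 135,
             Q = 198, E = 194, G = 84,  H = 184, I = 169,
             L = 164, K = 205, M = 188, F = 197, P = 136,
             S = 130, T = 142, W = 227, Y = 222, V = 142)

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# SASA (A^2) of the atoms with indices `which_atoms` in the context of all
# atoms given by coords (matrix) and elements (vector).
sasa_atoms <- function(coords, elements, which_atoms, probe = 1.4,
                       n_points = 256L) {
  radii <- VDW_RADII[elements]
  radii[is.na(radii)] <- VDW_RADII[["C"]]
  radii <- radii + probe
  sphere <- fibonacci_sphere(n_points)
  vapply(which_atoms, function(i) {
    ri <- radii[i]
    pts <- sweep(sphere * ri, 2L, coords[i, ], "+")
    near <- which(seq_len(nrow(coords)) != i &
                    sqrt(rowSums(sweep(coords, 2L, coords[i, ])^2)) < ri + radii)
    free <- rep(TRUE, n_points)
    for (j in near) {
      d2 <- rowSums(sweep(pts, 2L, coords[j, ])^2)
      free <- free & d2 > radii[j]^2
      if (!any(free)) break
    }
    4 * pi * ri^2 * sum(free) / n_points
  }, 0)
}

#' Relative solvent accessibility of a residue
#'
#' Computes the residue's solvent-accessible surface area numerically
#' (probe radius 1.4 Å, deterministic spherical quadrature over the
#' chain's heavy atoms), divides by the residue type's maximum
#' accessibility ([MAX_ACC]), and clamps to `[0, 1]`. 0 means fully buried,
#' 1 fully exposed.
#'
#' @param model A `ddg_structure`.
#' @param site A `ddg_structure_site`.
#' @param probe Probe radius in Å (default 1.4).
#' @param n_points Quadrature points per atom (default 256).
#' @return Relative accessibility in `[0, 1]`.
#' @export
relative_accessibility <- function(model, site, probe = 1.4, n_points = 256L) {
  stopifnot(inherits(model, "ddg_structure"), inherits(site, "ddg_structure_site"))
  if (is.na(site$aa)) {
    stop("relative accessibility is defined only for standard residues", call. = FALSE)
  }
  coords <- as.matrix(model$atoms[, c("x", "y", "z")])
  idx <- which(model$atoms$key == site$key)
  if (length(idx) == 0L) stop("site residue has no coordinates", call. = FALSE)
  area <- sum(sasa_atoms(coords, model$atoms$elesy, idx,
                         probe = probe, n_points = n_points))
  min(max(area / MAX_ACC[[site$aa]], 0), 1)
}
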