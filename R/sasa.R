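#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by the Shrake-Rupley construction: each atom is expanded
#' by the probe radius, covered with a deterministic golden-spiral point
#' lattice, and the fraction of points not buried inside any neighboring
#' expanded sphere contributes to its accessible area.  The fixed lattice
#' makes results bit-reproducible across runs.
#'
#' Van der Waals radii come from a bundled Bondi-type element table
#' (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 angstroms); an element
#' without a configured radius is an error.
#'
#' @param frame an atom data.frame.
#' @param probe probe radius in angstroms (default 1.4, water).
#' @param n_sphere_points lattice points per atom (default 960).
#' @param selection logical mask (default: protein atoms).
#' @return total SASA in square angstroms, with attribute `per_residue`
#'   (named by `resid`) and `per_atom`.
#' @examples
#' # a lone carbon: SASA ~ 4*pi*(1.7+1.4)^2
#' atom <- data.frame(record = "ATOM", serial = 1, name = "C", resname = "UNK",
#'                    chain = "A", resid = 1, x = 0, y = 0, z = 0, element = "C")
#' sasa(atom)
#' @export
sasa <- function(frame, probe = 1.4, n_sphere_points = 960, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(frame, "protein")
  x <- coords(frame, selection)
  n <- nrow(x)
  if (n == 0) stop("empty selection")
  radii <- element_property(frame$element[selection], "vdw") + probe
  resid <- frame$resid[selection]
  pts <- golden_spiral(n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    # neighbors whose expanded spheres can intersect atom i's
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    surf <- sweep(pts * ri, 2, x[i, ], "+")
    acc <- rep(TRUE, nrow(surf))
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, x[j, ])^2)
      acc <- acc & dj2 > radii[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * ri^2 * sum(acc) / n_sphere_points
  }
  total <- sum(per_atom)
  attr(total, "per_atom") <- per_atom
  attr(total, "per_residue") <- tapply(per_atom, resid, sum)
  total
}

# deterministic, near-uniform unit-sphere lattice (golden-angle spiral)
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}
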