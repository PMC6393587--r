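#' Generate toy conformer ensembles with placed waters
#'
#' Builds multi-model ensembles that mimic the two extremes seen in
#' conformational ensembles of a 20-residue miniprotein:
#'
#' * `"compact"` -- an ideal alpha-helix backbone (N, CA, C, O per residue)
#'   with small Gaussian coordinate jitter, so every pairwise backbone RMSD
#'   is far below a 1 angstrom clustering cutoff (one cluster);
#' * `"extended"` -- independent self-avoiding random coils with fixed
#'   3.8 angstrom CA-CA steps, whose pairwise RMSDs are typically well
#'   above 3 angstroms (many clusters);
#' * `"mixed"` -- a stated proportion of compact models, the rest extended.
#'
#' Waters (single-oxygen HOH residues) are placed on a cubic lattice
#' spanning the model's bounding box plus a margin, clash-filtered and
#' ordered by distance to the protein, so the count inside any cutoff is
#' known by construction (computable by brute force).
#'
#' @param kind `"compact"`, `"extended"` or `"mixed"`.
#' @param n_models number of conformers (>= 1).
#' @param n_waters waters per model (>= 0).
#' @param seed integer seed.
#' @param jitter_sd per-coordinate Gaussian jitter of the compact models,
#'   angstroms.
#' @param compact_frac fraction of compact models when `kind = "mixed"`.
#' @param n_res residues per model.
#' @param water_spacing lattice spacing of the water grid, angstroms.
#' @return a `conformer_ensemble`; write it with [write_pdb_ensemble()].
#' @examples
#' ens <- make_toy_ensemble("compact", n_models = 5, n_waters = 30)
#' gromos_cluster(ens, cutoff = 1.0)
#' @export
make_toy_ensemble <- function(kind = c("compact", "extended", "mixed"),
                              n_models = 10, n_waters = 0, seed = 1L,
                              jitter_sd = 0.05, compact_frac = 0.5,
                              n_res = 20, water_spacing = 3.1) {
  kind <- match.arg(kind)
  if (n_models < 1) stop("n_models must be >= 1")
  if (n_waters < 0) stop("n_waters must be >= 0")
  withr_seed(seed, {
    n_compact <- switch(kind, compact = n_models, extended = 0L,
                        mixed = round(compact_frac * n_models))
    models <- vector("list", n_models)
    helix <- ideal_helix_backbone(n_res)
    for (m in seq_len(n_models)) {
      bb <- if (m <= n_compact) {
        h <- helix
        h[, c("x", "y", "z")] <- h[, c("x", "y", "z")] +
          matrix(stats::rnorm(3 * nrow(h), 0, jitter_sd), ncol = 3)
        h
      } else {
        coil_backbone(n_res)
      }
      models[[m]] <- add_water_lattice(bb, n_waters, water_spacing, n_res)
    }
    new_conformer_ensemble(models)
  })
}

# Ideal alpha-helix backbone on cylindrical coordinates:
# 100 degrees twist and 1.5 A rise per residue; N/CA/C at standard radii
# and phase/axial offsets, carbonyl O placed radially out from C.
ideal_helix_backbone <- function(n_res) {
  deg <- pi / 180
  atom_rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    phi0 <- (i - 1) * 100 * deg
    z0 <- (i - 1) * 1.5
    place <- function(r, dphi, dz) {
      c(r * cos(phi0 + dphi * deg), r * sin(phi0 + dphi * deg), z0 + dz)
    }
    pos <- list(N = place(1.54, -26, -0.70),
                CA = place(2.27, 0, 0),
                C = place(1.66, 27, 0.70))
    # carbonyl O: 1.23 A radially outward from C
    cxy <- sqrt(sum(pos$C[1:2]^2))
    pos$O <- pos$C + c(pos$C[1] / cxy, pos$C[2] / cxy, 0) * 1.23
    for (nm in names(pos)) {
      serial <- serial + 1L
      atom_rows[[serial]] <- data.frame(
        record = "ATOM", serial = serial, name = nm, resname = "ALA",
        chain = "A", resid = i, x = pos[[nm]][1], y = pos[[nm]][2],
        z = pos[[nm]][3], element = substr(nm, 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, atom_rows)
}

# Self-avoiding random CA walk (3.8 A steps, bond angles 80-140 degrees,
# non-adjacent CA pairs >= 4 A), with N/C placed along the trace and O off C.
coil_backbone <- function(n_res, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    ca <- matrix(NA_real_, n_res, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- random_unit()
    ca[2, ] <- ca[1, ] + 3.8 * dir
    ok <- TRUE
    for (i in seq_len(n_res)[-(1:2)]) {
      placed <- FALSE
      for (att in 1:50) {
        # bend the previous direction by a random 40-100 degree turn
        ang <- stats::runif(1, 40, 100) * pi / 180
        perp <- random_perpendicular(dir)
        nd <- cos(ang) * dir + sin(ang) * perp
        cand <- ca[i - 1, ] + 3.8 * nd
        d2 <- rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
        if (all(d2 >= 16)) { ca[i, ] <- cand; dir <- nd; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("failed to grow a self-avoiding coil")
  atom_rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    prev_dir <- if (i > 1) normalize(ca[i - 1, ] - ca[i, ]) else
      normalize(ca[i, ] - ca[i + 1, ]) * -1
    next_dir <- if (i < n_res) normalize(ca[i + 1, ] - ca[i, ]) else
      normalize(ca[i, ] - ca[i - 1, ]) * -1
    pos <- list(N = ca[i, ] + 1.45 * prev_dir,
                CA = ca[i, ],
                C = ca[i, ] + 1.52 * next_dir)
    pos$O <- pos$C + 1.23 * normalize(random_perpendicular(next_dir))
    for (nm in names(pos)) {
      serial <- serial + 1L
      atom_rows[[serial]] <- data.frame(
        record = "ATOM", serial = serial, name = nm, resname = "ALA",
        chain = "A", resid = i, x = pos[[nm]][1], y = pos[[nm]][2],
        z = pos[[nm]][3], element = substr(nm, 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, atom_rows)
}

normalize <- function(v) v / sqrt(sum(v^2))

random_unit <- function() {
  v <- stats::rnorm(3)
  normalize(v)
}

random_perpendicular <- function(dir) {
  v <- stats::rnorm(3)
  v <- v - sum(v * dir) * dir
  normalize(v)
}

# Cubic-lattice waters around the protein: clash-filtered (>= 2.4 A from
# any protein atom), nearest-first, single O atom per HOH residue.
add_water_lattice <- function(protein, n_waters, spacing, n_res) {
  if (n_waters == 0) return(protein)
  px <- as.matrix(protein[, c("x", "y", "z")])
  lims <- apply(px, 2, range)
  margin <- 6 + spacing * ceiling((n_waters)^(1 / 3))
  grid <- expand.grid(
    x = seq(lims[1, 1] - margin, lims[2, 1] + margin, by = spacing),
    y = seq(lims[1, 2] - margin, lims[2, 2] + margin, by = spacing),
    z = seq(lims[1, 3] - margin, lims[2, 3] + margin, by = spacing))
  gm <- as.matrix(grid)
  # distance of every lattice point to the nearest protein atom
  dmin <- apply(gm, 1, function(p) sqrt(min(rowSums(sweep(px, 2, p)^2))))
  keep <- which(dmin >= 2.4)
  if (length(keep) < n_waters)
    stop("water lattice too small for ", n_waters, " waters")
  keep <- keep[order(dmin[keep])][seq_len(n_waters)]
  wat <- data.frame(
    record = "HETATM", serial = nrow(protein) + seq_len(n_waters),
    name = "O", resname = "HOH", chain = "W",
    resid = n_res + seq_len(n_waters),
    x = gm[keep, 1], y = gm[keep, 2], z = gm[keep, 3],
    element = "O", stringsAsFactors = FALSE)
  rbind(protein, wat)
}
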