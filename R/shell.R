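#' Count hydration-shell waters
#'
#' Number of water residues having at least one atom within `cutoff` of at
#' least one protein atom; each water counts once.  Typical first-shell
#' cutoffs are 2.6-2.8 angstroms.  Implemented with a cell-list spatial
#' grid (cells of edge `cutoff`, 27-neighborhood search), so the cost is
#' linear in atom count rather than quadratic.
#'
#' @param frame an atom data.frame.
#' @param cutoff shell cutoff in angstroms.
#' @param oxygen_only consider only water oxygen atoms (default FALSE: any
#'   water atom to any protein atom).
#' @param water_names residue names recognized as water.
#' @return integer count of shell waters.
#' @export
count_shell_waters <- function(frame, cutoff,
                               oxygen_only = FALSE,
                               water_names = c("HOH", "WAT", "SOL")) {
  if (cutoff <= 0) stop("cutoff must be positive")
  is_w <- select_atoms(frame, "water", water_names)
  is_p <- !is_w
  if (!any(is_p)) stop("frame contains no protein atoms")
  if (!any(is_w)) return(0L)
  wsel <- is_w & (!oxygen_only | frame$element == "O")
  wat <- coords(frame, wsel)
  wat_res <- frame$resid[wsel]
  prot <- coords(frame, is_p)
  hit <- grid_within(wat, prot, cutoff)
  length(unique(wat_res[hit]))
}

# For each row of `query`, TRUE if any row of `target` lies within cutoff.
# Cell-list grid over the target points.
grid_within <- function(query, target, cutoff) {
  if (nrow(target) == 0 || nrow(query) == 0)
    return(rep(FALSE, nrow(query)))
  origin <- apply(rbind(query, target), 2, min)
  cell_of <- function(x) floor(sweep(x, 2, origin) / cutoff)
  key_of <- function(cells) paste(cells[, 1], cells[, 2], cells[, 3])
  tc <- cell_of(target)
  buckets <- split(seq_len(nrow(target)), key_of(tc))
  qc <- cell_of(query)
  cut2 <- cutoff^2
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    keys <- paste(qc[i, 1] + offsets[, 1], qc[i, 2] + offsets[, 2],
                  qc[i, 3] + offsets[, 3])
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    d2 <- rowSums(sweep(target[cand, , drop = FALSE], 2, query[i, ])^2)
    out[i] <- any(d2 <= cut2)
  }
  out
}

#' Per-residue shell-water fluctuation across an ensemble
#'
#' For every model, counts the waters with at least one atom within
#' `cutoff` of any atom of the given residue, then returns the mean and
#' unbiased variance of the per-model counts.  The variance is the local
#' solvent density fluctuation commonly used as an effective-hydrophobicity
#' measure: hydrophobic residues carry few, weakly fluctuating waters.
#'
#' @param ensemble a `conformer_ensemble` with >= 2 models.
#' @param residue residue number (optionally `"chain:resid"`).
#' @param cutoff shell cutoff in angstroms.
#' @return list with `mean`, `variance`, and `counts` (per-model).
#' @export
residue_shell_stats <- function(ensemble, residue, cutoff) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (length(ensemble$models) < 2)
    stop("need at least 2 models for a fluctuation statistic")
  counts <- vapply(ensemble$models, function(frame) {
    pick <- if (is.character(residue) && grepl(":", residue)) {
      parts <- strsplit(residue, ":")[[1]]
      frame$chain == parts[1] & frame$resid == as.integer(parts[2])
    } else frame$resid == as.integer(residue)
    sel <- pick & select_atoms(frame, "protein", ensemble$water_names)
    if (!any(sel)) stop("residue not found: ", residue)
    is_w <- select_atoms(frame, "water", ensemble$water_names)
    if (!any(is_w)) return(0L)
    wat <- coords(frame, is_w)
    hit <- grid_within(wat, coords(frame, sel), cutoff)
    length(unique(frame$resid[is_w][hit]))
  }, integer(1))
  list(mean = mean(counts), variance = stats::var(counts), counts = counts)
}
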