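#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of the selected atoms of frame `A` onto
#' frame `B` using the Kabsch SVD construction, restricted to proper
#' rotations (a reflection in the SVD solution is corrected by flipping the
#' smallest singular direction).
#'
#' @param A,B atom data.frames with equal selected-atom counts (>= 3,
#'   non-collinear).
#' @param selection logical mask applied to both frames (default: backbone
#'   N, CA, C).
#' @return list with `rotation` (3x3), `translation` (length 3; the
#'   transform is `x %*% rotation + translation` mapping A onto B), and
#'   `rmsd` (angstroms, over the selection after superposition).
#' @export
kabsch_superpose <- function(A, B, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(A, "backbone")
  xa <- coords(A, selection)
  xb <- coords(B, selection)
  if (nrow(xa) != nrow(xb))
    stop("selected atom counts differ: ", nrow(xa), " vs ", nrow(xb))
  if (nrow(xa) < 3) stop("need at least 3 atoms to superpose")
  ca <- colMeans(xa); cb <- colMeans(xb)
  xa0 <- sweep(xa, 2, ca); xb0 <- sweep(xb, 2, cb)
  H <- crossprod(xa0, xb0)
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    stop("degenerate (collinear) geometry; superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # maps centered A onto centered B (row vectors: x %*% t(R))
  rot <- t(R)
  fitted <- xa0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - xb0)^2)))
  list(rotation = rot, translation = as.numeric(cb - ca %*% rot), rmsd = rmsd)
}

# pairwise superposed RMSD over a selection; symmetric matrix
rmsd_matrix <- function(ensemble, selection = NULL) {
  models <- ensemble$models
  if (is.null(selection)) selection <- select_atoms(models[[1]], "backbone")
  n <- length(models)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <-
        kabsch_superpose(models[[i]], models[[j]], selection)$rmsd
    }
  }
  M
}

#' GROMOS-style conformational clustering
#'
#' Iterative neighbor-count clustering of an ensemble on pairwise
#' superposed RMSD: the model with the most neighbors within `cutoff` (ties
#' broken toward the lowest model index) becomes a cluster center; the
#' center and its neighbors are removed as one cluster; the procedure
#' repeats on the remainder until every model is assigned.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param cutoff RMSD cutoff in angstroms (default 1.0).
#' @param selection logical atom mask for the RMSD (default: main-chain
#'   N, CA, C).
#' @return list of class `cluster_assignment`: `cluster_id` (integer per
#'   model, 1 = most populated found first), `centers` (model indices),
#'   `populations` (fractions summing to 1), `n_clusters`.
#' @export
gromos_cluster <- function(ensemble, cutoff = 1.0, selection = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  n <- length(ensemble$models)
  M <- rmsd_matrix(ensemble, selection)
  remaining <- seq_len(n)
  cluster_id <- integer(n)
  centers <- integer(0)
  k <- 0L
  while (length(remaining) > 0) {
    k <- k + 1L
    sub <- M[remaining, remaining, drop = FALSE]
    neigh <- rowSums(sub <= cutoff)   # includes self
    center <- remaining[which.max(neigh)]  # which.max takes the first (lowest index) on ties
    members <- remaining[sub[which.max(neigh), ] <= cutoff]
    cluster_id[members] <- k
    centers <- c(centers, center)
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(cluster_id, nbins = k)
  structure(list(cluster_id = cluster_id, centers = centers,
                 populations = sizes / n, n_clusters = k),
            class = "cluster_assignment")
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum(m_i |r_i - r_bar|^2) / sum(m_i))` over the selected
#' atoms, with atomic masses from a bundled element table (or unit masses
#' when `mass_weighted = FALSE`).
#'
#' @param frame an atom data.frame.
#' @param selection logical mask (default: protein atoms).
#' @param mass_weighted use atomic masses (default TRUE).
#' @return radius of gyration in angstroms.
#' @export
radius_of_gyration <- function(frame, selection = NULL, mass_weighted = TRUE) {
  if (is.null(selection)) selection <- select_atoms(frame, "protein")
  x <- coords(frame, selection)
  if (nrow(x) == 0) stop("empty selection")
  m <- if (mass_weighted) element_property(frame$element[selection], "mass")
       else rep(1, nrow(x))
  ctr <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, ctr)^2)) / sum(m))
}

#' Distance between two residues
#'
#' @param frame an atom data.frame.
#' @param res_a,res_b residue numbers (optionally `"chain:resid"` strings).
#' @param mode `"CA"` for the alpha-carbon distance, `"closest-heavy"` for
#'   the minimum over all heavy-atom pairs.
#' @return distance in angstroms.
#' @export
residue_distance <- function(frame, res_a, res_b,
                             mode = c("CA", "closest-heavy")) {
  mode <- match.arg(mode)
  pick <- function(spec) {
    if (is.character(spec) && grepl(":", spec)) {
      parts <- strsplit(spec, ":")[[1]]
      frame$chain == parts[1] & frame$resid == as.integer(parts[2])
    } else frame$resid == as.integer(spec)
  }
  sa <- pick(res_a) & select_atoms(frame, "protein")
  sb <- pick(res_b) & select_atoms(frame, "protein")
  if (!any(sa)) stop("residue not found: ", res_a)
  if (!any(sb)) stop("residue not found: ", res_b)
  if (mode == "CA") {
    sa <- sa & frame$name == "CA"
    sb <- sb & frame$name == "CA"
    if (!any(sa) || !any(sb)) stop("CA atom missing in one of the residues")
    xa <- coords(frame, sa)[1, ]
    xb <- coords(frame, sb)[1, ]
    sqrt(sum((xa - xb)^2))
  } else {
    sa <- sa & frame$element != "H"
    sb <- sb & frame$element != "H"
    xa <- coords(frame, sa)
    xb <- coords(frame, sb)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    sqrt(max(min(d2), 0))
  }
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("%d cluster(s); populations: %s\n", x$n_clusters,
              paste(sprintf("%.1f%%", 100 * x$populations), collapse = ", ")))
  invisible(x)
}
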