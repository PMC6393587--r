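# Shared fixture builders and independent brute-force oracles.

# atom data.frame in the package's frame layout
atom_frame <- function(name, resname, resid, xyz, chain = "A",
                       element = substr(name, 1, 1),
                       record = ifelse(resname %in% c("HOH", "WAT", "SOL"),
                                       "HETATM", "ATOM")) {
  data.frame(record = record, serial = seq_along(name), name = name,
             resname = resname, chain = chain, resid = resid,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = element, stringsAsFactors = FALSE)
}

# a frame of k protein atoms at random positions plus waters (1 O atom each)
random_water_frame <- function(n_prot = 15, n_wat = 40, box = 20) {
  p <- matrix(runif(3 * n_prot, 0, box), ncol = 3)
  w <- matrix(runif(3 * n_wat, 0, box), ncol = 3)
  rbind(
    atom_frame(rep("CA", n_prot), rep("ALA", n_prot), seq_len(n_prot), p),
    atom_frame(rep("O", n_wat), rep("HOH", n_wat),
               n_prot + seq_len(n_wat), w, chain = "W"))
}

# O(N^2) oracle: waters with any atom within cutoff of any protein atom
brute_shell_count <- function(frame, cutoff,
                              water_names = c("HOH", "WAT", "SOL")) {
  is_w <- frame$resname %in% water_names
  pw <- as.matrix(frame[is_w, c("x", "y", "z")])
  pp <- as.matrix(frame[!is_w, c("x", "y", "z")])
  hit <- logical(nrow(pw))
  for (i in seq_len(nrow(pw)))
    hit[i] <- any(sqrt(rowSums(sweep(pp, 2, pw[i, ])^2)) <= cutoff)
  length(unique(frame$resid[is_w][hit]))
}

# brute-force H-bond oracle: all donor x acceptor pairs, same criteria
brute_hbonds <- function(frame, donors, acceptors, d_DA = 3.5,
                         angle_min = 150, h_max = 1.25) {
  D <- as.matrix(frame[donors, c("x", "y", "z"), drop = FALSE])
  A <- as.matrix(frame[acceptors, c("x", "y", "z"), drop = FALSE])
  H <- as.matrix(frame[frame$element == "H", c("x", "y", "z"), drop = FALSE])
  have_h <- nrow(H) > 0
  count <- 0L
  for (i in seq_len(nrow(D))) for (j in seq_len(nrow(A))) {
    dij <- sqrt(sum((D[i, ] - A[j, ])^2))
    if (dij > d_DA || dij < 1e-6) next
    if (!have_h) { count <- count + 1L; next }
    hs <- which(sqrt(rowSums(sweep(H, 2, D[i, ])^2)) <= h_max)
    for (k in hs) {
      v1 <- D[i, ] - H[k, ]; v2 <- A[j, ] - H[k, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_min) { count <- count + 1L; break }
    }
  }
  count
}

# independent superposition oracle: coarse Euler-angle grid + Nelder-Mead
# polish of the post-rotation RMSD (centers aligned first)
grid_search_rmsd <- function(xa, xb, step_deg = 20) {
  xa <- sweep(xa, 2, colMeans(xa)); xb <- sweep(xb, 2, colMeans(xb))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((xa %*% rot(ang) - xb)^2)))
  grid <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  best <- c(0, 0, 0); best_v <- obj(best)
  for (a1 in grid) for (a2 in grid[grid <= pi]) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_v) { best_v <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  opt$value
}

# random proper rotation + translation applied to a frame
random_rigid_transform <- function(frame) {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, 0, 10)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% R
  frame$x <- xyz[, 1] + tr[1]
  frame$y <- xyz[, 2] + tr[2]
  frame$z <- xyz[, 3] + tr[3]
  frame
}

# noise-free acquisition used across round-trip tests
quiet_acq <- function(...) acquisition_params(noise_sd = 0, ...)

new_ens <- function(models) conformer_ensemble(models)
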