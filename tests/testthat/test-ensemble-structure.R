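test_that("kabsch_superpose is exact on rigid copies and symmetric", {
  set.seed(21)
  ens <- make_toy_ensemble("compact", n_models = 2, seed = 21)
  A <- ens$models[[1]]
  B <- random_rigid_transform(A)
  expect_lt(kabsch_superpose(A, B)$rmsd, 1e-9)
  C <- ens$models[[2]]
  expect_equal(kabsch_superpose(A, C)$rmsd, kabsch_superpose(C, A)$rmsd,
               tolerance = 1e-9)

  # the returned transform actually maps A onto B
  fit <- kabsch_superpose(A, C)
  sel <- select_atoms(A, "backbone")
  xa <- as.matrix(A[sel, c("x", "y", "z")]) %*% fit$rotation
  xa <- sweep(xa, 2, fit$translation, "+")
  xb <- as.matrix(C[sel, c("x", "y", "z")])
  expect_equal(sqrt(mean(rowSums((xa - xb)^2))), fit$rmsd, tolerance = 1e-9)

  expect_error(kabsch_superpose(A[1:9, ], C, selection = NULL), "differ")
})

test_that("kabsch rmsd matches an independent rotation grid search", {
  set.seed(22)
  for (i in 1:5) {
    xa <- matrix(rnorm(12, 0, 3), 4)
    xb <- matrix(rnorm(12, 0, 3), 4)
    fa <- atom_frame(c("N", "CA", "C", "CA"), rep("GLY", 4), 1:4, xa)
    fb <- atom_frame(c("N", "CA", "C", "CA"), rep("GLY", 4), 1:4, xb)
    mask <- rep(TRUE, 4)
    expect_equal(kabsch_superpose(fa, fb, mask)$rmsd,
                 grid_search_rmsd(xa, xb), tolerance = 1e-3)
  }
})

test_that("gromos_cluster reproduces constructed cluster structure", {
  # all models identical -> one cluster with population 1
  ens <- make_toy_ensemble("compact", n_models = 6, seed = 1, jitter_sd = 0)
  cl <- gromos_cluster(ens)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$populations, 1)
  expect_equal(cl$centers, 1L)  # tie broken toward the lowest index

  # 5 copies of X + 5 of Y with RMSD(X, Y) >> cutoff -> two clusters of 5
  X <- make_toy_ensemble("compact", n_models = 1, seed = 5)$models[[1]]
  Y <- make_toy_ensemble("extended", n_models = 1, seed = 7)$models[[1]]
  two <- new_ens(c(replicate(5, X, simplify = FALSE),
                   replicate(5, Y, simplify = FALSE)))
  cl2 <- gromos_cluster(two)
  expect_equal(cl2$n_clusters, 2L)
  expect_equal(sort(cl2$populations), c(0.5, 0.5))
  expect_equal(cl2$centers[1], 1L)

  # sizes sum to the model count; permuting model order keeps populations
  ext <- make_toy_ensemble("extended", n_models = 8, seed = 9)
  cle <- gromos_cluster(ext)
  expect_equal(sum(cle$populations), 1)
  perm <- new_ens(ext$models[c(5, 2, 8, 1, 7, 3, 6, 4)])
  clp <- gromos_cluster(perm)
  expect_equal(sort(clp$populations), sort(cle$populations))
})

test_that("shell-water grid counting agrees with the brute-force oracle", {
  set.seed(44)
  for (i in 1:100) {
    fr <- random_water_frame(n_prot = sample(5:20, 1),
                             n_wat = sample(10:60, 1),
                             box = runif(1, 10, 30))
    cutoff <- runif(1, 1.5, 6)
    expect_equal(count_shell_waters(fr, cutoff),
                 brute_shell_count(fr, cutoff))
  }
})

test_that("shell-water counting honours constructed geometry and cutoffs", {
  # k waters at exactly 2.0 A, the rest beyond 5 A
  prot <- atom_frame("CA", "ALA", 1, matrix(c(0, 0, 0), 1))
  k <- 4
  near <- matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2, -2, 0, 0), ncol = 3, byrow = TRUE)
  far <- matrix(rnorm(3 * 6, 0, 1), ncol = 3)
  far <- far / sqrt(rowSums(far^2)) * runif(6, 5.5, 9)
  fr <- rbind(prot,
              atom_frame(rep("O", 10), rep("HOH", 10), 1 + 1:10,
                         rbind(near, far), chain = "W"))
  expect_equal(count_shell_waters(fr, 2.8), k)
  # monotone in the cutoff
  expect_lte(count_shell_waters(fr, 2.6), count_shell_waters(fr, 2.8))
  expect_error(count_shell_waters(fr[fr$resname == "HOH", ], 2.8), "protein")
})

test_that("radius_of_gyration matches closed forms", {
  one <- atom_frame("CA", "ALA", 1, matrix(c(1, 2, 3), 1))
  expect_equal(radius_of_gyration(one), 0)
  two <- atom_frame(c("CA", "CA"), c("ALA", "ALA"), 1:2,
                    matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 1.0)
  # 8 unit masses at the corners of a cube with edge 2 -> Rg = sqrt(3)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  eight <- atom_frame(rep("CA", 8), rep("ALA", 8), 1:8, cube)
  expect_equal(radius_of_gyration(eight, mass_weighted = FALSE), sqrt(3))
  expect_error(radius_of_gyration(one, selection = rep(FALSE, 1)), "empty")
})

test_that("sasa matches sphere closed forms", {
  lone <- atom_frame("C", "UNK", 1, matrix(c(0, 0, 0), 1))
  r <- 1.70 + 1.4
  expect_equal(as.numeric(sasa(lone)), 4 * pi * r^2, tolerance = 0.01)

  # far-separated atoms are additive
  pair <- atom_frame(c("C", "O"), c("UNK", "UNK"), 1:2,
                     matrix(c(0, 0, 0, 50, 0, 0), 2, byrow = TRUE))
  expect_equal(as.numeric(sasa(pair)),
               4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.01)

  # two overlapping equal spheres: analytic spherical-cap solution
  d <- 2.5
  both <- atom_frame(c("C", "C"), c("UNK", "UNK"), 1:2,
                     matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE))
  R <- 1.7 + 1.4
  cap <- 2 * pi * R * (R - d / 2)          # buried cap area per sphere
  analytic <- 2 * (4 * pi * R^2 - cap)
  expect_equal(as.numeric(sasa(both)), analytic, tolerance = 0.02)

  expect_error(sasa(atom_frame("Q", "UNK", 1, matrix(0, 1, 3),
                               element = "Q")), "radius")
})

test_that("count_hbonds applies distance and angle criteria", {
  # carboxylate-guanidinium-like fixture: two N-O contacts at 2.9 A with
  # linear N-H...O geometry
  xyz <- rbind(
    c(0, 0, 0),      # O1 acceptor
    c(0, 4, 0),      # O2 acceptor
    c(2.9, 0, 0),    # N1 donor
    c(2.9, 4, 0),    # N2 donor
    c(1.9, 0, 0),    # H on N1, on the N1-O1 axis
    c(1.9, 4, 0))    # H on N2
  fr <- atom_frame(c("OD1", "OD2", "NH1", "NH2", "HH1", "HH2"),
                   c("ASP", "ASP", "ARG", "ARG", "ARG", "ARG"),
                   c(9, 9, 16, 16, 16, 16), xyz,
                   element = c("O", "O", "N", "N", "H", "H"))
  donors <- fr$element == "N"
  acceptors <- fr$element == "O"
  expect_equal(count_hbonds(fr, donors, acceptors), 2L)

  # pulled apart to 6 A: no bonds
  far <- fr
  far$x[far$element %in% c("N", "H")] <- far$x[far$element %in% c("N", "H")] + 3.1
  expect_equal(count_hbonds(far, donors, acceptors), 0L)

  # without hydrogens the heavy-atom distance criterion alone applies
  heavy <- fr[fr$element != "H", ]
  expect_equal(count_hbonds(heavy, heavy$element == "N",
                            heavy$element == "O"), 2L)
  expect_error(count_hbonds(fr, rep(FALSE, nrow(fr)), acceptors), "empty")
})

test_that("count_hbonds matches the brute-force oracle on random fixtures", {
  set.seed(55)
  for (i in 1:100) {
    nD <- sample(2:5, 1); nA <- sample(2:5, 1); nH <- sample(0:6, 1)
    xyz <- matrix(runif(3 * (nD + nA + nH), 0, 8), ncol = 3)
    el <- c(rep("N", nD), rep("O", nA), rep("H", nH))
    fr <- atom_frame(paste0(el, seq_along(el)), rep("UNK", length(el)),
                     seq_along(el), xyz, element = el)
    donors <- fr$element == "N"
    acceptors <- fr$element == "O"
    expect_equal(count_hbonds(fr, donors, acceptors),
                 brute_hbonds(fr, donors, acceptors))
  }
})

test_that("residue_distance supports CA and closest-heavy modes", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 0, 0), c(2.5, 4, 0))
  fr <- atom_frame(c("CA", "CA", "CB", "CB"),
                   c("TRP", "SER", "TRP", "SER"),
                   c(6, 14, 6, 14), xyz, element = c("C", "C", "C", "C"))
  expect_equal(residue_distance(fr, 6, 6, "CA"), 0)
  expect_equal(residue_distance(fr, 6, 14, "CA"), 5.0)
  # closest-heavy is the minimum over all heavy-atom pairs
  all_pairs <- c(5, sqrt(2.5^2 + 16), sqrt(4 + 16), sqrt(1.5^2 + 16))
  expect_equal(residue_distance(fr, 6, 14, "closest-heavy"), min(all_pairs))
  expect_lte(residue_distance(fr, 6, 14, "closest-heavy"),
             residue_distance(fr, 6, 14, "CA"))
  expect_error(residue_distance(fr, 6, 99), "not found")
})

test_that("residue_shell_stats summarizes per-model counts", {
  ens <- make_toy_ensemble("compact", n_models = 4, n_waters = 30, seed = 6)
  same <- new_ens(rep(ens$models[1], 3))
  st <- residue_shell_stats(same, 10, 4.0)
  expect_equal(st$variance, 0)

  # constructed two-model counts {2, 4} -> mean 3, variance 2
  prot <- atom_frame("CA", "ALA", 1, matrix(c(0, 0, 0), 1))
  wat_at <- function(d) atom_frame(rep("O", length(d)), rep("HOH", length(d)),
                                   1 + seq_along(d),
                                   cbind(d, 0, 0), chain = "W")
  m1 <- rbind(prot, wat_at(c(2, 3, 9, 9.5)))
  m2 <- rbind(prot, wat_at(c(1, 2, 3, 3.5)))
  two <- new_ens(list(m1, m2))
  st2 <- residue_shell_stats(two, 1, 4.0)
  expect_equal(st2$counts, c(2L, 4L))
  expect_equal(st2$mean, 3)
  expect_equal(st2$variance, 2)

  # oracle agreement on random fixtures
  set.seed(66)
  for (i in 1:20) {
    fr1 <- random_water_frame(8, 25, 15)
    fr2 <- random_water_frame(8, 25, 15)
    fr2$resid <- fr1$resid  # same topology, new coordinates
    e <- new_ens(list(fr1, fr2))
    st <- residue_shell_stats(e, 3, 3.0)
    brute <- vapply(list(fr1, fr2), function(f) {
      sub <- f[f$resid == 3 & f$resname != "HOH", ]
      wat <- f[f$resname == "HOH", ]
      hit <- vapply(seq_len(nrow(wat)), function(j)
        any(sqrt((sub$x - wat$x[j])^2 + (sub$y - wat$y[j])^2 +
                   (sub$z - wat$z[j])^2) <= 3.0), logical(1))
      length(unique(wat$resid[hit]))
    }, numeric(1))
    expect_equal(st$counts, as.integer(brute))
  }
})

test_that("geometric measures are invariant under rigid motion", {
  set.seed(77)
  ens <- make_toy_ensemble("mixed", n_models = 3, n_waters = 20, seed = 77)
  fr <- ens$models[[1]]
  for (i in 1:5) {
    moved <- random_rigid_transform(fr)
    expect_equal(radius_of_gyration(moved), radius_of_gyration(fr),
                 tolerance = 1e-6)
    expect_equal(count_shell_waters(moved, 3.5), count_shell_waters(fr, 3.5))
    expect_equal(as.numeric(sasa(moved, n_sphere_points = 240)),
                 as.numeric(sasa(fr, n_sphere_points = 240)), tolerance = 0.02)
    expect_equal(residue_distance(moved, 2, 15, "closest-heavy"),
                 residue_distance(fr, 2, 15, "closest-heavy"),
                 tolerance = 1e-6)
  }
})
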