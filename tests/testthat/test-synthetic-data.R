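test_that("melting profiles honour archetype shape invariants", {
  Tg <- seq(-80, 5, by = 0.5)

  folded <- make_melting_profile("folded")
  nf <- profile_n(folded, Tg)
  expect_true(all(diff(nf) >= 0))
  expect_equal(profile_n(folded, 5), 1.0)
  expect_equal(profile_n(folded, 0), 1.0)
  # exactly zero slope across the default plateau -48..-26 C
  plateau_T <- seq(-48, -26, by = 0.25)
  expect_true(all(profile_n(folded, plateau_T) == profile_n(folded, -48)))

  dis <- make_melting_profile("disordered")
  nd <- profile_n(dis, Tg)
  expect_true(all(diff(nd) >= 0))
  above <- Tg > dis$T_onset & Tg < 0
  expect_true(all(diff(nd[above]) > 0))  # strictly increasing above onset
})

test_that("profile invariants hold over random parameter draws", {
  set.seed(101)
  for (i in 1:40) {
    arch <- sample(c("folded", "intermediate", "disordered"), 1)
    ov <- if (arch == "disordered") {
      list(T_onset = runif(1, -60, -35), n_first = runif(1, 0.05, 0.5),
           onset_width = runif(1, 2, 8))
    } else {
      ps <- runif(1, -50, -35)
      list(T_onset = ps - runif(1, 3, 10), plateau_start = ps,
           plateau_end = ps + runif(1, 8, 20),
           n_first = runif(1, 0.05, 0.5))
    }
    if (!is.null(ov$plateau_end) && ov$plateau_end >= 0) next
    pf <- make_melting_profile(arch, ov, seed = i)
    Tg <- seq(-79.5, 4.5, by = 0.5)
    n <- profile_n(pf, Tg)
    expect_true(all(n >= 0 & n <= 1))
    expect_true(all(diff(n) >= -1e-12))
    expect_true(all(n[Tg >= 0] == 1))
    if (arch == "disordered") {
      above <- Tg > pf$T_onset & Tg < 0
      expect_true(all(diff(n[above]) > 0))
    } else {
      inside <- Tg >= pf$plateau_start & Tg <= pf$plateau_end
      expect_true(max(n[inside]) == min(n[inside]))
    }
  }
})

test_that("profile constructor rejects invalid requests", {
  expect_error(make_melting_profile("disordered", list(plateau_start = -40)),
               "plateau")
  expect_error(make_melting_profile("folded", list(plateau_start = -20,
                                                   plateau_end = -40)),
               "unordered")
  expect_error(make_melting_profile("folded", list(n_first = 1.2)), "n_first")
  expect_error(make_melting_profile("folded", list(bogus = 1)), "unknown")
})

test_that("synthesize_fid obeys the two-component Curie-scaled model", {
  acq <- quiet_acq()
  # no mobile component: the 200 us - 1 ms window is empty
  fid0 <- synthesize_fid(0, 233.15, acq)
  tail0 <- fid0$amplitudes[fid0$times >= 200]
  A_solid <- acq$curie_scale * (1 + acq$protein_frac) / 233.15
  expect_true(all(abs(tail0) < 1e-9 * A_solid))

  # Curie law: slow-component amplitude ratio is the inverse temperature ratio
  f1 <- synthesize_fid(1, 223.15, acq)
  f2 <- synthesize_fid(1, 263.15, acq)
  a1 <- fit_slow_component(f1)$A0
  a2 <- fit_slow_component(f2)$A0
  expect_equal(a1 / a2, 263.15 / 223.15, tolerance = 1e-9)

  # round trip: the fit recovers the generator amplitude to 1e-6 relative
  f <- synthesize_fid(0.5, 253.15, acq)
  fit <- fit_slow_component(f)
  expect_equal(fit$A0, acq$curie_scale * 0.5 / 253.15, tolerance = 1e-6)
  expect_equal(fit$tau, acq$T2star_mobile, tolerance = 1e-4)

  # dead-time samples are flagged invalid
  expect_true(all(fid0$times[!fid0$valid] < acq$dead_time))
  expect_error(synthesize_fid(1.5, 253.15, acq), "n_mobile")
  expect_error(acquisition_params(noise_sd = -1), "noise_sd")
})

test_that("synthesize_series is complete, deterministic and invertible", {
  pf <- make_melting_profile("folded")
  Tg <- seq(-80, -1, by = 1)
  acq <- acquisition_params(noise_sd = 0.01)
  s1 <- synthesize_series(pf, Tg, acq, seed = 7)
  expect_length(s1$signals, 80)
  expect_true(s1$reference$is_reference)
  expect_gt(s1$reference$temperature, 273.15)

  s2 <- synthesize_series(pf, Tg, acq, seed = 7)
  expect_identical(s1, s2)  # bit-identical under the same seed

  # zero-noise round trip reproduces the ground truth at every grid point
  dis <- make_melting_profile("disordered")
  s0 <- synthesize_series(dis, Tg, quiet_acq(), seed = 1)
  dg <- build_melting_diagram(s0$signals, s0$reference)
  expect_true(all(abs(dg$n - profile_n(dis, dg$T_C)) <= 1e-6))

  expect_error(synthesize_series(pf, numeric(0)), "empty")
  expect_error(synthesize_series(pf, c(-10, -20)), "increasing")
})

test_that("recovered n is unbiased above the onset under 1% noise", {
  # 50 seeds, noise at 1% of the reference amplitude; compare the mean
  # recovered n at each temperature with the truth.  Below the onset the
  # truth is exactly 0 and the non-negativity clip makes the estimator
  # one-sided there, so the unbiasedness check applies above the onset.
  # The per-temperature standardized biases are combined into a chi-squared
  # statistic (a joint per-temperature 2-SE band would false-alarm on ~30%
  # of seed sets for a perfectly unbiased estimator).
  pf <- make_melting_profile("folded")
  Tg <- seq(-60, -10, by = 5)
  acq <- acquisition_params(noise_sd = 0.01)
  truth <- profile_n(pf, Tg)
  n_rec <- matrix(NA_real_, 50, length(Tg))
  for (s in 1:50) {
    ser <- synthesize_series(pf, Tg, acq, seed = s)
    n_rec[s, ] <- build_melting_diagram(ser$signals, ser$reference)$n
  }
  above <- truth > 0
  bias <- colMeans(n_rec)[above] - truth[above]
  mc_se <- apply(n_rec, 2, stats::sd)[above] / sqrt(50)
  z <- bias / mc_se
  expect_lte(sum(z^2), stats::qchisq(0.999, df = length(z)))
  expect_true(all(abs(z) <= 4))  # no gross systematic bias anywhere
})

test_that("bit-identical FID output under a repeated seed", {
  acq <- acquisition_params(noise_sd = 0.02)
  f1 <- synthesize_fid(0.3, 243.15, acq, seed = 99)
  f2 <- synthesize_fid(0.3, 243.15, acq, seed = 99)
  expect_identical(f1, f2)
})

test_that("toy ensembles produce the stated cluster structure", {
  comp <- make_toy_ensemble("compact", n_models = 10, seed = 3)
  cl <- gromos_cluster(comp, cutoff = 1.0)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$populations, 1.0)

  ext <- make_toy_ensemble("extended", n_models = 10, seed = 3)
  cle <- gromos_cluster(ext, cutoff = 1.0)
  expect_gte(cle$n_clusters, 5L)

  mix <- make_toy_ensemble("mixed", n_models = 10, compact_frac = 0.5, seed = 3)
  clm <- gromos_cluster(mix, cutoff = 1.0)
  expect_gte(clm$n_clusters, 2L)
  expect_gte(max(clm$populations), 0.5)  # the compact half forms one cluster

  # no waters requested -> no shell waters at any cutoff
  expect_equal(count_shell_waters(comp$models[[1]], 2.8), 0L)
  waters <- make_toy_ensemble("compact", n_models = 2, n_waters = 25, seed = 4)
  f <- waters$models[[1]]
  expect_equal(sum(f$resname == "HOH"), 25)
  expect_error(make_toy_ensemble("compact", n_models = 0), "n_models")
})
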