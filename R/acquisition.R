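#' Acquisition parameters for synthetic wide-line FID records
#'
#' Bundles the instrument-level constants of a wide-line 1H-NMR free
#' induction decay (FID) acquisition.  Times are in microseconds.  The FID of
#' a frozen protein solution is modelled as two Gaussian decays: a fast
#' "solid" component (ice and protein protons, `T2 < 100 us`) and a slow
#' component from rotationally mobile water (`T2* > 100 us`, read in the
#' 200 us - 1 ms window).  Amplitudes follow the Curie law
#' `A = curie_scale * N / T`: equilibrium magnetization, and hence the t = 0
#' amplitude, is proportional to the number of contributing protons divided
#' by the absolute temperature.
#'
#' @param dead_time receiver dead time in us (default 7; instrument spec
#'   6-8 us); samples earlier than this carry no valid signal.
#' @param sample_dt sampling interval in us.
#' @param t_max last sampled time in us (>= 1000 so the full 200 us - 1 ms
#'   analysis window is covered).
#' @param T2_solid Gaussian decay constant of the fast component, us
#'   (< 100 us).
#' @param T2star_mobile Gaussian decay constant of the mobile-water
#'   component, us (> 100 us; field-inhomogeneity dominated, hence T2*).
#' @param noise_sd additive Gaussian noise, amplitude units.  With the
#'   default `curie_scale` the fully liquid reference signal has unit
#'   amplitude, so `noise_sd = 0.01` is 1 percent of the reference.
#' @param curie_scale the constant `c` in `A = c * n / T`, amplitude-kelvin.
#'   The default 278.15 gives the +5 C reference signal amplitude 1.
#' @param protein_frac fixed protein-proton contribution folded into the
#'   solid component, as a fraction of the total proton budget.
#' @return object of class `acquisition_params`.
#' @export
acquisition_params <- function(dead_time = 7, sample_dt = 2, t_max = 1000,
                               T2_solid = 25, T2star_mobile = 400,
                               noise_sd = 0.01, curie_scale = 278.15,
                               protein_frac = 0.05) {
  if (dead_time < 0) stop("dead_time must be non-negative")
  if (T2_solid >= 100) stop("T2_solid must be < 100 us (fast solid component)")
  if (T2star_mobile <= 100) stop("T2star_mobile must be > 100 us (mobile water)")
  if (t_max < 1000) stop("t_max must be >= 1000 us to cover the analysis window")
  if (sample_dt <= 0) stop("sample_dt must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (curie_scale <= 0) stop("curie_scale must be positive")
  structure(list(dead_time = dead_time, sample_dt = sample_dt, t_max = t_max,
                 T2_solid = T2_solid, T2star_mobile = T2star_mobile,
                 noise_sd = noise_sd, curie_scale = curie_scale,
                 protein_frac = protein_frac),
            class = "acquisition_params")
}

new_fid_signal <- function(times, amplitudes, temperature, is_reference, acq) {
  if (any(diff(times) <= 0)) stop("FID times must be strictly increasing")
  if (temperature <= 0) stop("temperature must be > 0 K")
  structure(list(times = times, amplitudes = amplitudes,
                 valid = times >= acq$dead_time,
                 temperature = temperature,
                 is_reference = isTRUE(is_reference),
                 acquisition = acq),
            class = "fid_signal")
}

#' Synthesize one two-component FID record
#'
#' Generates `A_solid * exp(-(t/T2_solid)^2) + A_mobile * exp(-(t/T2s)^2)`
#' plus additive Gaussian noise, where `A_mobile = c * n_mobile / T` and
#' `A_solid = c * ((1 - n_mobile) + protein_frac) / T` (Curie scaling of
#' both components; the protein protons relax with the fast component).
#' Samples recorded before the receiver dead time are flagged invalid.
#'
#' @param n_mobile mobile-water fraction in `[0, 1]`.
#' @param temperature sample temperature in kelvin.
#' @param acq an [acquisition_params()] object.
#' @param seed integer seed for the noise draw.
#' @param is_reference mark the record as a fully liquid reference.
#' @return object of class `fid_signal` with fields `times` (us),
#'   `amplitudes`, `valid`, `temperature` (K), `is_reference`, `acquisition`.
#' @examples
#' acq <- acquisition_params(noise_sd = 0)
#' fid <- synthesize_fid(0.5, 233.15, acq)
#' @export
synthesize_fid <- function(n_mobile, temperature, acq = acquisition_params(),
                           seed = 1L, is_reference = FALSE) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (n_mobile < 0 || n_mobile > 1) stop("n_mobile must lie in [0, 1]")
  if (temperature <= 0) stop("temperature must be > 0 K")
  times <- seq(acq$sample_dt, acq$t_max, by = acq$sample_dt)
  A_mobile <- acq$curie_scale * n_mobile / temperature
  A_solid <- acq$curie_scale * ((1 - n_mobile) + acq$protein_frac) / temperature
  amp <- A_solid * exp(-(times / acq$T2_solid)^2) +
    A_mobile * exp(-(times / acq$T2star_mobile)^2)
  if (acq$noise_sd > 0) {
    amp <- amp + withr_seed(seed, stats::rnorm(length(times), 0, acq$noise_sd))
  }
  new_fid_signal(times, amp, temperature, is_reference, acq)
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a full melting series of FID records
#'
#' One FID per temperature of `T_grid`, with the mobile fraction taken from
#' the ground-truth profile, plus exactly one fully liquid reference record
#' (`n = 1`) above 0 C.  Deterministic given `seed`: per-signal noise seeds
#' are derived from it.
#'
#' @param profile a [make_melting_profile()] object.
#' @param T_grid strictly increasing temperatures in degrees C, within
#'   `[-80, 0)`.  Default: 1-degree grid from -80 to -1 C (matching the
#'   +-1 C experimental temperature scale).
#' @param acq an [acquisition_params()] object.
#' @param seed integer master seed.
#' @param ref_T_C temperature of the reference record, degrees C (> 0).
#' @return list with elements `signals` (list of `fid_signal`, one per grid
#'   point) and `reference` (a single reference `fid_signal`).
#' @export
synthesize_series <- function(profile, T_grid = seq(-80, -1, by = 1),
                              acq = acquisition_params(), seed = 1L,
                              ref_T_C = 5) {
  stopifnot(inherits(profile, "melting_profile"))
  if (length(T_grid) == 0) stop("empty temperature grid")
  if (any(T_grid < -80) || any(T_grid >= 0))
    stop("T_grid must lie within [-80, 0) degrees C")
  if (any(diff(T_grid) <= 0)) stop("T_grid must be strictly increasing")
  if (ref_T_C <= 0) stop("the reference must be recorded above 0 C")
  n_true <- profile_n(profile, T_grid)
  # small deterministic per-signal seeds, kept within 32-bit integer range
  sub_seeds <- (as.double(seed) * 1000003 + seq_along(T_grid) * 7919) %% 2147483629 + 1
  signals <- lapply(seq_along(T_grid), function(i) {
    synthesize_fid(n_true[i], T_grid[i] + 273.15, acq, seed = sub_seeds[i])
  })
  ref_seed <- (as.double(seed) * 1000003 + 999983) %% 2147483629 + 1
  reference <- synthesize_fid(1, ref_T_C + 273.15, acq, seed = ref_seed,
                              is_reference = TRUE)
  list(signals = signals, reference = reference)
}

#' @export
print.fid_signal <- function(x, ...) {
  cat(sprintf("FID record: %d samples, %.1f K%s, dead time %.1f us\n",
              length(x$times), x$temperature,
              if (x$is_reference) " (reference)" else "",
              x$acquisition$dead_time))
  invisible(x)
}
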