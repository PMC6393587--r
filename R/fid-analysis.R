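#' Fit the slowly relaxing (mobile-water) FID component
#'
#' Least-squares fit of a single Gaussian decay `A * exp(-(t/tau)^2)` to the
#' FID samples inside the analysis window (default 200 us - 1 ms, the region
#' where ice and protein protons have fully relaxed and only mobile water
#' contributes).  `A0` is the signal intensity extrapolated to zero time,
#' which by the Curie law is proportional to the number of mobile protons
#' over temperature.
#'
#' The fit uses variable projection: for a fixed decay constant `tau` the
#' amplitude is linear and solved in closed form, so only a 1-D minimization
#' over `tau` remains.  This is robust on noise-free data (where generic
#' nonlinear least squares stalls on a zero residual) and fast enough for
#' thousands of records.
#'
#' @param fid a `fid_signal`.
#' @param window numeric length-2, fit window in us; must start after the
#'   dead time.
#' @param tau_range search range for the decay constant, us.  The lower
#'   bound defaults to 120 us: mobile water relaxes with `T2* > 100 us`, and
#'   allowing faster decays lets a noise-only tail be fitted by an
#'   arbitrarily large amplitude hiding at the window edge.
#' @param tau optional fixed decay constant, us; when given only the
#'   (linear) amplitude is fitted.  Used by [build_melting_diagram()] to
#'   share the reference record's `tau` across low-signal records, which
#'   keeps the amplitude estimate unbiased when the mobile fraction is
#'   near zero.
#' @return object of class `slow_component_fit`: list with `A0` (>= 0),
#'   `tau` (us), `A0_se` (standard error from the linear step), `window`,
#'   `residual_rms`, `n_points`.
#' @examples
#' acq <- acquisition_params(noise_sd = 0)
#' fit_slow_component(synthesize_fid(0.5, 253.15, acq))
#' @export
fit_slow_component <- function(fid, window = c(200, 1000),
                               tau_range = c(120, 5000), tau = NULL) {
  stopifnot(inherits(fid, "fid_signal"))
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be an increasing pair of times in us")
  if (window[1] < fid$acquisition$dead_time)
    stop("fit window must lie entirely after the receiver dead time")
  sel <- fid$valid & fid$times >= window[1] & fid$times <= window[2]
  if (sum(sel) < 8)
    stop("too few valid samples in the fit window (", sum(sel), " < 8)")
  t <- fid$times[sel]
  y <- fid$amplitudes[sel]

  # residual sum of squares for a given tau, amplitude solved linearly
  rss_for <- function(tau) {
    g <- exp(-(t / tau)^2)
    a <- sum(y * g) / sum(g * g)
    sum((y - a * g)^2)
  }
  if (is.null(tau)) {
    opt <- stats::optimize(rss_for, interval = tau_range, tol = 1e-7)
    tau <- opt$minimum
  }
  g <- exp(-(t / tau)^2)
  sg2 <- sum(g * g)
  A0 <- sum(y * g) / sg2
  rss <- sum((y - A0 * g)^2)
  dof <- length(t) - 2L
  A0_se <- if (dof > 0) sqrt(max(rss, 0) / dof / sg2) else NA_real_
  if (!is.finite(A0))
    stop("slow-component fit did not converge (non-finite amplitude); ",
         "window ", window[1], "-", window[2], " us, ", length(t), " points")
  structure(list(A0 = max(A0, 0), tau = tau, A0_se = A0_se,
                 window = window, residual_rms = sqrt(rss / length(t)),
                 n_points = length(t)),
            class = "slow_component_fit")
}

#' Mobile-water fraction from a slow-component fit
#'
#' Normalizes the extrapolated zero-time amplitude against the fully liquid
#' reference record.  Because the equilibrium magnetization follows the
#' Curie law (`M_0 = n * B_0 / T`, amplitude proportional to proton count
#' over temperature), the default applies the 1/T correction:
#' `n = (A0 * T) / (A0_ref * T_ref)`.  Set `curie_correction = FALSE` to
#' normalize raw amplitudes instead.
#'
#' Values above 1 indicate a calibration problem and are returned as-is
#' (with a warning), never clipped; negative values cannot occur since
#' `A0 >= 0`.
#'
#' @param fit a [fit_slow_component()] result for the sample record.
#' @param temperature sample temperature, K.
#' @param ref_fit fit of the fully liquid reference record.
#' @param ref_temperature reference temperature, K.
#' @param curie_correction apply the 1/T amplitude correction (default TRUE).
#' @return the fraction `n >= 0`, with attribute `se` (propagated standard
#'   error from the fit).
#' @export
mobile_fraction <- function(fit, temperature, ref_fit, ref_temperature,
                            curie_correction = TRUE) {
  stopifnot(inherits(fit, "slow_component_fit"),
            inherits(ref_fit, "slow_component_fit"))
  if (temperature <= 0 || ref_temperature <= 0)
    stop("temperatures must be > 0 K")
  if (ref_fit$A0 == 0)
    stop("reference amplitude is zero; cannot normalize")
  scale <- if (curie_correction) temperature / ref_temperature else 1
  n <- fit$A0 * scale / ref_fit$A0
  se <- if (is.na(fit$A0_se)) NA_real_ else fit$A0_se * scale / ref_fit$A0
  if (n > 1 + 3 * max(se, 0, na.rm = TRUE) && n > 1.001)
    warning(sprintf("mobile fraction %.4f exceeds 1: check normalization", n))
  attr(n, "se") <- se
  n
}

#' Build a melting diagram from a series of FID records
#'
#' Fits the slow component of every record, normalizes against the
#' reference, and assembles the per-temperature table of mobile-water
#' fraction `n` (and hydration `h = n * m_water / m_protein` when sample
#' masses are given).  The fundamental-temperature and activation-energy
#' columns are filled from the temperature alone (see
#' [fundamental_temperature()] and [activation_energy()]); the smoothed
#' derivative column is added by [derivative_melting()].
#'
#' Records sharing a temperature are averaged with inverse-variance weights
#' (a message reports how many were merged).
#'
#' @param signals list of `fid_signal` records (>= 3 temperatures).
#' @param reference a fully liquid `fid_signal` with `is_reference = TRUE`.
#' @param masses optional `list(m_water =, m_protein =)` sample masses (any
#'   common unit); when absent the `h` column is `NA`.
#' @param window fit window in us.
#' @param curie_correction passed to [mobile_fraction()].
#' @param share_tau fit the decay constant on the (high signal-to-noise)
#'   reference only and reuse it for every sample record (default TRUE).
#'   The mobile-water decay is dominated by static field inhomogeneity and
#'   so is essentially temperature-independent; sharing `tau` makes the
#'   per-record amplitude fit linear and unbiased even where the mobile
#'   fraction is near zero.
#' @return a `data.frame` of class `melting_diagram`, sorted by temperature,
#'   with columns `T_C`, `T_K`, `T_fn`, `E_a_kJ_mol`, `n`, `n_se`, `h`,
#'   `dn_dTfn` (the last `NA` until [derivative_melting()] is applied).
#' @export
build_melting_diagram <- function(signals, reference, masses = NULL,
                                  window = c(200, 1000),
                                  curie_correction = TRUE,
                                  share_tau = TRUE) {
  if (length(signals) < 3)
    stop("need at least 3 temperatures to build a melting diagram")
  if (missing(reference) || !inherits(reference, "fid_signal"))
    stop("a reference FID record is required")
  if (!reference$is_reference)
    stop("the supplied reference record is not flagged is_reference")
  if (!is.null(masses)) {
    if (!all(c("m_water", "m_protein") %in% names(masses)))
      stop("masses must provide m_water and m_protein")
    if (masses$m_water <= 0 || masses$m_protein <= 0)
      stop("masses must be positive")
  }
  ref_fit <- fit_slow_component(reference, window)
  tau_shared <- if (share_tau) ref_fit$tau else NULL
  temps <- vapply(signals, function(s) s$temperature, numeric(1))
  n <- n_se <- numeric(length(signals))
  for (i in seq_along(signals)) {
    fit <- fit_slow_component(signals[[i]], window, tau = tau_shared)
    ni <- suppressWarnings(
      mobile_fraction(fit, temps[i], ref_fit, reference$temperature,
                      curie_correction))
    n[i] <- as.numeric(ni)
    n_se[i] <- attr(ni, "se")
  }
  # merge duplicate temperatures by inverse-variance weighting
  if (anyDuplicated(temps)) {
    grp <- match(temps, unique(temps))
    message(length(temps) - length(unique(temps)),
            " duplicate-temperature record(s) averaged")
    w <- ifelse(is.finite(n_se) & n_se > 0, 1 / n_se^2, 1)
    n <- as.numeric(tapply(n * w, grp, sum) / tapply(w, grp, sum))
    n_se <- as.numeric(sqrt(1 / tapply(w, grp, sum)))
    temps <- unique(temps)
  }
  ord <- order(temps)
  T_K <- temps[ord]
  T_C <- T_K - 273.15
  h <- if (is.null(masses)) rep(NA_real_, length(T_C))
       else n[ord] * masses$m_water / masses$m_protein
  out <- data.frame(T_C = T_C, T_K = T_K,
                    T_fn = fundamental_temperature(T_C),
                    E_a_kJ_mol = activation_energy(T_C),
                    n = n[ord], n_se = n_se[ord], h = h,
                    dn_dTfn = NA_real_)
  class(out) <- c("melting_diagram", "data.frame")
  out
}

#' Mobile waters per protein molecule
#'
#' Converts hydration `h` (g water per g protein) into a count of mobile
#' water molecules per protein molecule:
#' `N_w = h * M_protein / M_water`.
#'
#' @param h hydration, g water / g protein.
#' @param protein_molar_mass protein molar mass, g/mol.
#' @param water_molar_mass water molar mass, g/mol (default 18.015).
#' @return number of waters per protein molecule.
#' @examples
#' waters_per_protein(0.4151, 2171)   # ~50 waters for a 20-residue miniprotein
#' @export
waters_per_protein <- function(h, protein_molar_mass,
                               water_molar_mass = 18.015) {
  if (protein_molar_mass <= 0 || water_molar_mass <= 0)
    stop("molar masses must be positive")
  if (any(h < 0)) stop("hydration h must be non-negative")
  h * protein_molar_mass / water_molar_mass
}
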