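#' Normalized fundamental temperature
#'
#' Absolute temperature divided by the melting point of ice:
#' `T_fn = (T_C + 273.15) / 273.15`.  This dimensionless scale anchors the
#' melting diagram at `T_fn = 1` for 0 degrees C.
#'
#' @param T_C temperature in degrees Celsius (vectorized).
#' @return dimensionless fundamental temperature.
#' @examples
#' fundamental_temperature(c(0, -41, -28))
#' @export
fundamental_temperature <- function(T_C) {
  if (any(T_C <= -273.15)) stop("temperature below absolute zero")
  (T_C + 273.15) / 273.15
}

#' Activation-energy scale of the melting diagram
#'
#' The potential barrier that must be overcome to mobilize a water molecule,
#' on a linear scale anchored by the melting heat of ice:
#' `E_a = 6.01 kJ/mol * T_fn`, so that `E_a(0 C) = 6.01 kJ/mol` exactly.
#'
#' @param T_C temperature in degrees Celsius (vectorized).
#' @param E_a_0C anchor value at 0 degrees C, kJ/mol.
#' @return activation energy in kJ/mol.
#' @examples
#' activation_energy(c(0, -35, -50))   # 6.01, 5.24, 4.91
#' @export
activation_energy <- function(T_C, E_a_0C = 6.01) {
  E_a_0C * fundamental_temperature(T_C)
}

#' Smoothed derivative of the melting diagram
#'
#' Fills the `dn_dTfn` column with a local-polynomial (quadratic) derivative
#' of `n` with respect to `T_fn`, computed over a centered window of odd
#' width (Savitzky-Golay style, implemented by windowed quadratic
#' regression so non-uniform grids are handled exactly).  Points within half
#' a window of either end use one-sided stencils: the quadratic is fitted on
#' the first (last) `window` rows and differentiated at the point.
#'
#' The derivative is exact for locally quadratic `n(T_fn)`, so a constant
#' series gives exactly zero slope and a linear series returns its slope.
#'
#' @param diagram a `melting_diagram` (>= 5 rows, strictly increasing
#'   `T_fn`).
#' @param window odd window width in points (default 5).
#' @return the diagram with `dn_dTfn` filled.
#' @export
derivative_melting <- function(diagram, window = 5) {
  stopifnot(inherits(diagram, "melting_diagram"))
  m <- nrow(diagram)
  if (m < 5) stop("need at least 5 rows to differentiate")
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (window > m) stop("window wider than the series")
  if (any(diff(diagram$T_fn) <= 0)) stop("T_fn must be strictly increasing")
  x <- diagram$T_fn
  y <- diagram$n
  half <- (window - 1L) / 2L
  d <- numeric(m)
  for (i in seq_len(m)) {
    lo <- max(1L, min(i - half, m - window + 1L))
    idx <- lo:(lo + window - 1L)
    xc <- x[idx] - x[i]            # center on the evaluation point
    fit <- stats::lm.fit(cbind(1, xc, xc^2), y[idx])
    d[i] <- fit$coefficients[2]    # derivative at xc = 0
  }
  diagram$dn_dTfn <- d
  diagram
}

#' Detect the zero-derivative plateau of a melting diagram
#'
#' Folded proteins show a temperature range where no additional water
#' mobilizes: `dn/dT_fn ~ 0` between the end of the first thaw and the final
#' rise.  This routine locates that plateau.
#'
#' Procedure: (1) the first-thaw onset is the first row where `n` exceeds
#' `onset_frac` of its value near -20 C; (2) the peak melting slope is the
#' largest `dn/dT_fn` among sub-zero rows from the onset on; (3) maximal
#' contiguous runs of rows with `|dn/dT_fn| <= slope_frac * peak` and
#' `T_fn` span `>= min_width_Tfn` are candidate plateaus; the longest run
#' wins (ties go to the colder run, since the first thaw precedes the
#' plateau).  When no run qualifies the diagram has no plateau
#' (`found = FALSE`), the signature of a disordered protein.
#'
#' Bound uncertainties default to `grid spacing / sqrt(12)` on the `T_fn`
#' scale (a uniform-error model for locating a breakpoint on a grid).
#'
#' @param diagram a `melting_diagram` with `dn_dTfn` filled.
#' @param slope_frac plateau slope threshold as a fraction of the peak
#'   melting slope (default 0.05).
#' @param min_width_Tfn minimal plateau width on the `T_fn` scale
#'   (default 0.02, about 5.5 degrees C).
#' @param onset_frac fraction of the near--20 C mobile fraction that defines
#'   the first-thaw onset (default 0.10).
#' @param zero_tol absolute floor on the slope threshold, so a numerically
#'   flat diagram (peak slope at rounding level) still counts as a plateau.
#' @return object of class `plateau_result`: list with `found`, `T_fno`,
#'   `T_fne` (fundamental temperatures of plateau begin/end), `T_fno_C`,
#'   `T_fne_C`, `se_bounds`, and `HeR`/`se_HeR` set to `NA` until
#'   [heterogeneity_ratio()] is applied.
#' @export
detect_plateau <- function(diagram, slope_frac = 0.05, min_width_Tfn = 0.02,
                           onset_frac = 0.10, zero_tol = 1e-9) {
  stopifnot(inherits(diagram, "melting_diagram"))
  if (all(is.na(diagram$dn_dTfn)))
    stop("derivative column is empty; run derivative_melting() first")
  sub0 <- diagram$T_C < 0
  d <- diagram[sub0, , drop = FALSE]
  # reference level for the onset: n at the row closest to -20 C
  i20 <- which.min(abs(d$T_C - (-20)))
  onset_level <- onset_frac * d$n[i20]
  onset <- which(d$n > onset_level)[1]
  if (is.na(onset)) {
    return(new_plateau_result(found = FALSE, se_bounds = NA_real_))
  }
  rows <- onset:nrow(d)
  peak <- max(d$dn_dTfn[rows])
  if (!is.finite(peak) || peak <= 0) {
    # degenerate: nothing melts after onset -> whole tail is flat
    peak <- Inf
  }
  flat <- abs(d$dn_dTfn[rows]) <= max(slope_frac * peak, zero_tol)
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- rows[starts[k]]; i1 <- rows[ends[k]]
    if (d$T_fn[i1] - d$T_fn[i0] < min_width_Tfn) next
    if (is.null(best) || (i1 - i0) > (best[2] - best[1]))
      best <- c(i0, i1)  # strict '>' keeps the colder run on ties
  }
  grid_step <- stats::median(diff(d$T_fn))
  se_b <- grid_step / sqrt(12)
  if (is.null(best)) {
    return(new_plateau_result(found = FALSE, se_bounds = se_b))
  }
  new_plateau_result(found = TRUE,
                     T_fno = d$T_fn[best[1]], T_fne = d$T_fn[best[2]],
                     T_fno_C = d$T_C[best[1]], T_fne_C = d$T_C[best[2]],
                     se_bounds = se_b)
}

new_plateau_result <- function(found, T_fno = NA_real_, T_fne = NA_real_,
                               T_fno_C = NA_real_, T_fne_C = NA_real_,
                               se_bounds = NA_real_,
                               HeR = NA_real_, se_HeR = NA_real_) {
  if (found && !(T_fno < T_fne || T_fno == T_fne))
    stop("plateau bounds must satisfy T_fno <= T_fne")
  structure(list(found = found, T_fno = T_fno, T_fne = T_fne,
                 T_fno_C = T_fno_C, T_fne_C = T_fne_C,
                 se_bounds = se_bounds, HeR = HeR, se_HeR = se_HeR),
            class = "plateau_result")
}

#' Construct a plateau result from known bounds
#'
#' Convenience constructor for computing HeR from tabulated plateau bounds
#' (e.g. published begin/end fundamental temperatures) rather than from a
#' detected plateau.
#'
#' @param T_fno,T_fne fundamental temperatures of plateau begin/end; both
#'   `NA` for a diagram with no plateau.
#' @param se_bounds uncertainty of each bound on the `T_fn` scale.
#' @return a `plateau_result` (without HeR; see [heterogeneity_ratio()]).
#' @export
plateau_result <- function(T_fno = NA, T_fne = NA, se_bounds = NA_real_) {
  found <- !is.na(T_fno) && !is.na(T_fne)
  if (found && T_fno > T_fne) stop("unordered plateau bounds")
  new_plateau_result(found = found,
                     T_fno = as.numeric(T_fno), T_fne = as.numeric(T_fne),
                     T_fno_C = if (found) T_fno * 273.15 - 273.15 else NA_real_,
                     T_fne_C = if (found) T_fne * 273.15 - 273.15 else NA_real_,
                     se_bounds = se_bounds)
}

#' Heterogeneity ratio (HeR) of a melting diagram
#'
#' The ratio of heterogeneous binding interface,
#' `HeR = (1 - T_fne) / (1 - T_fno)`, measures what share of the hydration
#' shell melts heterogeneously (i.e. outside the plateau).  A fully
#' disordered protein has no plateau and `HeR = 1` by definition; a folded
#' protein with a wide plateau has `HeR` well below 1.  A degenerate plateau
#' (`T_fno = T_fne`) also gives 1.
#'
#' The uncertainty is first-order propagation from the bound uncertainties:
#' `se^2 = (dHeR/dT_fno)^2 s^2 + (dHeR/dT_fne)^2 s^2` with `s = se_bounds`.
#'
#' @param plateau a `plateau_result`.
#' @return the same object with `HeR` and `se_HeR` filled.
#' @examples
#' heterogeneity_ratio(plateau_result(0.850, 0.897))$HeR   # 0.687
#' @export
heterogeneity_ratio <- function(plateau) {
  stopifnot(inherits(plateau, "plateau_result"))
  if (!plateau$found) {
    plateau$HeR <- 1
    plateau$se_HeR <- 0
    return(plateau)
  }
  if (plateau$T_fno >= 1)
    stop("plateau cannot begin at or above 0 degrees C (T_fno >= 1)")
  if (plateau$T_fno <= 0 || plateau$T_fne <= 0 || plateau$T_fne >= 1)
    stop("plateau bounds must lie in (0, 1) on the T_fn scale")
  her <- (1 - plateau$T_fne) / (1 - plateau$T_fno)
  s <- plateau$se_bounds
  if (is.finite(s)) {
    d_fne <- -1 / (1 - plateau$T_fno)
    d_fno <- (1 - plateau$T_fne) / (1 - plateau$T_fno)^2
    plateau$se_HeR <- sqrt((d_fne * s)^2 + (d_fno * s)^2)
  }
  plateau$HeR <- her
  plateau
}

#' Classify the fold state from HeR
#'
#' Thresholds are package choices anchored on published exemplar values for
#' folded (~0.54), intermediate (~0.69) and disordered (1) miniproteins:
#' `HeR <= f_max` is folded (F-state), `HeR >= u_min` disordered (U-state),
#' anything between is an intermediate (I-state).
#'
#' @param plateau a `plateau_result` with `HeR` computed.
#' @param f_max upper HeR bound of the F-state (default 0.6).
#' @param u_min lower HeR bound of the U-state (default 0.95).
#' @return one of `"F_state"`, `"I_state"`, `"U_state"`.
#' @export
classify_state <- function(plateau, f_max = 0.6, u_min = 0.95) {
  stopifnot(inherits(plateau, "plateau_result"))
  if (is.na(plateau$HeR)) stop("HeR not computed; run heterogeneity_ratio()")
  if (!(f_max < u_min)) stop("classification thresholds must satisfy f_max < u_min")
  her <- plateau$HeR
  if (her <= f_max) "F_state" else if (her >= u_min) "U_state" else "I_state"
}

#' @export
print.plateau_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf("Plateau: T_fno = %.3f (%.1f C) .. T_fne = %.3f (%.1f C)\n",
                x$T_fno, x$T_fno_C, x$T_fne, x$T_fne_C))
  } else {
    cat("No zero-derivative plateau found (continuous melting)\n")
  }
  if (!is.na(x$HeR))
    cat(sprintf("HeR = %.3f +- %.3f\n", x$HeR,
                ifelse(is.na(x$se_HeR), 0, x$se_HeR)))
  invisible(x)
}
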