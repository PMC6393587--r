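#' Parametric ground-truth melting profiles
#'
#' A melting profile describes the fraction `n(T)` of water protons that are
#' rotationally mobile at temperature `T` (degrees Celsius) in a frozen
#' protein solution, normalized so that `n = 1` for the fully liquid sample
#' at and above 0 degrees C.  Three archetypes reproduce the phenomenology of
#' melting diagrams of folded, partially folded and intrinsically disordered
#' proteins:
#'
#' * `"folded"` -- after the thaw of the first hydration layer the diagram
#'   shows an exactly temperature-independent plateau (`dn/dT = 0`) before
#'   the final rise to 1 at 0 degrees C;
#' * `"intermediate"` -- the first thaw is extended over a wider temperature
#'   range and the plateau is shortened;
#' * `"disordered"` -- melting is continuous: above the onset `n(T)` is
#'   strictly increasing with no zero-slope segment.
#'
#' The functional form is a clamped cubic smoothstep for the first thaw
#' (reaching exactly `n_first` at `plateau_start`), an exactly flat plateau,
#' and a monotone linear-plus-quadratic final rise reaching exactly 1 at
#' 0 degrees C.  For the disordered archetype the smoothstep first thaw is
#' superimposed on the continuous rise, so the slope is strictly positive
#' everywhere above the onset.
#'
#' @param archetype one of `"folded"`, `"intermediate"`, `"disordered"`.
#' @param overrides named list overriding the archetype defaults; recognized
#'   names are `T_onset`, `onset_width`, `n_first`, `plateau_start`,
#'   `plateau_end`, `rise_lin_frac`.
#' @param seed integer seed stored with the profile (used by downstream
#'   generators).
#'
#' @return an object of class `melting_profile`: a list with the archetype,
#'   the thaw/plateau temperatures (degrees C), `n_first` (mobile fraction
#'   after the first thaw), and the shape parameter `rise_lin_frac` (linear
#'   share of the final rise).
#'
#' @details Default temperatures: folded -- first thaw completing at
#'   -48 degrees C with onset at -53, plateau -48..-26; intermediate --
#'   extended thaw -53..-40, plateau -40..-25; disordered -- onset at -50,
#'   then strictly increasing.  `n_first` defaults to 0.1, the fraction
#'   corresponding to ~50 first-shell waters out of a nominal 500 waters per
#'   protein molecule in the sample (the waters-per-protein budget is a
#'   concentration choice, exposed rather than fixed; see
#'   [waters_per_protein()]).
#'
#' @examples
#' pf <- make_melting_profile("folded")
#' profile_n(pf, c(-60, -35, -10, 5))
#' @export
make_melting_profile <- function(archetype = c("folded", "intermediate", "disordered"),
                                 overrides = list(), seed = 1L) {
  archetype <- match.arg(archetype)
  defaults <- switch(archetype,
    folded = list(T_onset = -53, plateau_start = -48, plateau_end = -26,
                  n_first = 0.1, onset_width = NA_real_, rise_lin_frac = 0.3),
    intermediate = list(T_onset = -53, plateau_start = -40, plateau_end = -25,
                        n_first = 0.12, onset_width = NA_real_, rise_lin_frac = 0.3),
    disordered = list(T_onset = -50, plateau_start = NA_real_, plateau_end = NA_real_,
                      n_first = 0.1, onset_width = 5, rise_lin_frac = 0.3)
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown profile override(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, overrides)

  if (archetype == "disordered" &&
      (!is.na(p$plateau_start) || !is.na(p$plateau_end)))
    stop("a plateau cannot be requested for the disordered archetype")
  if (archetype != "disordered") {
    if (is.na(p$plateau_start) || is.na(p$plateau_end))
      stop("plateau bounds are required for the ", archetype, " archetype")
    if (p$plateau_start >= p$plateau_end)
      stop("unordered plateau bounds: plateau_start must be < plateau_end")
    if (p$T_onset >= p$plateau_start)
      stop("T_onset must precede plateau_start")
    temps <- c(p$T_onset, p$plateau_start, p$plateau_end)
  } else {
    temps <- p$T_onset
  }
  if (any(temps <= -80) || any(temps >= 0))
    stop("profile temperatures must lie in (-80, 0) degrees C")
  if (p$n_first <= 0 || p$n_first >= 1)
    stop("n_first must lie strictly in (0, 1)")
  if (p$rise_lin_frac < 0 || p$rise_lin_frac > 1)
    stop("rise_lin_frac must lie in [0, 1]")
  if (archetype == "disordered" && p$onset_width <= 0)
    stop("onset_width must be positive")

  structure(c(list(archetype = archetype), p, list(seed = as.integer(seed))),
            class = "melting_profile")
}

# clamped cubic smoothstep: 0 below 0, 1 above 1, C1-continuous in between
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# monotone final rise from 0 to 1 on u in [0,1]: linear share a, quadratic rest
final_rise <- function(u, a) {
  u <- pmin(pmax(u, 0), 1)
  a * u + (1 - a) * u * u
}

#' Evaluate a ground-truth melting profile
#'
#' @param profile a [make_melting_profile()] object.
#' @param T_C temperatures in degrees Celsius (vectorized).
#' @return mobile-water fraction `n` in `[0, 1]`; exactly 1 for `T_C >= 0`.
#' @export
profile_n <- function(profile, T_C) {
  stopifnot(inherits(profile, "melting_profile"))
  p <- profile
  n <- numeric(length(T_C))
  if (p$archetype == "disordered") {
    u <- (T_C - p$T_onset) / (0 - p$T_onset)
    step <- smoothstep((T_C - p$T_onset) / p$onset_width)
    n <- p$n_first * step + (1 - p$n_first) * final_rise(u, p$rise_lin_frac)
    n[T_C <= p$T_onset] <- 0
  } else {
    # first thaw over [T_onset, plateau_start], flat plateau, then final rise
    step <- smoothstep((T_C - p$T_onset) / (p$plateau_start - p$T_onset))
    n <- p$n_first * step
    u <- (T_C - p$plateau_end) / (0 - p$plateau_end)
    post <- T_C > p$plateau_end
    n[post] <- p$n_first + (1 - p$n_first) * final_rise(u[post], p$rise_lin_frac)
  }
  n[T_C >= 0] <- 1
  n
}

#' @export
print.melting_profile <- function(x, ...) {
  cat("Ground-truth melting profile (", x$archetype, ")\n", sep = "")
  cat("  first-thaw onset: ", x$T_onset, " C, n_first = ", x$n_first, "\n", sep = "")
  if (!is.na(x$plateau_start))
    cat("  plateau: ", x$plateau_start, " .. ", x$plateau_end, " C (dn/dT = 0)\n", sep = "")
  else
    cat("  no plateau (continuous melting)\n")
  invisible(x)
}
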