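#' Define a radionuclide
#'
#' A nuclide carries the physical half-life and the derived decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}} used everywhere activity is decay-corrected,
#' decay-uncorrected or integrated to infinity.
#'
#' `half_life_min = Inf` is permitted and gives \eqn{\lambda = 0} (a
#' non-decaying test nuclide, useful for limiting-case checks of the bladder
#' model); the identity \eqn{\lambda \cdot T_{1/2} = \ln 2} holds for all
#' finite half-lives.
#'
#' @param name Nuclide label, e.g. `"Ga-68"`.
#' @param half_life_min Physical half-life in minutes (> 0, may be `Inf`).
#' @return An object of class `"nuclide"` with fields `name`, `half_life_min`
#'   and `decay_constant_per_min`.
#' @examples
#' ga68()
#' nuclide("F-18", 109.77)
#' @export
nuclide <- function(name, half_life_min) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("`name` must be a single string", call. = FALSE)
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      is.na(half_life_min) || half_life_min <= 0)
    stop("`half_life_min` must be a single positive number", call. = FALSE)
  lambda <- if (is.finite(half_life_min)) log(2) / half_life_min else 0
  structure(
    list(name = name,
         half_life_min = as.numeric(half_life_min),
         decay_constant_per_min = lambda),
    class = "nuclide"
  )
}

#' Gallium-68
#'
#' The default nuclide: physical half-life 68 min.
#' @return A `"nuclide"` object.
#' @export
ga68 <- function() nuclide("Ga-68", 68)

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g min, lambda = %.6g /min\n",
              x$name, x$half_life_min, x$decay_constant_per_min))
  invisible(x)
}

is_nuclide <- function(x) inherits(x, "nuclide")

#' Physical decay factor
#'
#' Fraction of activity remaining after `dt_min` minutes of physical decay,
#' \eqn{\exp(-\lambda \, \Delta t)}. Multiplicative in time:
#' `decay_factor(n, a + b) == decay_factor(n, a) * decay_factor(n, b)`.
#'
#' @param nuclide A [nuclide()].
#' @param dt_min Elapsed time in minutes, >= 0 (vectorised). Negative times
#'   are an error: no implicit back-extrapolation.
#' @return Numeric vector of fractions in (0, 1].
#' @examples
#' decay_factor(ga68(), 68)   # 0.5, one half-life
#' @export
decay_factor <- function(nuclide, dt_min) {
  stopifnot(is_nuclide(nuclide))
  if (!is.numeric(dt_min) || anyNA(dt_min))
    stop("`dt_min` must be numeric and non-missing", call. = FALSE)
  if (any(dt_min < 0))
    stop("`dt_min` must be >= 0: refusing to back-extrapolate decay",
         call. = FALSE)
  exp(-nuclide$decay_constant_per_min * dt_min)
}

#' Decay-correct a measured concentration to injection time
#'
#' Removes physical decay from a concentration measured `t_min` minutes after
#' injection: `conc / decay_factor(nuclide, t_min)`. Exact inverse of
#' [decay_uncorrect()].
#'
#' @param conc Measured activity concentration (kBq/mL), vectorised.
#' @param t_min Minutes post-injection, >= 0.
#' @param nuclide A [nuclide()].
#' @return Concentration referred to injection time, same units.
#' @export
decay_correct <- function(conc, t_min, nuclide = ga68()) {
  conc / decay_factor(nuclide, t_min)
}

#' Remove decay correction (project a corrected value forward in time)
#'
#' @inheritParams decay_correct
#' @param conc Decay-corrected concentration at injection time.
#' @return Physically decayed concentration at `t_min`.
#' @export
decay_uncorrect <- function(conc, t_min, nuclide = ga68()) {
  conc * decay_factor(nuclide, t_min)
}
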