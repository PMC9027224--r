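#' Plasma activity series
#'
#' Decay-corrected relative activity concentrations in plasma over time for
#' one patient (arbitrary units; the mono-exponential fit is amplitude
#' scale-invariant).
#'
#' @param patient_id Identifier.
#' @param times_min Strictly increasing sample times, minutes >= 0.
#' @param rel_conc Positive relative concentrations.
#' @return An object of class `"plasma_series"`.
#' @export
plasma_series <- function(patient_id, times_min, rel_conc) {
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stop("`patient_id` must be a single string", call. = FALSE)
  t <- as.numeric(times_min); y <- as.numeric(rel_conc)
  if (length(t) == 0L || length(t) != length(y))
    stop("times and concentrations must be non-empty and equal length",
         call. = FALSE)
  if (anyNA(t) || any(t < 0) || any(diff(t) <= 0))
    stop("`times_min` must be nonnegative and strictly increasing",
         call. = FALSE)
  if (anyNA(y) || any(y <= 0))
    stop("`rel_conc` must be positive", call. = FALSE)
  structure(list(patient_id = patient_id, times_min = t, rel_conc = y),
            class = "plasma_series")
}

#' @export
print.plasma_series <- function(x, ...) {
  cat(sprintf("<plasma_series> %s: %d samples over %g-%g min\n",
              x$patient_id, length(x$times_min), min(x$times_min),
              max(x$times_min)))
  invisible(x)
}

#' Fit a mono-exponential plasma clearance model
#'
#' Nonlinear least squares of \eqn{C(t) = C_0 e^{-kt}} with log-linear
#' regression used for initialisation; the plasma half-life is
#' \eqn{\ln 2 / k}. Input series are decay-corrected, so the fitted
#' half-life is biologic clearance. A series whose fitted rate is not
#' positive (non-decaying data) is flagged invalid rather than erroring,
#' and [cohort_half_life()] excludes it with a warning.
#'
#' @param series A [plasma_series()] with at least 3 samples.
#' @return An object of class `"plasma_fit"` with fields `patient_id`,
#'   `half_life_min`, `rate_per_min`, `amplitude`, `rss`, `n`, `valid`.
#' @export
fit_monoexp <- function(series) {
  stopifnot(inherits(series, "plasma_series"))
  t <- series$times_min; y <- series$rel_conc
  if (length(t) < 3L)
    stop("need at least 3 plasma samples to fit", call. = FALSE)
  # log-linear initialisation
  ll <- stats::lm(log(y) ~ t)
  k0 <- -unname(stats::coef(ll)[2L])
  c0 <- exp(unname(stats::coef(ll)[1L]))
  if (!is.finite(k0) || k0 <= 1e-10) {
    # non-decaying data: report the log-linear slope, flagged invalid
    return(structure(list(patient_id = series$patient_id,
                          half_life_min = NA_real_, rate_per_min = k0,
                          amplitude = c0,
                          rss = sum(stats::resid(ll)^2), n = length(t),
                          valid = FALSE),
                     class = "plasma_fit"))
  }
  fit <- minpack.lm::nlsLM(
    y ~ C0 * exp(-k * t), data = data.frame(t = t, y = y),
    start = list(C0 = c0, k = k0),
    lower = c(C0 = 1e-12, k = -10), upper = c(C0 = Inf, k = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  k <- unname(co[["k"]])
  valid <- is.finite(k) && k > 0
  structure(list(patient_id = series$patient_id,
                 half_life_min = if (valid) log(2) / k else NA_real_,
                 rate_per_min = k,
                 amplitude = unname(co[["C0"]]),
                 rss = sum(stats::resid(fit)^2),
                 n = length(t),
                 valid = valid),
            class = "plasma_fit")
}

#' @export
print.plasma_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<plasma_fit> %s: T1/2 = %.2f min (k = %.5g /min, n = %d)\n",
                x$patient_id, x$half_life_min, x$rate_per_min, x$n))
  } else {
    cat(sprintf("<plasma_fit> %s: non-decaying (k = %.3g), flagged invalid\n",
                x$patient_id, x$rate_per_min))
  }
  invisible(x)
}

#' Cohort plasma half-life summary
#'
#' Arithmetic mean of per-patient half-lives (not \eqn{\ln 2} over the mean
#' rate, which differs), plus the min-max range. Fits flagged non-decaying
#' are excluded with a warning.
#'
#' @param fits List of [fit_monoexp()] results (at least one valid).
#' @return List with `mean_min`, `range_min` (length 2), `n`,
#'   `half_lives_min`.
#' @export
cohort_half_life <- function(fits) {
  if (inherits(fits, "plasma_fit")) fits <- list(fits)
  if (!is.list(fits) || length(fits) == 0L ||
      !all(vapply(fits, inherits, logical(1), "plasma_fit")))
    stop("`fits` must be a non-empty list of plasma_fit objects",
         call. = FALSE)
  valid <- vapply(fits, `[[`, logical(1), "valid")
  if (any(!valid))
    warning(sprintf("excluding %d non-decaying fit(s): %s", sum(!valid),
                    paste(vapply(fits[!valid], `[[`, character(1),
                                 "patient_id"), collapse = ", ")),
            call. = FALSE)
  hl <- vapply(fits[valid], `[[`, numeric(1), "half_life_min")
  if (length(hl) == 0L)
    stop("no valid plasma fits to summarise", call. = FALSE)
  list(mean_min = mean(hl), range_min = range(hl), n = length(hl),
       half_lives_min = hl)
}
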