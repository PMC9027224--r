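#' Cumulative urine collection series
#'
#' Decay-corrected cumulative excreted activity, as a fraction of injected
#' activity, at increasing void times. The series must be nondecreasing and
#' lie in \[0, 1\].
#'
#' @param patient_id Identifier.
#' @param void_times_min Strictly increasing void times, minutes > 0.
#' @param cum_activity_frac Nondecreasing cumulative fractions in \[0, 1\].
#' @return An object of class `"urine_series"`.
#' @export
urine_series <- function(patient_id, void_times_min, cum_activity_frac) {
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stop("`patient_id` must be a single string", call. = FALSE)
  t <- as.numeric(void_times_min); u <- as.numeric(cum_activity_frac)
  if (length(t) == 0L || length(t) != length(u))
    stop("times and cumulative fractions must be non-empty and equal length",
         call. = FALSE)
  if (anyNA(t) || any(t <= 0) || any(diff(t) <= 0))
    stop("`void_times_min` must be positive and strictly increasing",
         call. = FALSE)
  if (anyNA(u) || any(u < 0) || any(u > 1) || any(diff(u) < 0))
    stop("`cum_activity_frac` must be nondecreasing and within [0, 1]",
         call. = FALSE)
  structure(list(patient_id = patient_id, void_times_min = t,
                 cum_activity_frac = u),
            class = "urine_series")
}

#' @export
print.urine_series <- function(x, ...) {
  cat(sprintf("<urine_series> %s: %d voids, plateau so far %.3f\n",
              x$patient_id, length(x$void_times_min),
              max(x$cum_activity_frac)))
  invisible(x)
}

#' Fit a one-phase exponential association to cumulative urinary excretion
#'
#' Least-squares fit of \eqn{U(t) = F (1 - e^{-kt})} to the pooled point
#' cloud of one or more cumulative urine series (pooling across patients is
#' the default, matching a cohort-level excretion model); `pooled = FALSE`
#' returns one fit per patient for diagnostics.
#'
#' Initialisation: \eqn{F_0} = maximum observed cumulative fraction,
#' \eqn{k_0 = \ln 2 / 60} per min; bounds \eqn{F \in [0,1]},
#' \eqn{k \in (0, 1]}. An all-zero series is degenerate and returns
#' \eqn{F = 0} with a warning rather than failing.
#'
#' @param series A [urine_series()] or list of them.
#' @param pooled Fit one curve to all points (default) or one per patient.
#' @return An object of class `"excretion_fit"` with fields `limit_frac`
#'   (plateau F), `rate_per_min` (k), `biologic_half_life_min`
#'   (\eqn{\ln 2 / k}), `rss`, `n` and `degenerate`; or a named list of such
#'   objects when `pooled = FALSE`.
#' @export
fit_cumulative_excretion <- function(series, pooled = TRUE) {
  if (inherits(series, "urine_series")) series <- list(series)
  if (!is.list(series) || length(series) == 0L ||
      !all(vapply(series, inherits, logical(1), "urine_series")))
    stop("`series` must be a urine_series or a list of them", call. = FALSE)
  if (!pooled) {
    fits <- lapply(series, function(s) fit_cumulative_excretion(s, pooled = TRUE))
    names(fits) <- vapply(series, `[[`, character(1), "patient_id")
    return(fits)
  }
  t <- unlist(lapply(series, `[[`, "void_times_min"))
  u <- unlist(lapply(series, `[[`, "cum_activity_frac"))
  if (length(unique(t)) < 3L)
    stop("need at least 3 distinct void times to fit the excretion model",
         call. = FALSE)
  if (all(u == 0)) {
    warning("all cumulative activities are zero; degenerate fit F = 0",
            call. = FALSE)
    return(structure(list(limit_frac = 0, rate_per_min = NA_real_,
                          biologic_half_life_min = NA_real_,
                          rss = 0, n = length(u), degenerate = TRUE),
                     class = "excretion_fit"))
  }
  dat <- data.frame(t = t, u = u)
  fit <- minpack.lm::nlsLM(
    u ~ F * (1 - exp(-k * t)), data = dat,
    start = list(F = max(u), k = log(2) / 60),
    lower = c(F = 0, k = 1e-8), upper = c(F = 1, k = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  structure(list(limit_frac = unname(co[["F"]]),
                 rate_per_min = unname(co[["k"]]),
                 biologic_half_life_min = log(2) / unname(co[["k"]]),
                 rss = sum(stats::resid(fit)^2), n = nrow(dat),
                 degenerate = FALSE),
            class = "excretion_fit")
}

#' Construct an excretion model directly from parameters
#'
#' Useful for limiting-case analyses; `rate_per_min = Inf` means instant
#' excretion (the plateau is reached immediately after injection).
#'
#' @param limit_frac Plateau F in \[0, 1\].
#' @param rate_per_min Association rate k > 0 (1/min), may be `Inf`.
#' @return An `"excretion_fit"`.
#' @export
excretion_fit <- function(limit_frac, rate_per_min) {
  if (!is.numeric(limit_frac) || length(limit_frac) != 1L ||
      limit_frac < 0 || limit_frac > 1)
    stop("`limit_frac` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(rate_per_min) || length(rate_per_min) != 1L ||
      rate_per_min <= 0)
    stop("`rate_per_min` must be > 0", call. = FALSE)
  structure(list(limit_frac = as.numeric(limit_frac),
                 rate_per_min = as.numeric(rate_per_min),
                 biologic_half_life_min = log(2) / rate_per_min,
                 rss = NA_real_, n = 0L, degenerate = limit_frac == 0),
            class = "excretion_fit")
}

#' @export
print.excretion_fit <- function(x, ...) {
  if (x$degenerate && x$limit_frac == 0) {
    cat("<excretion_fit> degenerate: F = 0\n")
  } else {
    cat(sprintf(
      "<excretion_fit> F = %.4f, k = %.5g /min (biologic T1/2 = %.2f min), n = %d\n",
      x$limit_frac, x$rate_per_min, x$biologic_half_life_min, x$n))
  }
  invisible(x)
}

# Decay-corrected cumulative excretion U(t); handles k = Inf (instant).
excretion_curve <- function(fit) {
  F <- fit$limit_frac; k <- fit$rate_per_min
  if (F == 0) return(function(t) rep(0, length(t)))
  if (is.infinite(k)) return(function(t) ifelse(t > 0, F, 0))
  function(t) F * (1 - exp(-k * t))
}

#' Urinary-bladder-contents TIAC under periodic voiding
#'
#' Dynamic voiding-bladder model: activity enters the bladder per the fitted
#' cumulative excretion \eqn{U(t)} and the bladder is emptied completely and
#' instantaneously every `voiding_interval_min` minutes (first void at one
#' interval after injection). Between voids, the physical activity in the
#' bladder is \eqn{B(t) = e^{-\lambda t} [U(t) - U(t_{last\,void})]}; the
#' TIAC is the sum over voiding cycles of \eqn{\int B(t)\,dt}, integrated
#' numerically until extending the horizon changes the result by less than
#' 0.01%.
#'
#' @param fit An `"excretion_fit"`.
#' @param nuclide A [nuclide()]; `half_life_min = Inf` is allowed (no
#'   physical decay).
#' @param voiding_interval_min Voiding interval, minutes > 0 (default 60).
#' @param rel_tol Relative convergence tolerance on the cycle sum.
#' @return Bladder-contents TIAC in hours.
#' @examples
#' # instant excretion of everything, no decay: exactly one hour in the bladder
#' bladder_tiac(excretion_fit(1, Inf), nuclide("stable", Inf), 60)
#' @export
bladder_tiac <- function(fit, nuclide = ga68(), voiding_interval_min = 60,
                         rel_tol = 1e-6) {
  stopifnot(inherits(fit, "excretion_fit"), is_nuclide(nuclide))
  if (!is.numeric(voiding_interval_min) || length(voiding_interval_min) != 1L ||
      voiding_interval_min <= 0)
    stop("`voiding_interval_min` must be > 0", call. = FALSE)
  if (fit$limit_frac == 0) return(0)
  if (is.na(fit$rate_per_min))
    stop("excretion fit has no rate; cannot run the bladder model",
         call. = FALSE)
  U <- excretion_curve(fit)
  lam <- nuclide$decay_constant_per_min
  Tv <- voiding_interval_min
  total <- 0
  j <- 0L
  repeat {
    t0 <- j * Tv
    u0 <- U(t0)
    inc <- stats::integrate(function(t) exp(-lam * t) * (U(t) - u0),
                            lower = t0, upper = t0 + Tv,
                            rel.tol = 1e-10, abs.tol = 1e-14)$value
    total <- total + inc
    j <- j + 1L
    # upper bound on everything future cycles can still add: the not-yet-
    # excreted activity F - U(jTv), physically decayed to the cycle start
    left <- (fit$limit_frac - U(j * Tv)) * exp(-lam * j * Tv)
    bound <- if (lam > 0) {
      left / lam                      # all its future decays
    } else if (is.finite(fit$rate_per_min)) {
      # lambda = 0: cycle m >= j adds at most (F - U(mTv)) * Tv, geometric in m
      left * Tv / (1 - exp(-fit$rate_per_min * Tv))
    } else {
      0                               # instant excretion: nothing remains
    }
    if (bound < rel_tol * max(total, .Machine$double.eps)) break
    if (j > 100000L)
      stop("bladder model failed to converge", call. = FALSE)
  }
  total / 60
}

#' Decays occurring in voided urine
#'
#' Activity leaves the body at each void; once outside it still decays.
#' Per void at \eqn{t_j = j T_v}, the physical activity removed is
#' \eqn{e^{-\lambda t_j} [U(t_j) - U(t_{j-1})]} and contributes
#' \eqn{e^{-\lambda t_j} \Delta U_j / \lambda} decays. Used to close the
#' whole-body decay balance in [remainder_tiac()].
#'
#' @inheritParams bladder_tiac
#' @return Decays in voided urine, in hours per unit injected activity.
#' @export
voided_urine_decays <- function(fit, nuclide = ga68(),
                                voiding_interval_min = 60, rel_tol = 1e-9) {
  stopifnot(inherits(fit, "excretion_fit"), is_nuclide(nuclide))
  lam <- nuclide$decay_constant_per_min
  if (lam <= 0)
    stop("voided-urine decays are infinite for a non-decaying nuclide",
         call. = FALSE)
  if (fit$limit_frac == 0) return(0)
  U <- excretion_curve(fit)
  Tv <- voiding_interval_min
  total <- 0
  j <- 1L
  repeat {
    dU <- U(j * Tv) - U((j - 1L) * Tv)
    total <- total + exp(-lam * j * Tv) * dU / lam
    bound <- (fit$limit_frac - U(j * Tv)) * exp(-lam * j * Tv) / lam
    if (bound < rel_tol * max(total, .Machine$double.eps)) break
    j <- j + 1L
    if (j > 100000L) stop("voided-urine sum failed to converge", call. = FALSE)
  }
  total / 60
}
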