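#' Convert an organ concentration to a fraction of injected activity
#'
#' Organ activity is estimated by multiplying the measured concentration by
#' the phantom organ volume scaled to the patient:
#' \deqn{a = C \,[\mathrm{kBq/mL}] \cdot
#'       m_{organ}\,[\mathrm{g}] \cdot (W_{patient}/W_{phantom}) /
#'       (1000 \cdot A_0\,[\mathrm{MBq}])}
#' at 1 g/mL, i.e. the dimensionless fraction of injected activity resident
#' in the organ.
#'
#' @param conc Activity concentration(s) in kBq/mL, >= 0 (vectorised).
#' @param region Region name; must be present in the phantom.
#' @param phantom A [phantom()].
#' @param patient A [patient_meta()].
#' @return Fraction(s) of injected activity.
#' @export
organ_activity_fraction <- function(conc, region, phantom, patient) {
  stopifnot(inherits(phantom, "phantom"), inherits(patient, "patient_meta"))
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0))
    stop("`conc` must be numeric and >= 0", call. = FALSE)
  if (!region %in% names(phantom$organ_masses_g))
    stop(sprintf("region '%s' is not in phantom '%s'", region, phantom$name),
         call. = FALSE)
  vol_mL <- phantom$organ_masses_g[[region]] *
    patient$weight_kg / phantom$total_mass_kg
  conc * vol_mL / 1000 / patient$injected_activity_MBq
}

#' Convert a concentration TAC to an activity-fraction curve
#'
#' Applies [organ_activity_fraction()] sample-wise to a decay-uncorrected
#' concentration curve, yielding the decay-uncorrected fraction-of-injected
#' curve that [tiac()] integrates.
#'
#' @param tac A `"tac"` in kBq/mL; must be decay-uncorrected (the dosimetry
#'   chain integrates physical activity, not corrected values).
#' @inheritParams organ_activity_fraction
#' @return A `"tac"` with `unit = "fraction"`.
#' @export
as_fraction_curve <- function(tac, phantom, patient) {
  stopifnot(inherits(tac, "tac"))
  if (tac$unit != "kBq_per_mL")
    stop("`tac` is already a fraction curve", call. = FALSE)
  if (tac$decay_corrected)
    stop("fraction curves for TIAC must be built from decay-uncorrected data",
         call. = FALSE)
  build_tac(tac$region, tac$times_min,
            organ_activity_fraction(tac$values, tac$region, phantom, patient),
            decay_corrected = FALSE, unit = "fraction")
}

#' Time-integrated activity coefficient of a sampled curve
#'
#' Integrates a decay-uncorrected activity-fraction curve from injection to
#' infinity:
#' trapezoidal rule over the sampled interval, a linear rise from zero at
#' injection to the first sample over `[0, t1]`, and an analytic tail
#' \eqn{A(t_n)/\lambda} beyond the last sample assuming only physical decay
#' (no biologic clearance in the tail). The result is in hours per unit
#' injected activity.
#'
#' @param curve A `"tac"` with `unit = "fraction"`, `decay_corrected = FALSE`.
#'   Passing a decay-corrected curve is an error.
#' @param nuclide A [nuclide()]; must have a finite half-life unless the last
#'   sampled value is zero.
#' @return TIAC in hours.
#' @examples
#' # all activity in one region at t = 0, Ga-68: 1/lambda = 1.6350 h
#' tiac(build_tac("wb", 0, 1, FALSE, unit = "fraction"))
#' @export
tiac <- function(curve, nuclide = ga68()) {
  stopifnot(inherits(curve, "tac"), is_nuclide(nuclide))
  if (curve$decay_corrected)
    stop("tiac() integrates decay-uncorrected curves; decay-corrected input",
         call. = FALSE)
  if (curve$unit != "fraction")
    stop("tiac() expects an activity-fraction curve; see as_fraction_curve()",
         call. = FALSE)
  t <- curve$times_min
  a <- curve$values
  n <- length(t)
  body_min <- if (n > 1L) sum(diff(t) * (a[-n] + a[-1L]) / 2) else 0
  lead_min <- t[1L] * a[1L] / 2       # linear rise from 0 at injection
  lam <- nuclide$decay_constant_per_min
  tail_min <- if (a[n] == 0) 0 else {
    if (lam <= 0)
      stop("infinite tail: last activity > 0 with a non-decaying nuclide",
           call. = FALSE)
    a[n] / lam
  }
  (lead_min + body_min + tail_min) / 60
}

#' Per-patient set of TIACs
#'
#' Named collection of source-region TIACs (hours) for one patient, validated
#' against the physical bound: the total number of decays per unit injected
#' activity cannot exceed \eqn{1/\lambda = T_{1/2}/(60 \ln 2)} hours.
#'
#' @param patient_id Identifier.
#' @param tiac_h Named numeric vector, region -> hours, all >= 0. May include
#'   the special regions `"remainder"` and `"urinary_bladder_contents"`.
#' @param nuclide A [nuclide()] used for the whole-body bound.
#' @return An object of class `"tiac_set"`.
#' @export
tiac_set <- function(patient_id, tiac_h, nuclide = ga68()) {
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stop("`patient_id` must be a single string", call. = FALSE)
  if (length(tiac_h) == 0L || is.null(names(tiac_h)) ||
      any(!nzchar(names(tiac_h))))
    stop("`tiac_h` must be a non-empty named vector", call. = FALSE)
  if (anyDuplicated(names(tiac_h)))
    stop("duplicate region names in `tiac_h`", call. = FALSE)
  if (!is.numeric(tiac_h) || anyNA(tiac_h) || any(tiac_h < 0))
    stop("all TIACs must be numeric and >= 0", call. = FALSE)
  if (is.finite(nuclide$half_life_min)) {
    bound_h <- 1 / nuclide$decay_constant_per_min / 60
    if (sum(tiac_h) > bound_h * (1 + 1e-9))
      stop(sprintf(
        "TIACs sum to %.4f h, above the physical whole-body bound %.4f h",
        sum(tiac_h), bound_h), call. = FALSE)
  }
  structure(list(patient_id = patient_id, tiac_h = unlist(tiac_h),
                 nuclide = nuclide),
            class = "tiac_set")
}

#' @export
print.tiac_set <- function(x, ...) {
  cat(sprintf("<tiac_set> %s (%s): %d source regions, sum %.4f h\n",
              x$patient_id, x$nuclide$name, length(x$tiac_h), sum(x$tiac_h)))
  df <- data.frame(region = names(x$tiac_h), tiac_h = unname(x$tiac_h))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Average TIAC sets over patients
#'
#' Arithmetic mean per source region across patients. The union of regions
#' is used; a region missing in some patients is averaged over the patients
#' reporting it (missing means absent, not zero) and a warning records the
#' reduced n.
#'
#' @param per_patient Non-empty list of [tiac_set()] objects.
#' @return A cohort [tiac_set()] (patient_id `"cohort"`) with an
#'   `n_per_region` attribute.
#' @export
average_tiacs <- function(per_patient) {
  if (!is.list(per_patient) || length(per_patient) == 0L ||
      !all(vapply(per_patient, inherits, logical(1), "tiac_set")))
    stop("`per_patient` must be a non-empty list of tiac_set objects",
         call. = FALSE)
  regions <- unique(unlist(lapply(per_patient, function(s) names(s$tiac_h))))
  means <- numeric(length(regions))
  ns <- integer(length(regions))
  names(means) <- names(ns) <- regions
  for (r in regions) {
    vals <- unlist(lapply(per_patient, function(s)
      if (r %in% names(s$tiac_h)) s$tiac_h[[r]] else NULL))
    means[[r]] <- mean(vals)
    ns[[r]] <- length(vals)
  }
  if (any(ns < length(per_patient)))
    warning(sprintf(
      "region(s) %s missing in some patients; averaged over available n",
      paste(regions[ns < length(per_patient)], collapse = ", ")),
      call. = FALSE)
  out <- tiac_set("cohort", means, nuclide = per_patient[[1L]]$nuclide)
  attr(out, "n_per_region") <- ns
  out
}

#' Remainder-of-body TIAC
#'
#' Closes the decay balance: of the \eqn{1/\lambda} hours of total decays per
#' unit injected activity, subtract decays occurring in voided urine (outside
#' the body), in the bladder contents, and in the explicitly quantified
#' organs; the rest is assigned to the remainder of body, floored at zero.
#'
#' @param organ_tiac_h Named vector (or [tiac_set()]) of explicit organ TIACs
#'   in hours (exclude bladder contents and remainder).
#' @param bladder_tiac_h Urinary-bladder-contents TIAC, hours.
#' @param voided_decays_h Decays in voided urine, hours (see
#'   [voided_urine_decays()]).
#' @param nuclide A [nuclide()] with finite half-life.
#' @return Remainder TIAC in hours (>= 0).
#' @export
remainder_tiac <- function(organ_tiac_h, bladder_tiac_h = 0,
                           voided_decays_h = 0, nuclide = ga68()) {
  if (inherits(organ_tiac_h, "tiac_set")) organ_tiac_h <- organ_tiac_h$tiac_h
  stopifnot(is.numeric(organ_tiac_h), is_nuclide(nuclide))
  if (!is.finite(nuclide$half_life_min))
    stop("remainder TIAC requires a decaying nuclide", call. = FALSE)
  total_h <- 1 / nuclide$decay_constant_per_min / 60
  max(0, total_h - voided_decays_h - bladder_tiac_h - sum(organ_tiac_h))
}
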