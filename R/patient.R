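#' Patient metadata
#'
#' Holds the administered-activity and body-weight data required for SUV and
#' fraction-of-injected-activity normalisation. Time zero is the injection.
#'
#' @param patient_id Identifier string.
#' @param weight_kg Body weight in kg; must lie in (20, 300).
#' @param injected_activity_MBq Administered activity in MBq, > 0.
#' @param injection_time_min Injection time on the study clock (minutes);
#'   defaults to 0, the package's time reference.
#' @return An object of class `"patient_meta"`.
#' @export
patient_meta <- function(patient_id, weight_kg, injected_activity_MBq,
                         injection_time_min = 0) {
  if (!is.character(patient_id) || length(patient_id) != 1L || is.na(patient_id))
    stop("`patient_id` must be a single string", call. = FALSE)
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || is.na(weight_kg) ||
      weight_kg <= 20 || weight_kg >= 300)
    stop("`weight_kg` must be a single number in (20, 300)", call. = FALSE)
  if (!is.numeric(injected_activity_MBq) || length(injected_activity_MBq) != 1L ||
      is.na(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("`injected_activity_MBq` must be a single positive number",
         call. = FALSE)
  structure(
    list(patient_id = patient_id,
         weight_kg = as.numeric(weight_kg),
         injected_activity_MBq = as.numeric(injected_activity_MBq),
         injection_time_min = as.numeric(injection_time_min)),
    class = "patient_meta"
  )
}

#' @export
print.patient_meta <- function(x, ...) {
  cat(sprintf("<patient_meta> %s: %.1f kg, %.1f MBq injected\n",
              x$patient_id, x$weight_kg, x$injected_activity_MBq))
  invisible(x)
}

#' Standardized uptake value
#'
#' SUV of a decay-corrected activity concentration, normalised to injected
#' activity per body weight:
#' \deqn{SUV = C \,[\mathrm{kBq/mL}] \cdot W \,[\mathrm{kg}] /
#'       A_0 \,[\mathrm{MBq}]}
#' which is dimensionally g/mL at the assumed tissue density of 1 g/mL.
#' Body-weight normalisation is used (not lean mass or BSA).
#'
#' @param conc_decaycorr Decay-corrected concentration in kBq/mL
#'   (vectorised, >= 0).
#' @param patient A [patient_meta()].
#' @return SUV (g/mL), same length as `conc_decaycorr`.
#' @examples
#' p <- patient_meta("P01", 70, 200)
#' suv(5.0, p)  # 1.75
#' @export
suv <- function(conc_decaycorr, patient) {
  stopifnot(inherits(patient, "patient_meta"))
  if (!is.numeric(conc_decaycorr) || anyNA(conc_decaycorr) ||
      any(conc_decaycorr < 0))
    stop("`conc_decaycorr` must be numeric and >= 0", call. = FALSE)
  conc_decaycorr * patient$weight_kg / patient$injected_activity_MBq
}
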