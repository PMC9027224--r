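#' Per-patient organ TIACs from a TAC table
#'
#' Converts each patient's decay-uncorrected organ concentration curves to
#' activity-fraction curves via the phantom masses and integrates them to
#' TIACs.
#'
#' @param tac TAC data frame (dialect of [read_tac_csv()]); rows must be
#'   decay-uncorrected.
#' @param patients Named list of [patient_meta()].
#' @param phantom A [phantom()].
#' @param nuclide A [nuclide()].
#' @return List with `sets` (named list of [tiac_set()]) and `table`
#'   (data frame `patient_id`, `region`, `tiac_h`, `n_points`,
#'   `tail_fraction`).
#' @export
patient_tiacs <- function(tac, patients, phantom, nuclide = ga68()) {
  if (any(tac$decay_corrected))
    stop("dosimetry integrates decay-uncorrected data; the TAC table ",
         "contains decay-corrected rows", call. = FALSE)
  sets <- list()
  rows <- list()
  for (pid in sort(unique(tac$patient_id))) {
    if (is.null(patients[[pid]]))
      stop(sprintf("no patient metadata for '%s'", pid), call. = FALSE)
    sub <- tac[tac$patient_id == pid, ]
    vals <- c()
    for (r in sort(unique(sub$region))) {
      d <- sub[sub$region == r, ]
      curve <- build_tac(r, d$time_min, d$conc_kBq_per_mL,
                         decay_corrected = FALSE)
      fc <- as_fraction_curve(curve, phantom, patients[[pid]])
      th <- tiac(fc, nuclide)
      nlast <- length(fc$times_min)
      tail_h <- if (fc$values[nlast] == 0) 0 else
        fc$values[nlast] / nuclide$decay_constant_per_min / 60
      vals[r] <- th
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, region = r, tiac_h = th, n_points = nlast,
        tail_fraction = if (th > 0) tail_h / th else NA_real_,
        stringsAsFactors = FALSE)
    }
    sets[[pid]] <- tiac_set(pid, vals, nuclide)
  }
  list(sets = sets, table = do.call(rbind, rows))
}

#' Run the full dosimetry and pharmacokinetics analysis
#'
#' The end-to-end chain: organ TACs -> per-patient TIACs -> cohort-average
#' TIACs; pooled urinary excretion fit -> bladder-contents TIAC under
#' periodic voiding and decays in voided urine -> remainder-of-body TIAC
#' closing the decay balance; MIRD absorbed dose coefficients and ICRP-103
#' effective dose, scaled to an administered activity; per-patient plasma
#' fits and cohort half-life; lesion uptake summaries and tumor-to-organ
#' ratios against organ backgrounds taken from the TACs.
#'
#' The blood-pool TIAC is kept as an explicit diagnostic region but aliased
#' into the remainder source for the dose step (default `alias`), since the
#' S-matrix has no separate blood compartment.
#'
#' @param tac TAC data frame (decay-uncorrected).
#' @param patients Named list of [patient_meta()].
#' @param phantom A [phantom()].
#' @param smat An [smatrix()].
#' @param urine Optional named list of [urine_series()].
#' @param plasma Optional named list of [plasma_series()].
#' @param lesions Optional lesion data frame.
#' @param weights Tissue weighting factors (default [icrp103_weights()]).
#' @param nuclide A [nuclide()].
#' @param voiding_interval_min Bladder voiding interval, minutes.
#' @param administration_MBq Administered activity the effective dose is
#'   scaled to.
#' @param alias Source alias table passed to [absorbed_doses()].
#' @param ratio_organs Background regions for tumor-to-organ ratios.
#' @return An object of class `"study_report"`.
#' @export
run_report <- function(tac, patients, phantom, smat,
                       urine = NULL, plasma = NULL, lesions = NULL,
                       weights = icrp103_weights(), nuclide = ga68(),
                       voiding_interval_min = 60, administration_MBq = 200,
                       alias = c(blood = "remainder"),
                       ratio_organs = c("blood", "liver", "kidneys", "muscle")) {
  pt <- patient_tiacs(tac, patients, phantom, nuclide)
  cohort <- average_tiacs(pt$sets)

  excretion <- NULL; bladder_h <- 0; voided_h <- 0
  if (!is.null(urine) && length(urine)) {
    excretion <- fit_cumulative_excretion(unname(urine), pooled = TRUE)
    bladder_h <- bladder_tiac(excretion, nuclide, voiding_interval_min)
    voided_h <- voided_urine_decays(excretion, nuclide, voiding_interval_min)
  }
  rem_h <- remainder_tiac(cohort$tiac_h, bladder_h, voided_h, nuclide)
  sources <- c(cohort$tiac_h,
               urinary_bladder_contents = bladder_h, remainder = rem_h)
  doses <- absorbed_doses(sources, smat, alias = alias)
  ed <- suppressMessages(effective_dose(list(doses), weights))
  report <- dose_report(doses, ed, smat$phantom_name)
  scaled_mSv <- scale_to_administration(ed, administration_MBq)

  pk <- NULL
  if (!is.null(plasma) && length(plasma)) {
    fits <- lapply(unname(plasma), fit_monoexp)
    pk <- cohort_half_life(fits)
    pk$fits <- fits
  }

  lesion_summary <- NULL; ratios <- NULL; ratio_summary <- NULL
  if (!is.null(lesions) && nrow(lesions)) {
    lesions <- validate_lesions(lesions)
    lesion_summary <- lesion_group_summary(lesions)
    ratios <- tumor_organ_ratios(lesions, tac, patients, nuclide,
                                 organs = ratio_organs)
    if (!is.null(ratios) && nrow(ratios))
      ratio_summary <- ratio_group_summary(ratios)
  }

  structure(list(
    tiac_per_patient = pt$table, tiac_sets = pt$sets, tiac_cohort = cohort,
    excretion = excretion, bladder_tiac_h = bladder_h,
    voided_decays_h = voided_h, remainder_tiac_h = rem_h,
    dose = report, effective_mSv_per_MBq = ed,
    administration_MBq = administration_MBq,
    administered_dose_mSv = scaled_mSv,
    pk = pk, lesion_summary = lesion_summary,
    ratios = ratios, ratio_summary = ratio_summary,
    voiding_interval_min = voiding_interval_min, nuclide = nuclide),
    class = "study_report")
}

# lesion SUVmax over organ-background SUVmean, per patient and timepoint;
# organ backgrounds come from decay-correcting the TAC concentrations.
tumor_organ_ratios <- function(lesions, tac, patients, nuclide,
                               organs = c("blood", "liver", "kidneys",
                                          "muscle")) {
  tps <- intersect(valid_timepoints, unique(lesions$timepoint))
  times <- sort(unique(tac$time_min))
  if (length(times) != length(tps)) return(NULL)
  tp_time <- stats::setNames(times, tps)
  rows <- list()
  for (i in seq_len(nrow(lesions))) {
    pid <- lesions$patient_id[i]
    tp <- lesions$timepoint[i]
    if (is.null(patients[[pid]])) next
    for (org in organs) {
      sel <- tac$patient_id == pid & tac$region == org &
        tac$time_min == tp_time[[tp]]
      if (!any(sel)) next
      conc <- tac$conc_kBq_per_mL[sel][1L]
      if (!tac$decay_corrected[sel][1L])
        conc <- decay_correct(conc, tp_time[[tp]], nuclide)
      organ_suv <- suv(conc, patients[[pid]])
      if (organ_suv <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, group = lesions$group[i], timepoint = tp,
        organ = org,
        ratio = tumor_to_organ(lesions$suv_max[i], organ_suv),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== study report ==\n")
  cat(sprintf("cohort TIACs (%d regions), bladder %.4f h, remainder %.4f h\n",
              length(x$tiac_cohort$tiac_h), x$bladder_tiac_h,
              x$remainder_tiac_h))
  if (!is.null(x$excretion))
    cat(sprintf("urinary excretion: F = %.3f, biologic T1/2 = %.1f min\n",
                x$excretion$limit_frac, x$excretion$biologic_half_life_min))
  cat(sprintf("effective dose: %.4g mSv/MBq (%.3g mSv at %g MBq)\n",
              x$effective_mSv_per_MBq, x$administered_dose_mSv,
              x$administration_MBq))
  if (!is.null(x$pk))
    cat(sprintf("plasma half-life: mean %.2f min (range %.2f-%.2f, n = %d)\n",
                x$pk$mean_min, x$pk$range_min[1], x$pk$range_min[2], x$pk$n))
  invisible(x)
}

#' Write a study report to disk
#'
#' Deterministic CSV output: per-patient and cohort TIAC tables, a dose
#' table mirroring the organ/coefficient layout with a final effective-dose
#' row (mSv/MBq), plasma-fit and lesion-summary tables. Re-running on
#' identical inputs is byte-identical.
#'
#' @param report A [run_report()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiac_csv(report$tiac_per_patient, file.path(dir, "tiac_per_patient.csv"))
  cset <- report$tiac_cohort
  cohort_df <- data.frame(region = names(cset$tiac_h),
                          tiac_h = unname(cset$tiac_h),
                          stringsAsFactors = FALSE)
  extra <- data.frame(region = c("urinary_bladder_contents", "remainder"),
                      tiac_h = c(report$bladder_tiac_h,
                                 report$remainder_tiac_h),
                      stringsAsFactors = FALSE)
  write_table_csv(rbind(cohort_df[order(cohort_df$region), ], extra),
                  file.path(dir, "tiac_cohort.csv"))
  ab <- report$dose$absorbed_mGy_per_MBq
  dose_df <- data.frame(organ = names(ab),
                        coefficient = signif(unname(ab), 3),
                        unit = "mGy_per_MBq", stringsAsFactors = FALSE)
  dose_df <- dose_df[order(dose_df$organ), ]
  dose_df <- rbind(dose_df, data.frame(
    organ = "effective_dose",
    coefficient = signif(report$effective_mSv_per_MBq, 3),
    unit = "mSv_per_MBq", stringsAsFactors = FALSE))
  write_table_csv(dose_df, file.path(dir, "dose.csv"))
  if (!is.null(report$pk)) {
    pk_df <- do.call(rbind, lapply(report$pk$fits, function(f) {
      data.frame(patient_id = f$patient_id, half_life_min = f$half_life_min,
                 rate_per_min = f$rate_per_min, n = f$n, valid = f$valid,
                 stringsAsFactors = FALSE)
    }))
    write_table_csv(pk_df[order(pk_df$patient_id), ],
                    file.path(dir, "plasma_fits.csv"))
  }
  if (!is.null(report$lesion_summary))
    write_table_csv(report$lesion_summary, file.path(dir, "lesion_summary.csv"))
  if (!is.null(report$ratio_summary))
    write_table_csv(report$ratio_summary, file.path(dir, "ratio_summary.csv"))
  invisible(dir)
}
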