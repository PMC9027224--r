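#' Mean and standard error of the mean
#'
#' Cohort summaries are reported as mean +/- SEM, with SEM computed from the
#' n-1 sample standard deviation: \eqn{SEM = s / \sqrt n}. For a single
#' value the SEM is reported as 0 with `single = TRUE` flagged.
#'
#' @param values Non-empty numeric vector.
#' @return List with `mean`, `sem`, `n`, `single`.
#' @examples
#' group_mean_sem(c(4.53, 10.36, 7.85, 7.39, 5.90))$mean  # 7.206
#' @export
group_mean_sem <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values))
    stop("`values` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  n <- length(values)
  list(mean = mean(values),
       sem = if (n == 1L) 0 else stats::sd(values) / sqrt(n),
       n = n,
       single = n == 1L)
}

#' Round half away from zero
#'
#' Report-time rounding; internal comparisons always use unrounded values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

valid_groups <- c("BC", "NEN")
valid_timepoints <- c("PET_10", "PET_1h", "PET_2h")

#' Validate a lesion table
#'
#' Required columns: `patient_id`, `group` (BC/NEN), `timepoint`
#' (PET_10/PET_1h/PET_2h), `suv_max`, `suv_mean`; optional `tumor_size_cm`,
#' `lesion_id`, `organ`. Enforces `suv_mean <= suv_max` and nonnegative SUVs.
#'
#' @param df Data frame of lesion records.
#' @return The validated data frame (invisibly the same shape).
#' @export
validate_lesions <- function(df) {
  req <- c("patient_id", "group", "timepoint", "suv_max", "suv_mean")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("lesion table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(df$group %in% valid_groups))
    stop("invalid group label(s): ",
         paste(unique(setdiff(df$group, valid_groups)), collapse = ", "),
         call. = FALSE)
  if (!all(df$timepoint %in% valid_timepoints))
    stop("invalid timepoint label(s): ",
         paste(unique(setdiff(df$timepoint, valid_timepoints)), collapse = ", "),
         call. = FALSE)
  if (any(df$suv_max < 0) || any(df$suv_mean < 0))
    stop("SUVs must be >= 0", call. = FALSE)
  if (any(df$suv_mean > df$suv_max + 1e-9))
    stop("suv_mean exceeds suv_max in some record(s)", call. = FALSE)
  if ("tumor_size_cm" %in% names(df) &&
      any(!is.na(df$tumor_size_cm) & df$tumor_size_cm <= 0))
    stop("tumor_size_cm must be > 0", call. = FALSE)
  df
}

#' Packaged primary-tumor uptake table
#'
#' Loads the per-patient primary-tumor SUVmax/SUVmean readouts at the three
#' imaging time points (10 min, 1 h, 2 h post-injection) shipped with the
#' package: 5 breast-cancer and 5 neuroendocrine-neoplasm patients. Patient
#' P05's values refer to a liver metastasis (primary unknown); the record is
#' flagged (`liver_metastasis`) but included in group summaries.
#'
#' @return Validated lesion data frame (long format, 30 rows).
#' @export
example_lesions <- function() {
  path <- system.file("extdata", "primary_tumor_suv.csv",
                      package = "petdosim", mustWork = TRUE)
  validate_lesions(read_checked_csv(
    path,
    c("patient_id", "group", "timepoint", "suv_max", "suv_mean",
      "tumor_size_cm", "liver_metastasis"),
    numeric_cols = c("suv_max", "suv_mean", "tumor_size_cm")))
}

#' Group-wise SUV summary
#'
#' Mean +/- SEM (and range) of `suv_max` and `suv_mean` per disease group
#' and time point.
#'
#' @param lesions Lesion data frame (see [validate_lesions()]).
#' @return Data frame with one row per (group, timepoint): n, means, SEMs,
#'   ranges. Values are unrounded; round at report time with
#'   [round_half_up()].
#' @export
lesion_group_summary <- function(lesions) {
  lesions <- validate_lesions(lesions)
  combos <- expand.grid(group = valid_groups, timepoint = valid_timepoints,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- lesions$group == combos$group[i] &
      lesions$timepoint == combos$timepoint[i]
    if (!any(sel)) return(NULL)
    mx <- group_mean_sem(lesions$suv_max[sel])
    mn <- group_mean_sem(lesions$suv_mean[sel])
    data.frame(group = combos$group[i], timepoint = combos$timepoint[i],
               n = mx$n,
               suv_max_mean = mx$mean, suv_max_sem = mx$sem,
               suv_max_min = min(lesions$suv_max[sel]),
               suv_max_max = max(lesions$suv_max[sel]),
               suv_mean_mean = mn$mean, suv_mean_sem = mn$sem,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pick the hottest lesion per organ
#'
#' For tables that report one lesion per organ: the lesion with the highest
#' `suv_max`. Ties are broken deterministically by `lesion_id` order (or row
#' order if absent).
#'
#' @param lesions Data frame with at least `suv_max`, optionally `lesion_id`.
#' @return The selected row.
#' @export
pick_hottest_lesion <- function(lesions) {
  if (!is.data.frame(lesions) || nrow(lesions) == 0L ||
      !"suv_max" %in% names(lesions))
    stop("`lesions` must be a non-empty data frame with a suv_max column",
         call. = FALSE)
  ord <- if ("lesion_id" %in% names(lesions))
    order(lesions$lesion_id) else seq_len(nrow(lesions))
  lesions <- lesions[ord, , drop = FALSE]
  lesions[which.max(lesions$suv_max), , drop = FALSE]
}

#' Tumor-to-organ ratio
#'
#' Lesion SUVmax over organ-background SUVmean, computed per patient before
#' any averaging (group summaries are means of per-patient ratios, not
#' ratios of means).
#'
#' @param lesion_suv_max Lesion SUVmax, >= 0 (vectorised).
#' @param organ_suv_mean Organ background SUVmean, > 0.
#' @return Ratio(s).
#' @export
tumor_to_organ <- function(lesion_suv_max, organ_suv_mean) {
  if (!is.numeric(lesion_suv_max) || any(lesion_suv_max < 0))
    stop("`lesion_suv_max` must be >= 0", call. = FALSE)
  if (!is.numeric(organ_suv_mean) || any(organ_suv_mean <= 0))
    stop("`organ_suv_mean` must be > 0", call. = FALSE)
  lesion_suv_max / organ_suv_mean
}

#' Group-wise tumor-to-organ ratio summary
#'
#' @param ratios Data frame with columns `patient_id`, `group`, `timepoint`,
#'   `organ`, `ratio`.
#' @return Data frame per (group, timepoint, organ): n, mean, SEM.
#' @export
ratio_group_summary <- function(ratios) {
  req <- c("patient_id", "group", "timepoint", "organ", "ratio")
  missing <- setdiff(req, names(ratios))
  if (length(missing))
    stop("ratio table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(ratios$ratio < 0)) stop("ratios must be >= 0", call. = FALSE)
  key <- interaction(ratios$group, ratios$timepoint, ratios$organ, drop = TRUE)
  rows <- lapply(split(ratios, key), function(d) {
    s <- group_mean_sem(d$ratio)
    data.frame(group = d$group[1L], timepoint = d$timepoint[1L],
               organ = d$organ[1L], n = s$n, ratio_mean = s$mean,
               ratio_sem = s$sem, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$timepoint, out$organ, out$group), ]
}
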