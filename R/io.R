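# CSV dialects: all tables are UTF-8 CSV with required headers; units are
# encoded in column names (time_min, conc_kBq_per_mL, tiac_h,
# s_mGy_per_MBq_h) and never inferred. Floats are written with 6 significant
# digits so re-running a report on identical inputs is byte-identical.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  gsub(" ", "", out)
}

write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
    if (is.logical(out[[j]]))
      out[[j]] <- ifelse(out[[j]], "true", "false")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_checked_csv <- function(path, required_cols, numeric_cols = character()) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) && !all(is.na(v) == is.na(vn))) {
        bad <- which(is.na(vn) & !is.na(v))[1L]
        stop(sprintf("%s: column '%s', line %d: not a number ('%s')",
                     path, col, bad + 1L, v[bad]), call. = FALSE)
      }
      df[[col]] <- vn
    }
    if (anyNA(df[[col]]) && !col %in% c("tumor_size_cm"))
      stop(sprintf("%s: column '%s' contains missing values", path, col),
           call. = FALSE)
  }
  df
}

parse_bool <- function(x, path, col) {
  v <- tolower(as.character(x))
  if (!all(v %in% c("true", "false")))
    stop(sprintf("%s: column '%s' must be true/false", path, col),
         call. = FALSE)
  v == "true"
}

#' Read a time-activity-curve table
#'
#' Columns: `patient_id`, `region`, `time_min`, `conc_kBq_per_mL`,
#' `decay_corrected` (true/false).
#'
#' @param path CSV path.
#' @return Data frame in the TAC dialect.
#' @export
read_tac_csv <- function(path) {
  df <- read_checked_csv(path,
                         c("patient_id", "region", "time_min",
                           "conc_kBq_per_mL", "decay_corrected"),
                         numeric_cols = c("time_min", "conc_kBq_per_mL"))
  df$decay_corrected <- parse_bool(df$decay_corrected, path, "decay_corrected")
  if (any(df$conc_kBq_per_mL < 0))
    stop(sprintf("%s: negative concentrations", path), call. = FALSE)
  df
}

#' Write a time-activity-curve table
#' @param df TAC data frame (see [read_tac_csv()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tac_csv <- function(df, path) write_table_csv(df, path)

#' Read urine collections
#'
#' Columns: `patient_id`, `void_time_min`,
#' `cum_activity_MBq_decay_corrected`. Absolute activities are divided by
#' the patient's injected activity at load time, yielding [urine_series()]
#' objects in fractions of injected activity.
#'
#' @param path CSV path.
#' @param patients Named list of [patient_meta()] (names = patient ids)
#'   supplying the injected activities.
#' @return Named list of [urine_series()].
#' @export
read_urine_csv <- function(path, patients) {
  df <- read_checked_csv(path,
                         c("patient_id", "void_time_min",
                           "cum_activity_MBq_decay_corrected"),
                         numeric_cols = c("void_time_min",
                                          "cum_activity_MBq_decay_corrected"))
  out <- lapply(split(df, df$patient_id), function(d) {
    pid <- d$patient_id[1L]
    if (is.null(patients[[pid]]))
      stop(sprintf("%s: no patient metadata for '%s'", path, pid),
           call. = FALSE)
    d <- d[order(d$void_time_min), ]
    urine_series(pid, d$void_time_min,
                 d$cum_activity_MBq_decay_corrected /
                   patients[[pid]]$injected_activity_MBq)
  })
  out[order(names(out))]
}

#' Write urine collections
#' @param series Named list of [urine_series()].
#' @param patients Named list of [patient_meta()] used to convert fractions
#'   back to MBq.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_urine_csv <- function(series, patients, path) {
  rows <- lapply(series, function(s) {
    data.frame(patient_id = s$patient_id,
               void_time_min = s$void_times_min,
               cum_activity_MBq_decay_corrected =
                 s$cum_activity_frac *
                 patients[[s$patient_id]]$injected_activity_MBq,
               stringsAsFactors = FALSE)
  })
  write_table_csv(do.call(rbind, rows), path)
}

#' Read plasma samples
#'
#' Columns: `patient_id`, `time_min`, `rel_conc`, `decay_corrected`
#' (must be true: the PK model fits biologic clearance).
#'
#' @param path CSV path.
#' @return Named list of [plasma_series()].
#' @export
read_plasma_csv <- function(path) {
  df <- read_checked_csv(path,
                         c("patient_id", "time_min", "rel_conc",
                           "decay_corrected"),
                         numeric_cols = c("time_min", "rel_conc"))
  dc <- parse_bool(df$decay_corrected, path, "decay_corrected")
  if (!all(dc))
    stop(sprintf("%s: plasma series must be decay-corrected", path),
         call. = FALSE)
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$time_min), ]
    plasma_series(d$patient_id[1L], d$time_min, d$rel_conc)
  })
  out[order(names(out))]
}

#' Write plasma samples
#' @param series Named list of [plasma_series()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_plasma_csv <- function(series, path) {
  rows <- lapply(series, function(s) {
    data.frame(patient_id = s$patient_id, time_min = s$times_min,
               rel_conc = s$rel_conc, decay_corrected = TRUE,
               stringsAsFactors = FALSE)
  })
  write_table_csv(do.call(rbind, rows), path)
}

#' Read a lesion table
#' @param path CSV path with the columns of [validate_lesions()].
#' @return Validated lesion data frame.
#' @export
read_lesions_csv <- function(path) {
  df <- read_checked_csv(path,
                         c("patient_id", "group", "timepoint", "suv_max",
                           "suv_mean"),
                         numeric_cols = c("suv_max", "suv_mean"))
  validate_lesions(df)
}

#' Write a lesion table
#' @param df Lesion data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_lesions_csv <- function(df, path) write_table_csv(validate_lesions(df), path)

#' Read patient metadata
#'
#' Columns: `patient_id`, `group`, `weight_kg`, `injected_activity_MBq`.
#'
#' @param path CSV path.
#' @return Named list of [patient_meta()] with a `group` attribute per entry.
#' @export
read_patients_csv <- function(path) {
  df <- read_checked_csv(path,
                         c("patient_id", "group", "weight_kg",
                           "injected_activity_MBq"),
                         numeric_cols = c("weight_kg",
                                          "injected_activity_MBq"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    p <- patient_meta(df$patient_id[i], df$weight_kg[i],
                      df$injected_activity_MBq[i])
    attr(p, "group") <- df$group[i]
    p
  })
  names(out) <- df$patient_id
  out
}

#' Write patient metadata
#' @param patients Named list of [patient_meta()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_patients_csv <- function(patients, path) {
  df <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id,
               group = attr(p, "group") %||% NA_character_,
               weight_kg = p$weight_kg,
               injected_activity_MBq = p$injected_activity_MBq,
               stringsAsFactors = FALSE)
  }))
  write_table_csv(df, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-patient TIACs
#'
#' Columns: `patient_id`, `region`, `tiac_h`, `n_points`, `tail_fraction`
#' (share of the TIAC contributed by the analytic tail beyond the last
#' sample; NA where not applicable).
#'
#' @param df TIAC data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tiac_csv <- function(df, path) write_table_csv(df, path)
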