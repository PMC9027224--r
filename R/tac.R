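#' Build a validated time-activity curve
#'
#' A time-activity curve (TAC) is a set of (time, concentration) samples for
#' one region, with an explicit decay-correction flag. Samples are sorted by
#' time; duplicate times, negative concentrations and empty input are
#' rejected. The same container also carries fraction-of-injected-activity
#' curves (see [as_fraction_curve()]); `values` then holds dimensionless
#' fractions and `unit` records which.
#'
#' @param region Region label (e.g. `"liver"`, `"blood"`).
#' @param times_min Sample times, minutes post-injection, >= 0.
#' @param values Activity concentrations (kBq/mL) or activity fractions,
#'   all >= 0, same length as `times_min`.
#' @param decay_corrected Logical flag: have the values been corrected for
#'   physical decay back to injection time?
#' @param unit `"kBq_per_mL"` (default) or `"fraction"`.
#' @return An object of class `"tac"`.
#' @examples
#' build_tac("liver", c(60, 10), c(2, 5), decay_corrected = FALSE)
#' @export
build_tac <- function(region, times_min, values, decay_corrected,
                      unit = c("kBq_per_mL", "fraction")) {
  unit <- match.arg(unit)
  if (!is.character(region) || length(region) != 1L || is.na(region))
    stop("`region` must be a single string", call. = FALSE)
  if (length(times_min) == 0L)
    stop("a time-activity curve needs at least one sample", call. = FALSE)
  if (!is.numeric(times_min) || anyNA(times_min) || any(times_min < 0))
    stop("`times_min` must be numeric, non-missing and >= 0", call. = FALSE)
  if (!is.numeric(values) || anyNA(values) || any(values < 0))
    stop("`values` must be numeric, non-missing and >= 0", call. = FALSE)
  if (length(values) != length(times_min))
    stop("`times_min` and `values` must have the same length", call. = FALSE)
  if (!is.logical(decay_corrected) || length(decay_corrected) != 1L ||
      is.na(decay_corrected))
    stop("`decay_corrected` must be TRUE or FALSE", call. = FALSE)
  ord <- order(times_min)
  times_min <- as.numeric(times_min[ord])
  values <- as.numeric(values[ord])
  if (anyDuplicated(times_min))
    stop(sprintf("duplicate sample times in region '%s'", region),
         call. = FALSE)
  structure(
    list(region = region, times_min = times_min, values = values,
         decay_corrected = decay_corrected, unit = unit),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s (%s, %s): %d sample%s over %g-%g min\n",
              x$region, x$unit,
              if (x$decay_corrected) "decay-corrected" else "decay-uncorrected",
              length(x$times_min), if (length(x$times_min) == 1L) "" else "s",
              min(x$times_min), max(x$times_min)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(region = x$region, time_min = x$times_min, value = x$values,
             decay_corrected = x$decay_corrected,
             stringsAsFactors = FALSE)
}
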