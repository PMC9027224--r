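#' S-value matrix
#'
#' Phantom-specific dose-conversion factors \eqn{S(\mathrm{target}
#' \leftarrow \mathrm{source})} in mGy/(MBq h): absorbed dose rate to a
#' target region per unit activity resident in a source region. The table
#' must be complete over its declared target and source sets, all entries
#' nonnegative, and every source must have a self-dose entry.
#'
#' @param phantom_name Label of the phantom the factors belong to.
#' @param entries Data frame with columns `target`, `source`,
#'   `s_mGy_per_MBq_h`.
#' @return An object of class `"smatrix"` holding a dense targets x sources
#'   matrix.
#' @export
smatrix <- function(phantom_name, entries) {
  req <- c("target", "source", "s_mGy_per_MBq_h")
  if (!is.data.frame(entries) || !all(req %in% names(entries)))
    stop("`entries` must be a data frame with columns target, source, s_mGy_per_MBq_h",
         call. = FALSE)
  if (anyNA(entries[req]))
    stop("S-matrix entries contain missing values", call. = FALSE)
  if (any(entries$s_mGy_per_MBq_h < 0))
    stop("S-values must be >= 0", call. = FALSE)
  targets <- sort(unique(entries$target))
  sources <- sort(unique(entries$source))
  if (anyDuplicated(entries[c("target", "source")]))
    stop("duplicate (target, source) pairs in S-matrix", call. = FALSE)
  if (nrow(entries) != length(targets) * length(sources))
    stop("S-matrix is not complete over its target x source grid",
         call. = FALSE)
  m <- matrix(NA_real_, length(targets), length(sources),
              dimnames = list(target = targets, source = sources))
  m[cbind(match(entries$target, targets), match(entries$source, sources))] <-
    entries$s_mGy_per_MBq_h
  missing_self <- setdiff(intersect(sources, targets), sources[
    vapply(intersect(sources, targets), function(r) !is.na(m[r, r]), logical(1))])
  if (length(missing_self))
    stop("missing self-dose entries: ", paste(missing_self, collapse = ", "),
         call. = FALSE)
  structure(list(phantom_name = phantom_name, s = m), class = "smatrix")
}

#' @export
print.smatrix <- function(x, ...) {
  cat(sprintf("<smatrix> %s: %d targets x %d sources\n",
              x$phantom_name, nrow(x$s), ncol(x$s)))
  invisible(x)
}

#' Read an S-value matrix from CSV
#'
#' Expected columns: `phantom`, `target`, `source`, `s_mGy_per_MBq_h`.
#'
#' @param path CSV path.
#' @return An [smatrix()].
#' @export
read_smatrix <- function(path) {
  df <- read_checked_csv(path, c("phantom", "target", "source",
                                 "s_mGy_per_MBq_h"),
                         numeric_cols = "s_mGy_per_MBq_h")
  if (length(unique(df$phantom)) != 1L)
    stop(sprintf("%s: S-matrix file must describe a single phantom", path),
         call. = FALSE)
  smatrix(df$phantom[1L], df[c("target", "source", "s_mGy_per_MBq_h")])
}

#' Packaged synthetic adult male S-matrix
#'
#' Loads the S-value table shipped with the package: a synthetic,
#' physically plausible factor set (local beta absorption plus a uniform
#' photon bath, bladder-wall surface dose from bladder contents) built for
#' this package's phantom. It is a documented stand-in, not a copy of any
#' proprietary dose-factor library.
#'
#' @return An [smatrix()].
#' @export
default_smatrix <- function() {
  read_smatrix(system.file("extdata", "smatrix_male_synthetic.csv",
                           package = "petdosim", mustWork = TRUE))
}

#' MIRD-schema absorbed dose coefficients
#'
#' \deqn{D(\mathrm{target}) = \sum_{\mathrm{source}}
#'   \tilde a(\mathrm{source})\,[\mathrm{h}] \cdot
#'   S(\mathrm{target} \leftarrow \mathrm{source})\,[\mathrm{mGy/(MBq\,h)}]}
#' Linear in the TIACs. Every TIAC source region must resolve to an
#' S-matrix source, either directly or through the `alias` table (aliased
#' sources have their TIAC added to the target source's); unresolved sources
#' are an error listing them.
#'
#' @param tiacs A [tiac_set()] or named numeric vector of TIACs in hours.
#' @param s An [smatrix()].
#' @param alias Named character vector mapping TIAC region -> S-matrix
#'   source, e.g. `c(blood = "remainder")`.
#' @return Named numeric vector, target -> mGy/MBq.
#' @export
absorbed_doses <- function(tiacs, s, alias = character()) {
  if (inherits(tiacs, "tiac_set")) tiacs <- tiacs$tiac_h
  stopifnot(inherits(s, "smatrix"))
  if (!is.numeric(tiacs) || is.null(names(tiacs)))
    stop("`tiacs` must be a named numeric vector or tiac_set", call. = FALSE)
  if (any(tiacs < 0)) stop("negative TIAC", call. = FALSE)
  src <- names(tiacs)
  mapped <- ifelse(src %in% names(alias), alias[src], src)
  unresolved <- setdiff(unique(mapped), colnames(s$s))
  if (length(unresolved))
    stop("TIAC source region(s) not in S-matrix (add an alias?): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  a <- tapply(tiacs, mapped, sum)                 # merge aliased sources
  vec <- numeric(ncol(s$s)); names(vec) <- colnames(s$s)
  vec[names(a)] <- a
  drop(s$s %*% vec)
}

#' ICRP-103 tissue weighting factors
#'
#' The published tissue weighting factors \eqn{w_T} (sum = 1): 0.12 for
#' red marrow, colon, lung, stomach, breast and the remainder aggregate;
#' 0.08 gonads; 0.04 urinary bladder, oesophagus, liver, thyroid; 0.01
#' bone surface, brain, salivary glands, skin. The remainder tissues are
#' handled as a single aggregate target.
#'
#' @return Named numeric vector of weights summing to 1.
#' @export
icrp103_weights <- function() {
  w <- c(red_marrow = 0.12, colon = 0.12, lungs = 0.12, stomach_wall = 0.12,
         breasts = 0.12, remainder = 0.12,
         gonads = 0.08,
         urinary_bladder_wall = 0.04, esophagus = 0.04, liver = 0.04,
         thyroid = 0.04,
         bone_surface = 0.01, brain = 0.01, salivary_glands = 0.01,
         skin = 0.01)
  stopifnot(abs(sum(w) - 1) < 1e-9)
  w
}

#' ICRP-103 effective dose
#'
#' \eqn{ED = \sum_T w_T \bar D_T} where \eqn{\bar D_T} is the mean over the
#' supplied sexes of the target's absorbed dose coefficient. With a
#' radiation weighting factor of 1 (positrons/photons), equivalent dose
#' equals absorbed dose numerically, so mGy/MBq in gives mSv/MBq out.
#' Supplying a single phantom is allowed (a caveat message is emitted since
#' the reference quantity is defined as a male/female mean).
#'
#' @param doses_by_sex A named numeric vector of target doses (mGy/MBq), or
#'   a list of one or two such vectors (e.g. `list(male = ..., female = ...)`).
#' @param weights Tissue weighting factors; must sum to 1 within 1e-9.
#'   Every weighted tissue must be present in each dose vector.
#' @return Effective dose coefficient, mSv/MBq.
#' @export
effective_dose <- function(doses_by_sex, weights = icrp103_weights()) {
  if (is.numeric(doses_by_sex)) doses_by_sex <- list(doses_by_sex)
  if (!is.list(doses_by_sex) || !length(doses_by_sex) %in% 1:2)
    stop("`doses_by_sex` must be one or two named dose vectors", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("tissue weights must sum to 1", call. = FALSE)
  if (length(doses_by_sex) == 1L)
    message("effective dose computed from a single phantom; ",
            "the reference quantity is a male/female mean")
  per_sex <- lapply(doses_by_sex, function(d) {
    missing <- setdiff(names(weights), names(d))
    if (length(missing))
      stop("weighted tissue(s) missing from dose map: ",
           paste(missing, collapse = ", "), call. = FALSE)
    d[names(weights)]
  })
  mean_d <- Reduce(`+`, per_sex) / length(per_sex)
  sum(weights * mean_d)
}

#' Scale a dose coefficient to an administered activity
#'
#' @param coeff Dose coefficient, mSv/MBq (or mGy/MBq), >= 0.
#' @param activity_MBq Administered activity in MBq, >= 0.
#' @return Dose in mSv (or mGy): the product.
#' @examples
#' scale_to_administration(0.022, 200)  # 4.4 mSv
#' @export
scale_to_administration <- function(coeff, activity_MBq) {
  if (!is.numeric(coeff) || any(coeff < 0) ||
      !is.numeric(activity_MBq) || any(activity_MBq < 0))
    stop("`coeff` and `activity_MBq` must be >= 0", call. = FALSE)
  coeff * activity_MBq
}

#' Assemble a dose report
#'
#' @param absorbed Named vector of absorbed dose coefficients (mGy/MBq).
#' @param effective Effective dose coefficient (mSv/MBq).
#' @param phantoms Character vector of phantom names used.
#' @return An object of class `"dose_report"`.
#' @export
dose_report <- function(absorbed, effective, phantoms) {
  if (any(absorbed < 0) || effective < 0)
    stop("doses must be >= 0", call. = FALSE)
  if (effective > max(absorbed) + 1e-12)
    stop("effective dose exceeds the maximum organ dose; inconsistent inputs",
         call. = FALSE)
  structure(list(absorbed_mGy_per_MBq = absorbed,
                 effective_mSv_per_MBq = effective,
                 phantoms = phantoms),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> phantom(s): %s\n",
              paste(x$phantoms, collapse = ", ")))
  ab <- x$absorbed_mGy_per_MBq
  df <- data.frame(organ = names(ab),
                   mGy_per_MBq = signif(unname(ab), 3))
  print(df[order(df$organ), ], row.names = FALSE)
  cat(sprintf("effective dose: %s mSv/MBq\n",
              format(signif(x$effective_mSv_per_MBq, 3))))
  invisible(x)
}
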