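#' Reference phantom
#'
#' A dosimetry phantom: a named set of reference organ masses and the total
#' body mass they belong to. Organ volumes are taken as mass in grams at
#' 1 g/mL, scaled to the patient by the total-mass ratio (see
#' [organ_activity_fraction()]).
#'
#' @param name Phantom label.
#' @param sex `"male"` or `"female"`.
#' @param total_mass_kg Total body mass of the phantom, kg.
#' @param organ_masses_g Named numeric vector or list, region -> grams; all
#'   masses > 0 and their sum must be below the total mass.
#' @return An object of class `"phantom"`.
#' @export
phantom <- function(name, sex = c("male", "female"), total_mass_kg,
                    organ_masses_g) {
  sex <- match.arg(sex)
  if (!is.character(name) || length(name) != 1L)
    stop("`name` must be a single string", call. = FALSE)
  if (!is.numeric(total_mass_kg) || length(total_mass_kg) != 1L ||
      total_mass_kg <= 0)
    stop("`total_mass_kg` must be a single positive number", call. = FALSE)
  m <- unlist(organ_masses_g)
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("`organ_masses_g` must be named by region", call. = FALSE)
  if (anyDuplicated(names(m)))
    stop("duplicate region names in `organ_masses_g`", call. = FALSE)
  if (!is.numeric(m) || anyNA(m) || any(m <= 0))
    stop("all organ masses must be positive", call. = FALSE)
  if (sum(m) >= total_mass_kg * 1000)
    stop("organ masses sum to more than the phantom's total mass",
         call. = FALSE)
  structure(
    list(name = name, sex = sex, total_mass_kg = as.numeric(total_mass_kg),
         organ_masses_g = m),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s (%s, %.1f kg): %d organs\n",
              x$name, x$sex, x$total_mass_kg, length(x$organ_masses_g)))
  invisible(x)
}

#' Read a phantom from JSON
#'
#' Expected layout:
#' `{"name": ..., "sex": ..., "total_mass_kg": ..., "organ_masses_g": {region: grams}}`.
#'
#' @param path Path to a phantom JSON file.
#' @return A [phantom()].
#' @export
read_phantom <- function(path) {
  if (!file.exists(path))
    stop(sprintf("phantom file not found: %s", path), call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "sex", "total_mass_kg", "organ_masses_g"))
    if (is.null(j[[f]]))
      stop(sprintf("phantom file %s: missing field '%s'", path, f),
           call. = FALSE)
  phantom(j$name, j$sex, j$total_mass_kg, j$organ_masses_g)
}

#' Packaged synthetic adult male phantom
#'
#' Loads the phantom shipped with the package. Its organ masses are a
#' synthetic, physiologically plausible adult-male reference set constructed
#' for this package; it is a documented stand-in, not a copy of any
#' proprietary phantom.
#'
#' @return A [phantom()].
#' @export
default_phantom <- function() {
  read_phantom(system.file("extdata", "phantom_male_synthetic.json",
                           package = "petdosim", mustWork = TRUE))
}
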