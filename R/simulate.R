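#' Synthetic-cohort configuration
#'
#' Ground-truth parameters for the synthetic study generator. Defaults
#' describe the study conditions the pipeline is designed for: two disease
#' groups of 5 patients (breast cancer, neuroendocrine neoplasm) imaged at
#' 10 min / 1 h / 2 h post-injection of ~184 MBq of a 68-min tracer;
#' renal-dominant excretion rising to a plateau; a declining blood pool;
#' near-zero brain/lung/bone/muscle concentrations; mono-exponential plasma
#' clearance with per-patient half-lives on 3.9-14.0 min; urine and plasma
#' sampling in a 7-patient subset.
#'
#' Each organ follows an uptake-washout model; as a decay-uncorrected
#' fraction of injected activity,
#' \deqn{A_r(t) = f_r \frac{k_u}{k_u - k_w}
#'   (e^{-k_w t} - e^{-k_u t}) \, e^{-\lambda t}}
#' whose analytic integral (the true TIAC, hours) is
#' \eqn{f_r k_u / [(k_w+\lambda)(k_u+\lambda)] / 60}.
#'
#' @param n_bc,n_nen Patients per group.
#' @param n_pk Number of patients with urine and plasma sampling.
#' @param schedule_min Whole-body acquisition times, minutes post-injection.
#' @param void_offset_min Urine void delay after each acquisition start.
#' @param organ_kinetics Data frame `region`, `f` (uptake fraction), `k_u`
#'   (uptake rate, 1/min), `k_w` (washout rate, 1/min).
#' @param excretion_limit,excretion_rate Urinary plateau F and association
#'   rate k (1/min) of the cumulative excretion truth.
#' @param plasma_half_life_range_min Per-patient plasma half-life range
#'   (uniform draw), minutes.
#' @param plasma_times_min Plasma sampling schedule, minutes.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise on concentrations (0 = noiseless).
#' @param lesion_suv_mu Named list per group of mean SUVmax at each
#'   timepoint (log-normal medians).
#' @param lesion_sdlog Between-patient log-SD of lesion uptake.
#' @param suv_mean_ratio_range SUVmean/SUVmax uniform range.
#' @param weight_range_kg,injected_mean_MBq,injected_sd_MBq,injected_range_MBq
#'   Patient weight and administered-activity distributions.
#' @param nuclide A [nuclide()].
#' @return An object of class `"cohort_config"`. Construction fails if the
#'   organ uptake fractions plus the excreted fraction exceed 1 (infeasible
#'   mass balance).
#' @export
cohort_config <- function(
    n_bc = 5L, n_nen = 5L, n_pk = 7L,
    schedule_min = c(10, 60, 120),
    void_offset_min = 25,
    organ_kinetics = default_organ_kinetics(),
    excretion_limit = 0.55, excretion_rate = 0.02,
    plasma_half_life_range_min = c(3.9, 14.0),
    plasma_times_min = c(2, 5, 10, 20, 40),
    noise_cv = 0.05,
    lesion_suv_mu = list(
      NEN = c(PET_10 = 7.2, PET_1h = 9.6, PET_2h = 10.0),
      BC  = c(PET_10 = 5.1, PET_1h = 6.3, PET_2h = 6.6)),
    lesion_sdlog = 0.35,
    suv_mean_ratio_range = c(0.45, 0.65),
    weight_range_kg = c(55, 95),
    injected_mean_MBq = 184.4, injected_sd_MBq = 38.4,
    injected_range_MBq = c(97.3, 220),
    nuclide = ga68()) {
  stopifnot(n_bc >= 0, n_nen >= 0, n_bc + n_nen >= 1,
            all(schedule_min > 0), all(diff(schedule_min) > 0),
            noise_cv >= 0, lesion_sdlog >= 0,
            excretion_limit >= 0, excretion_limit <= 1, excretion_rate > 0,
            all(plasma_half_life_range_min > 0),
            is_nuclide(nuclide))
  req <- c("region", "f", "k_u", "k_w")
  if (!is.data.frame(organ_kinetics) || !all(req %in% names(organ_kinetics)))
    stop("`organ_kinetics` needs columns region, f, k_u, k_w", call. = FALSE)
  if (any(organ_kinetics$f < 0) || any(organ_kinetics$k_u <= 0) ||
      any(organ_kinetics$k_w <= 0))
    stop("organ kinetic rates must be positive and fractions >= 0",
         call. = FALSE)
  if (any(organ_kinetics$k_u <= organ_kinetics$k_w))
    stop("uptake rate k_u must exceed washout rate k_w", call. = FALSE)
  if (sum(organ_kinetics$f) + excretion_limit > 1)
    stop(sprintf(
      "infeasible mass balance: uptake fractions (%.3f) + excreted (%.3f) > 1",
      sum(organ_kinetics$f), excretion_limit), call. = FALSE)
  structure(
    list(n_bc = as.integer(n_bc), n_nen = as.integer(n_nen),
         n_pk = as.integer(n_pk), schedule_min = schedule_min,
         void_offset_min = void_offset_min, organ_kinetics = organ_kinetics,
         excretion_limit = excretion_limit, excretion_rate = excretion_rate,
         plasma_half_life_range_min = plasma_half_life_range_min,
         plasma_times_min = plasma_times_min, noise_cv = noise_cv,
         lesion_suv_mu = lesion_suv_mu, lesion_sdlog = lesion_sdlog,
         suv_mean_ratio_range = suv_mean_ratio_range,
         weight_range_kg = weight_range_kg,
         injected_mean_MBq = injected_mean_MBq,
         injected_sd_MBq = injected_sd_MBq,
         injected_range_MBq = injected_range_MBq, nuclide = nuclide),
    class = "cohort_config")
}

#' Default organ kinetic parameters
#'
#' Kidney- and liver-dominant uptake with a rapidly equilibrating, declining
#' blood pool and near-zero brain/lung/bone/muscle concentrations (muscle
#' carries a visible fraction only because of its large mass). Chosen once
#' as a qualitative match to a renally cleared small peptide tracer, not
#' fitted to any dataset.
#'
#' @return Data frame `region`, `f`, `k_u`, `k_w`.
#' @export
default_organ_kinetics <- function() {
  data.frame(
    region = c("blood", "kidneys", "liver", "spleen", "small_intestine",
               "lungs", "red_marrow", "muscle", "brain"),
    f   = c(0.15, 0.05, 0.06, 0.015, 0.04, 0.008, 0.02, 0.04, 0.002),
    k_u = c(3.0, 0.15, 0.10, 0.12, 0.08, 0.20, 0.10, 0.05, 0.30),
    k_w = c(0.020, 0.004, 0.003, 0.004, 0.003, 0.010, 0.004, 0.006, 0.020),
    stringsAsFactors = FALSE
  )
}

# decay-uncorrected fraction-of-injected at time t for one organ
organ_fraction_model <- function(t, f, k_u, k_w, lambda) {
  f * k_u / (k_u - k_w) * (exp(-k_w * t) - exp(-k_u * t)) * exp(-lambda * t)
}

# analytic TIAC (hours) of the uptake-washout model
organ_tiac_analytic <- function(f, k_u, k_w, lambda) {
  f * k_u / ((k_w + lambda) * (k_u + lambda)) / 60
}

# mean-one multiplicative log-normal noise with coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Generate a synthetic study cohort
#'
#' Draws a full synthetic dataset — patients, organ time-activity curves,
#' cumulative urine, plasma series and lesion uptake tables — together with
#' the analytic ground truth of every generating parameter. All randomness
#' comes from a single stream keyed by `seed`, with draws ordered
#' deterministically by (patient, region, time), so identical
#' (config, seed) pairs give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param phantom A [phantom()] used to convert activity fractions to
#'   concentrations (and back by the pipeline).
#' @return An object of class `"pet_cohort"`: data frames `patients`, `tac`,
#'   `lesions`; lists `urine`, `plasma`; list `ground_truth` (per-patient
#'   kinetics, analytic TIACs, excretion and plasma parameters); plus the
#'   config, phantom and seed.
#' @export
gen_cohort <- function(config = cohort_config(), seed = 42L,
                       phantom = default_phantom()) {
  stopifnot(inherits(config, "cohort_config"), inherits(phantom, "phantom"))
  missing_regions <- setdiff(config$organ_kinetics$region,
                             names(phantom$organ_masses_g))
  if (length(missing_regions))
    stop("phantom lacks mass for region(s): ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  lam <- config$nuclide$decay_constant_per_min
  n <- config$n_nen + config$n_bc
  ids <- sprintf("P%02d", seq_len(n))
  groups <- c(rep("NEN", config$n_nen), rep("BC", config$n_bc))

  # --- patients -----------------------------------------------------------
  weight <- stats::runif(n, config$weight_range_kg[1], config$weight_range_kg[2])
  injected <- pmin(pmax(
    stats::rnorm(n, config$injected_mean_MBq, config$injected_sd_MBq),
    config$injected_range_MBq[1]), config$injected_range_MBq[2])
  patients <- lapply(seq_len(n), function(i) {
    p <- patient_meta(ids[i], weight[i], injected[i])
    attr(p, "group") <- groups[i]
    p
  })
  names(patients) <- ids

  # --- per-patient ground truth ------------------------------------------
  pk_ids <- ids[seq_len(min(config$n_pk, n))]
  truth <- list()
  tac_rows <- list()
  urine <- list()
  plasma <- list()
  ok <- config$organ_kinetics
  for (i in seq_len(n)) {
    pid <- ids[i]
    # jitter organ kinetics per patient (10% log-normal), preserving balance
    kin <- ok
    kin$f <- ok$f * lnorm_noise(nrow(ok), 0.10)
    kin$k_u <- ok$k_u * lnorm_noise(nrow(ok), 0.10)
    kin$k_w <- ok$k_w * lnorm_noise(nrow(ok), 0.10)
    F_i <- config$excretion_limit * lnorm_noise(1, 0.05)
    k_i <- config$excretion_rate * lnorm_noise(1, 0.10)
    if (sum(kin$f) + F_i > 1) {      # rescale jitter back into balance
      scl <- (1 - F_i) / sum(kin$f) * 0.999
      kin$f <- kin$f * scl
    }
    t_half_i <- stats::runif(1, config$plasma_half_life_range_min[1],
                             config$plasma_half_life_range_min[2])
    tiac_true <- stats::setNames(
      organ_tiac_analytic(kin$f, kin$k_u, kin$k_w, lam), kin$region)
    truth[[pid]] <- list(kinetics = kin,
                         excretion = c(F = F_i, k = k_i),
                         plasma_half_life_min = t_half_i,
                         tiac_h = tiac_true)

    # --- organ TACs (decay-uncorrected kBq/mL) ----------------------------
    for (r in seq_len(nrow(kin))) {
      frac <- organ_fraction_model(config$schedule_min,
                                   kin$f[r], kin$k_u[r], kin$k_w[r], lam)
      vol_mL <- phantom$organ_masses_g[[kin$region[r]]] *
        weight[i] / phantom$total_mass_kg
      conc <- frac * injected[i] * 1000 / vol_mL *
        lnorm_noise(length(frac), config$noise_cv)
      tac_rows[[length(tac_rows) + 1L]] <- data.frame(
        patient_id = pid, region = kin$region[r],
        time_min = config$schedule_min, conc_kBq_per_mL = conc,
        decay_corrected = FALSE, stringsAsFactors = FALSE)
    }

    # --- urine and plasma for the PK subset -------------------------------
    if (pid %in% pk_ids) {
      vt <- config$schedule_min + config$void_offset_min
      u_true <- F_i * (1 - exp(-k_i * vt))
      du <- diff(c(0, u_true)) * lnorm_noise(length(vt), config$noise_cv)
      u <- pmin(cumsum(du), 1)
      urine[[pid]] <- urine_series(pid, vt, u)

      kp <- log(2) / t_half_i
      conc_p <- 100 * exp(-kp * config$plasma_times_min) *
        lnorm_noise(length(config$plasma_times_min), config$noise_cv)
      plasma[[pid]] <- plasma_series(pid, config$plasma_times_min, conc_p)
    }
  }

  # --- lesions -------------------------------------------------------------
  lesion_rows <- lapply(seq_len(n), function(i) {
    mu <- config$lesion_suv_mu[[groups[i]]]
    z <- stats::rnorm(1, 0, config$lesion_sdlog)
    suv_max <- unname(mu) * exp(z) * exp(stats::rnorm(length(mu), 0, 0.08))
    ratio <- stats::runif(length(mu), config$suv_mean_ratio_range[1],
                          config$suv_mean_ratio_range[2])
    size <- if (groups[i] == "NEN") stats::rlnorm(1, log(4.9), 0.5)
            else stats::rlnorm(1, log(1.4), 0.5)
    data.frame(patient_id = ids[i], group = groups[i],
               timepoint = names(mu), suv_max = suv_max,
               suv_mean = suv_max * ratio,
               tumor_size_cm = size, stringsAsFactors = FALSE)
  })
  lesions <- validate_lesions(do.call(rbind, lesion_rows))
  rownames(lesions) <- NULL

  tac <- do.call(rbind, tac_rows)
  rownames(tac) <- NULL
  structure(list(patients = patients, tac = tac, urine = urine,
                 plasma = plasma, lesions = lesions, ground_truth = truth,
                 config = config, phantom = phantom, seed = as.integer(seed)),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf(
    "<pet_cohort> %d patients (%d with urine/plasma), %d TAC rows, seed %d\n",
    length(x$patients), length(x$urine), nrow(x$tac), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the pipeline's CSV dialects (`patients.csv`, `tac.csv`,
#' `urine.csv`, `plasma.csv`, `lesions.csv`) plus `ground_truth.json`.
#' Output is byte-identical for identical cohorts.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patients_csv(cohort$patients, file.path(dir, "patients.csv"))
  write_tac_csv(cohort$tac, file.path(dir, "tac.csv"))
  if (length(cohort$urine))
    write_urine_csv(cohort$urine, cohort$patients, file.path(dir, "urine.csv"))
  if (length(cohort$plasma))
    write_plasma_csv(cohort$plasma, file.path(dir, "plasma.csv"))
  write_lesions_csv(cohort$lesions, file.path(dir, "lesions.csv"))
  gt <- lapply(cohort$ground_truth, function(g) {
    list(kinetics = g$kinetics,
         excretion = as.list(g$excretion),
         plasma_half_life_min = g$plasma_half_life_min,
         tiac_h = as.list(g$tiac_h))
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
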