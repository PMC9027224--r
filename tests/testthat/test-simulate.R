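test_that("identical (config, seed) gives byte-identical datasets", {
  co1 <- gen_cohort(cohort_config(), seed = 42)
  co2 <- gen_cohort(cohort_config(), seed = 42)
  d1 <- file.path(tempdir(), "cohort_a"); d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  co3 <- gen_cohort(cohort_config(), seed = 43)
  expect_false(identical(co1$tac$conc_kBq_per_mL, co3$tac$conc_kBq_per_mL))
})

test_that("zero-noise pipeline TIACs match analytic ground truth", {
  cfg <- small_config(noise_cv = 0, schedule_min = seq(1, 300, by = 1))
  co <- gen_cohort(cfg, seed = 9)
  pt <- patient_tiacs(co$tac, co$patients, co$phantom)
  for (pid in names(pt$sets)) {
    got <- pt$sets[[pid]]$tiac_h
    truth <- co$ground_truth[[pid]]$tiac_h
    expect_equal(got[names(truth)], truth, tolerance = 0.03)
  }
})

test_that("zero-noise urine and plasma follow their generating models exactly", {
  cfg <- small_config(noise_cv = 0)
  co <- gen_cohort(cfg, seed = 3)
  for (pid in names(co$urine)) {
    tr <- co$ground_truth[[pid]]$excretion
    u <- co$urine[[pid]]
    expect_equal(u$cum_activity_frac,
                 tr[["F"]] * (1 - exp(-tr[["k"]] * u$void_times_min)),
                 tolerance = 1e-12)
    p <- co$plasma[[pid]]
    hl <- co$ground_truth[[pid]]$plasma_half_life_min
    expect_equal(p$rel_conc, 100 * exp(-log(2) / hl * p$times_min),
                 tolerance = 1e-12)
  }
})

test_that("mass balance holds at every sampled time", {
  co <- gen_cohort(cohort_config(noise_cv = 0), seed = 21)
  lam <- co$config$nuclide$decay_constant_per_min
  for (pid in names(co$patients)) {
    kin <- co$ground_truth[[pid]]$kinetics
    ex <- co$ground_truth[[pid]]$excretion
    for (t in co$config$schedule_min) {
      organs <- sum(kin$f * kin$k_u / (kin$k_u - kin$k_w) *
                      (exp(-kin$k_w * t) - exp(-kin$k_u * t)))
      urine <- ex[["F"]] * (1 - exp(-ex[["k"]] * t))
      expect_lte(organs + urine, 1 + 1e-9)
    }
  }
})

test_that("generated lesion uptake brackets the observed clinical ranges", {
  co <- gen_cohort(cohort_config(), seed = 42)
  nen <- co$lesions[co$lesions$group == "NEN", ]
  expect_true(all(nen$suv_max >= 2 & nen$suv_max <= 20))
  expect_true(all(co$lesions$suv_mean <= co$lesions$suv_max))
  expect_true(all(co$lesions$tumor_size_cm > 0))
})

test_that("the excreted fraction is renal-dominant", {
  cfg <- cohort_config()
  hepatobiliary <- cfg$organ_kinetics$f[
    cfg$organ_kinetics$region == "small_intestine"]
  renal_share <- cfg$excretion_limit / (cfg$excretion_limit + hepatobiliary)
  expect_gte(renal_share, 0.8)
})

test_that("infeasible mass balance is rejected before generation", {
  ok <- default_organ_kinetics()
  ok$f[1] <- 0.9
  expect_error(cohort_config(organ_kinetics = ok), "mass balance")
})

test_that("noisy urine recovery: 200 seeds give < 5 % median error", {
  t <- c(35, 85, 145)
  cfgF <- 0.55; cfgk <- 0.02
  set.seed(77)
  est <- replicate(200, {
    du <- diff(c(0, cfgF * (1 - exp(-cfgk * t)))) * exp(rnorm(3, 0, 0.05))
    fit <- fit_cumulative_excretion(urine_series("P", t, pmin(cumsum(du), 1)))
    c(fit$limit_frac, fit$rate_per_min)
  })
  expect_lt(abs(median(est[1, ]) - cfgF) / cfgF, 0.05)
  expect_lt(abs(median(est[2, ]) - cfgk) / cfgk, 0.05)
})
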