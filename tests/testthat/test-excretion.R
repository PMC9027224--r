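test_that("excretion fit recovers exact one-phase association parameters", {
  t <- c(30, 60, 90, 120, 180)
  s <- urine_series("P1", t, 0.5 * (1 - exp(-0.02 * t)))
  fit <- fit_cumulative_excretion(s)
  expect_lt(abs(fit$limit_frac - 0.5), 1e-6)
  expect_lt(abs(fit$rate_per_min - 0.02), 1e-6)
  expect_false(fit$degenerate)
})

test_that("all-zero urine is degenerate, not an error", {
  s <- urine_series("P1", c(30, 60, 90), c(0, 0, 0))
  expect_warning(fit <- fit_cumulative_excretion(s), "degenerate")
  expect_equal(fit$limit_frac, 0)
  expect_true(fit$degenerate)
  expect_equal(bladder_tiac(fit), 0)
})

test_that("noisy excretion parameters are recovered within 5 % median error", {
  set.seed(101)
  t <- c(30, 60, 90, 120, 180)
  truth <- 0.6 * (1 - exp(-0.015 * t))
  est <- replicate(200, {
    u <- cummax(pmin(truth * exp(rnorm(length(t), 0, 0.02)), 1))
    fit <- fit_cumulative_excretion(urine_series("P1", t, u))
    c(fit$limit_frac, fit$rate_per_min)
  })
  expect_lt(abs(median(est[1, ]) - 0.6) / 0.6, 0.05)
  expect_lt(abs(median(est[2, ]) - 0.015) / 0.015, 0.05)
})

test_that("pooled fitting is the default; per-patient mode is available", {
  t <- c(30, 60, 120)
  s1 <- urine_series("P1", t, 0.5 * (1 - exp(-0.02 * t)))
  s2 <- urine_series("P2", t + 5, 0.5 * (1 - exp(-0.02 * (t + 5))))
  pooled <- fit_cumulative_excretion(list(s1, s2))
  expect_lt(abs(pooled$limit_frac - 0.5), 1e-6)
  expect_equal(pooled$n, 6L)
  per <- fit_cumulative_excretion(list(s1, s2), pooled = FALSE)
  expect_named(per, c("P1", "P2"))
  expect_lt(abs(per$P1$limit_frac - 0.5), 1e-6)
})

test_that("bladder model matches instant-excretion closed forms", {
  # no decay: everything sits in the bladder exactly one voiding interval
  stable <- nuclide("stable", Inf)
  expect_equal(bladder_tiac(excretion_fit(1, Inf), stable, 60), 1.0,
               tolerance = 1e-3)
  # physical decay only: (1 - e^(-60 lambda)) / lambda
  lam <- log(2) / 68
  exact <- (1 - exp(-60 * lam)) / lam / 60
  expect_equal(bladder_tiac(excretion_fit(1, Inf), ga68(), 60), exact,
               tolerance = 1e-3)
  expect_equal(exact, 0.748, tolerance = 1e-3)
})

test_that("bladder TIAC is monotone in plateau and voiding interval, and bounded", {
  lam_h <- log(2) / 68 * 60
  fits <- lapply(c(0.2, 0.4, 0.6, 0.8), excretion_fit, rate_per_min = 0.02)
  vals <- vapply(fits, bladder_tiac, numeric(1))
  expect_true(all(diff(vals) > 0))
  tv <- vapply(c(30, 60, 120, 240), function(v)
    bladder_tiac(excretion_fit(0.5, 0.02), ga68(), v), numeric(1))
  expect_true(all(diff(tv) > 0))
  for (v in vals) expect_lt(v, 0.8 * (1 / lam_h))
})

test_that("bladder plus voided decays equal the excreted fraction's total decays", {
  # every atom that reaches the bladder decays there or after voiding:
  # bladder TIAC + voided decays = integral e^(-lambda t) dU / lambda
  F <- 0.5; k <- 0.02; lam <- log(2) / 68
  fit <- excretion_fit(F, k)
  exact_h <- F * k / (lam * (k + lam)) / 60
  got <- bladder_tiac(fit, ga68(), 60) + voided_urine_decays(fit, ga68(), 60)
  expect_equal(got, exact_h, tolerance = 1e-4)
})

test_that("urine series reject non-physical input", {
  expect_error(urine_series("P1", c(30, 20), c(0.1, 0.2)), "increasing")
  expect_error(urine_series("P1", c(30, 60), c(0.2, 0.1)), "nondecreasing")
  expect_error(urine_series("P1", c(30, 60), c(0.2, 1.2)), "\\[0, 1\\]")
  expect_error(fit_cumulative_excretion(
    urine_series("P1", c(30, 60), c(0.1, 0.2))), "3 distinct")
})
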