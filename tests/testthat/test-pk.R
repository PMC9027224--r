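test_that("mono-exponential fit recovers a noiseless half-life exactly", {
  t <- c(2, 5, 10, 20, 40)
  s <- plasma_series("P1", t, 50 * exp(-log(2) / 8.6 * t))
  fit <- fit_monoexp(s)
  expect_lt(abs(fit$half_life_min - 8.6), 1e-6)
  expect_true(fit$valid)
})

test_that("non-decaying plasma data are flagged, not fitted blindly", {
  s <- plasma_series("P1", c(2, 5, 10, 20), rep(10, 4))
  fit <- fit_monoexp(s)
  expect_false(fit$valid)
  expect_true(is.na(fit$half_life_min))
  good <- fit_monoexp(plasma_series("P2", c(2, 5, 10),
                                    10 * exp(-0.1 * c(2, 5, 10))))
  expect_warning(ch <- cohort_half_life(list(fit, good)), "non-decaying")
  expect_equal(ch$n, 1L)
})

test_that("noisy half-lives are recovered within 3 % median error", {
  set.seed(202)
  t <- c(2, 5, 10, 20, 40)
  k <- log(2) / 10
  est <- replicate(500, {
    y <- 100 * exp(-k * t) * exp(rnorm(length(t), 0, 0.05))
    fit_monoexp(plasma_series("P1", t, y))$half_life_min
  })
  expect_lt(abs(median(est) - 10) / 10, 0.03)
})

test_that("the fit is amplitude- and time-shift invariant", {
  t <- c(2, 5, 10, 20, 40)
  y <- 30 * exp(-log(2) / 7 * t) * exp(c(0.02, -0.01, 0.03, -0.02, 0.01))
  h1 <- fit_monoexp(plasma_series("P1", t, y))$half_life_min
  h2 <- fit_monoexp(plasma_series("P1", t, 5 * y))$half_life_min
  h3 <- fit_monoexp(plasma_series("P1", t + 12, y))$half_life_min
  expect_equal(h1, h2, tolerance = 1e-8)
  expect_equal(h1, h3, tolerance = 1e-6)
})

test_that("cohort half-life is the mean of per-patient half-lives", {
  mk <- function(hl, id) {
    t <- c(2, 5, 10, 20)
    fit_monoexp(plasma_series(id, t, 10 * exp(-log(2) / hl * t)))
  }
  fits <- list(mk(4, "a"), mk(8, "b"), mk(12, "c"))
  ch <- cohort_half_life(fits)
  expect_equal(ch$mean_min, 8, tolerance = 1e-6)
  expect_equal(ch$range_min, c(4, 12), tolerance = 1e-6)
  one <- cohort_half_life(list(mk(6.5, "solo")))
  expect_equal(one$mean_min, 6.5, tolerance = 1e-6)
  # deliberately different from ln2 / mean(k)
  pooled_k <- mean(log(2) / c(4, 8, 12))
  expect_gt(abs(ch$mean_min - log(2) / pooled_k), 0.5)
})

test_that("synthetic cohort plasma half-lives average near the generator truth", {
  co <- gen_cohort(cohort_config(), seed = 11)
  fits <- lapply(co$plasma, fit_monoexp)
  ch <- cohort_half_life(unname(fits))
  truth <- vapply(names(co$plasma), function(p)
    co$ground_truth[[p]]$plasma_half_life_min, numeric(1))
  expect_equal(ch$mean_min, mean(truth), tolerance = 0.05)
  expect_true(all(ch$half_lives_min > 2 & ch$half_lives_min < 20))
})
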