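test_that("organ activity fractions scale with phantom mass and weight", {
  p_eq <- patient_meta("P1", 70, 200)
  ph70 <- phantom("toy70", "male", 70, c(A = 1000, B = 500))
  expect_equal(organ_activity_fraction(10, "A", ph70, p_eq), 0.05)
  expect_equal(organ_activity_fraction(0, "A", ph70, p_eq), 0)
  p_heavier <- patient_meta("P2", 77, 200)    # Wp/Wph = 1.1
  expect_equal(organ_activity_fraction(10, "A", ph70, p_heavier), 0.055,
               tolerance = 1e-12)
  expect_error(organ_activity_fraction(1, "nope", ph70, p_eq), "not in phantom")
})

test_that("TIAC integration: closed-form single-point and sampled cases", {
  lam <- log(2) / 68
  # all activity in the region at t = 0: tail only, 1/lambda
  expect_equal(tiac(build_tac("wb", 0, 1, FALSE, unit = "fraction")),
               68 / (60 * log(2)), tolerance = 1e-9)
  # pure physical decay sampled at the clinical 3-point schedule: the
  # linear-from-zero leading segment undershoots the convex decay over
  # [0, t1] by more than the trapezoid overshoots, so the net error is
  # about -3.5 %; see the methods vignette
  t <- c(10, 60, 120)
  curve <- build_tac("r", t, 0.2 * exp(-lam * t), FALSE, unit = "fraction")
  expect_equal(tiac(curve), 0.2 * 68 / (60 * log(2)), tolerance = 0.04)
  # all-zero curve integrates to zero even for a non-decaying nuclide
  z <- build_tac("r", c(10, 60), c(0, 0), FALSE, unit = "fraction")
  expect_identical(tiac(z), 0)
  # explicit flag check
  cc <- build_tac("r", t, 0.2 * exp(-lam * t), TRUE, unit = "fraction")
  expect_error(tiac(cc), "decay-corrected")
  expect_error(tiac(build_tac("r", 10, 1, FALSE)), "fraction")
})

test_that("TIAC matches analytic integrals on dense grids within 0.1 %", {
  lam <- log(2) / 68
  t <- seq(0, 600, by = 0.1)
  # mono-exponential
  a1 <- 0.3 * exp(-(lam + 0.01) * t)
  exact1 <- 0.3 / (lam + 0.01) / 60
  got1 <- tiac(build_tac("m", t, a1, FALSE, unit = "fraction"))
  expect_lt(abs(got1 - exact1) / exact1, 1e-3)
  # bi-exponential (uptake-washout shape)
  f <- 0.1; ku <- 0.2; kw <- 0.005
  a2 <- f * ku / (ku - kw) * (exp(-kw * t) - exp(-ku * t)) * exp(-lam * t)
  exact2 <- uptake_washout_tiac(f, ku, kw, lam)
  got2 <- tiac(build_tac("b", t, a2, FALSE, unit = "fraction"))
  expect_lt(abs(got2 - exact2) / exact2, 1e-3)
})

test_that("TIAC is monotone nondecreasing in every sampled value", {
  lam <- log(2) / 68
  t <- c(10, 60, 120)
  a <- c(0.05, 0.04, 0.02)
  base <- tiac(build_tac("r", t, a, FALSE, unit = "fraction"))
  for (i in seq_along(a)) {
    a2 <- a; a2[i] <- a2[i] + 0.01
    expect_gt(tiac(build_tac("r", t, a2, FALSE, unit = "fraction")), base)
  }
})

test_that("TIAC sets enforce the whole-body decay bound", {
  bound <- 68 / (60 * log(2))
  expect_silent(tiac_set("P1", c(liver = bound * 0.9)))
  expect_error(tiac_set("P1", c(liver = bound, kidneys = 0.2)), "bound")
  expect_error(tiac_set("P1", c(liver = -0.1)), ">= 0")
})

test_that("cohort averaging uses available patients per region", {
  s1 <- tiac_set("P1", c(liver = 1.0))
  s2 <- tiac_set("P2", c(liver = 1.2))
  avg <- average_tiacs(list(s1, s2))
  expect_equal(unname(avg$tiac_h[["liver"]]), 1.1)
  # identity for a single patient
  one <- average_tiacs(list(s1))
  expect_equal(one$tiac_h, s1$tiac_h)
  # region missing in one patient: mean over reporters, with a warning
  s3 <- tiac_set("P3", c(liver = 0.8, kidneys = 0.3))
  expect_warning(avg3 <- average_tiacs(list(s1, s3)), "missing")
  expect_equal(unname(avg3$tiac_h[["kidneys"]]), 0.3)
  expect_equal(attr(avg3, "n_per_region")[["kidneys"]], 1L)
  expect_equal(unname(avg3$tiac_h[["liver"]]), 0.9)
  expect_error(average_tiacs(list()), "non-empty")
})

test_that("remainder closes the decay balance and is floored at zero", {
  total <- 68 / (60 * log(2))
  rem <- remainder_tiac(c(liver = 0.2, kidneys = 0.1),
                        bladder_tiac_h = 0.2, voided_decays_h = 0.3)
  expect_equal(rem, total - 0.2 - 0.1 - 0.2 - 0.3, tolerance = 1e-12)
  expect_equal(remainder_tiac(c(liver = total), 0.5, 0.5), 0)
})
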