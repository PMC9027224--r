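test_that("absorbed doses follow the TIAC-weighted S-value sum", {
  s <- toy_smatrix()
  d1 <- absorbed_doses(c(A = 1), smatrix("t", data.frame(
    target = "A", source = "A", s_mGy_per_MBq_h = 0.01)))
  expect_equal(unname(d1["A"]), 0.01)
  # hand sum with two sources
  d <- absorbed_doses(c(A = 1.5, B = 0.5), s)
  expect_equal(unname(d["A"]), 1.5 * 0.02 + 0.5 * 0.004, tolerance = 1e-12)
  expect_equal(unname(d["B"]), 1.5 * 0.003 + 0.5 * 0.05, tolerance = 1e-12)
  # linearity and permutation invariance
  d2 <- absorbed_doses(2 * c(A = 1.5, B = 0.5), s)
  expect_equal(d2, 2 * d, tolerance = 1e-12)
  dp <- absorbed_doses(c(B = 0.5, A = 1.5), s)
  expect_equal(dp[names(d)], d, tolerance = 1e-12)
  # unresolved sources are named in the error; aliases resolve them
  expect_error(absorbed_doses(c(A = 1, blood = 0.2), s), "blood")
  da <- absorbed_doses(c(A = 1, blood = 0.2), s, alias = c(blood = "A"))
  expect_equal(da, absorbed_doses(c(A = 1.2), s), tolerance = 1e-12)
  expect_error(absorbed_doses(c(A = -1), s), "negative")
})

test_that("S-matrix construction enforces completeness and nonnegativity", {
  expect_error(smatrix("t", data.frame(
    target = c("A", "B"), source = c("A", "A"),
    s_mGy_per_MBq_h = c(0.01, -0.001))), ">= 0")
  expect_error(smatrix("t", data.frame(
    target = c("A", "A", "B"), source = c("A", "B", "A"),
    s_mGy_per_MBq_h = c(0.01, 0.002, 0.001))), "complete")
})

test_that("effective dose is the tissue-weighted sex-averaged sum", {
  w <- icrp103_weights()
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # equal organ doses d give ED = d
  d <- setNames(rep(0.02, length(w)), names(w))
  expect_message(ed <- effective_dose(d, w), "single phantom")
  expect_equal(ed, 0.02, tolerance = 1e-12)
  # two-tissue weighted mean
  w2 <- c(a = 0.5, b = 0.5)
  expect_equal(suppressMessages(effective_dose(c(a = 0.02, b = 0.04), w2)),
               0.03, tolerance = 1e-12)
  # male-only input equals male ED; adding a zero-weight tissue changes nothing
  w3 <- c(a = 0.5, b = 0.5, c = 0)
  expect_equal(suppressMessages(effective_dose(c(a = 0.02, b = 0.04, c = 9), w3)),
               0.03, tolerance = 1e-12)
  # two sexes are averaged per tissue
  male <- c(a = 0.02, b = 0.04); female <- c(a = 0.04, b = 0.06)
  expect_equal(effective_dose(list(male = male, female = female), w2), 0.04,
               tolerance = 1e-12)
  expect_error(suppressMessages(effective_dose(c(a = 0.02), w2)), "missing")
})

test_that("dose coefficients scale linearly to the administered activity", {
  expect_equal(scale_to_administration(0.022, 200), 4.4, tolerance = 1e-12)
  expect_equal(scale_to_administration(0.05, 0), 0)
  expect_equal(scale_to_administration(0.0218, 200), 4.36, tolerance = 1e-12)
  expect_error(scale_to_administration(-1, 10), ">= 0")
})

test_that("toy pipeline TIAC -> dose -> ED matches a hand calculation", {
  lam <- log(2) / 68
  # region A: samples at 0/30/60 min; region B: all activity at t = 0
  a <- c(0.4, 0.2, 0.1)
  tiac_A <- tiac(build_tac("A", c(0, 30, 60), a, FALSE, unit = "fraction"))
  tiac_B <- tiac(build_tac("B", 0, 0.05, FALSE, unit = "fraction"))
  # spreadsheet arithmetic, written out independently
  hand_A <- (30 * (0.4 + 0.2) / 2 + 30 * (0.2 + 0.1) / 2 + 0.1 / lam) / 60
  hand_B <- 0.05 / lam / 60
  expect_equal(tiac_A, hand_A, tolerance = 1e-9)
  expect_equal(tiac_B, hand_B, tolerance = 1e-9)
  d <- absorbed_doses(c(A = tiac_A, B = tiac_B), toy_smatrix())
  hand_dA <- hand_A * 0.02 + hand_B * 0.004
  hand_dB <- hand_A * 0.003 + hand_B * 0.05
  expect_equal(unname(d["A"]), hand_dA, tolerance = 1e-9)
  ed <- suppressMessages(effective_dose(d, c(A = 0.7, B = 0.3)))
  expect_equal(ed, 0.7 * hand_dA + 0.3 * hand_dB, tolerance = 1e-9)
  expect_lte(ed, max(d))
})

test_that("packaged S-matrix is physically coherent", {
  s <- default_smatrix()
  expect_true(all(s$s >= 0))
  shared <- intersect(rownames(s$s), colnames(s$s))
  for (r in shared)
    expect_true(all(s$s[r, r] >= s$s[r, ]))
  # bladder wall is dominated by bladder contents
  expect_gt(s$s["urinary_bladder_wall", "urinary_bladder_contents"],
            max(s$s["urinary_bladder_wall",
                    setdiff(colnames(s$s), "urinary_bladder_contents")]))
})
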