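test_that("group mean/SEM matches the printed cohort summaries", {
  nen10 <- group_mean_sem(c(4.53, 10.36, 7.85, 7.39, 5.90))
  expect_equal(round_half_up(nen10$mean, 2), 7.21)
  bc1h <- group_mean_sem(c(8.75, 7.15, 2.29, 8.40, 4.99))
  expect_equal(round_half_up(bc1h$mean, 2), 6.32)
  const <- group_mean_sem(c(3, 3, 3))
  expect_equal(const$mean, 3)
  expect_equal(const$sem, 0)
  single <- group_mean_sem(5)
  expect_equal(single$sem, 0)
  expect_true(single$single)
  # SEM uses the n-1 sample SD
  expect_equal(group_mean_sem(c(2, 4))$sem, sd(c(2, 4)) / sqrt(2))
})

test_that("group mean/SEM is permutation invariant; SEM = 0 iff constant", {
  set.seed(5)
  for (i in 1:20) {
    x <- rlnorm(sample(2:9, 1), 1, 0.5)
    a <- group_mean_sem(x); b <- group_mean_sem(sample(x))
    expect_equal(a$mean, b$mean)
    expect_equal(a$sem, b$sem)
    expect_true((a$sem == 0) == (length(unique(x)) == 1L))
  }
})

test_that("the packaged uptake table reproduces all six group means at 2 d.p.", {
  s <- lesion_group_summary(example_lesions())
  get <- function(g, tp)
    round_half_up(s$suv_max_mean[s$group == g & s$timepoint == tp], 2)
  expect_equal(get("NEN", "PET_10"), 7.21)
  expect_equal(get("NEN", "PET_1h"), 9.60)
  expect_equal(get("NEN", "PET_2h"), 10.00)
  expect_equal(get("BC", "PET_10"), 5.09)
  expect_equal(get("BC", "PET_1h"), 6.32)
  expect_equal(get("BC", "PET_2h"), 6.55)
  # and the printed ranges
  expect_equal(s$suv_max_min[s$group == "NEN" & s$timepoint == "PET_10"], 4.53)
  expect_equal(s$suv_max_max[s$group == "NEN" & s$timepoint == "PET_1h"], 17.70)
  expect_equal(s$suv_max_min[s$group == "BC" & s$timepoint == "PET_1h"], 2.29)
})

test_that("tumor-to-organ ratios are per-patient ratios, averaged second", {
  expect_equal(tumor_to_organ(6, 2), 3)
  expect_equal(tumor_to_organ(2.5, 2.5), 1)
  expect_error(tumor_to_organ(3, 0), "> 0")
  r <- group_mean_sem(c(2, 4))
  expect_equal(r$mean, 3)
  expect_equal(r$sem, 1)   # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  df <- data.frame(patient_id = c("a", "b"), group = "BC",
                   timepoint = "PET_1h", organ = "liver", ratio = c(2, 4))
  summ <- ratio_group_summary(df)
  expect_equal(summ$ratio_mean, 3)
  expect_equal(summ$ratio_sem, 1)
})

test_that("hottest-lesion selection is maximal and tie-stable", {
  df <- data.frame(lesion_id = c("l1", "l2", "l3"),
                   suv_max = c(3.0, 7.1, 5.2))
  expect_equal(pick_hottest_lesion(df)$lesion_id, "l2")
  one <- df[1, ]
  expect_equal(pick_hottest_lesion(one)$lesion_id, "l1")
  tie <- data.frame(lesion_id = c("b", "a"), suv_max = c(5.0, 5.0))
  expect_equal(pick_hottest_lesion(tie)$lesion_id, "a")
})

test_that("lesion validation enforces labels and suv_mean <= suv_max", {
  bad_grp <- data.frame(patient_id = "x", group = "XX", timepoint = "PET_10",
                        suv_max = 2, suv_mean = 1)
  expect_error(validate_lesions(bad_grp), "group")
  bad_rel <- data.frame(patient_id = "x", group = "BC", timepoint = "PET_10",
                        suv_max = 2, suv_mean = 3)
  expect_error(validate_lesions(bad_rel), "suv_mean")
})
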