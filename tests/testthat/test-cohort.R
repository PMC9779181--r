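test_that("zero-variance configs reproduce the configured means exactly", {
  cfg <- cohortConfig(sdScale = 0)
  set.seed(1)
  s <- generateSubject("male", cfg)
  expect_equal(s$hr_rest, 53.9)
  expect_equal(s$vo2_rest, 3.7)
  expect_equal(s$hr_max_treadmill, 183.0)
  expect_equal(s$vo2_max_treadmill, 57.3)
  # reserve = max - rest at the configured male means
  expect_equal(s$hrr_treadmill, 129.1)
  expect_equal(s$vo2r_treadmill, 53.6)
  f <- generateSubject("female", cfg)
  expect_equal(f$hrr_treadmill, 129.5)
  expect_equal(f$vo2r_cycle, 40.3)
})

test_that("Monte-Carlo moments converge to the configured values", {
  cfg <- cohortConfig()
  set.seed(99)
  hrRest <- replicate(10000, generateSubject("male", cfg)$hr_rest)
  se <- 6.3 / sqrt(10000)
  expect_lt(abs(mean(hrRest) - 53.9), 3 * se)
  expect_lt(abs(sd(hrRest) - 6.3), 0.2)
})

test_that("noiseless identity truth puts %HRR exactly on the %VO2 grid", {
  cfg <- cohortConfig(sdScale = 0)
  set.seed(2)
  s <- generateSubject("male", cfg)
  pr <- protocolConfig("treadmill")
  tr <- truthParams(0, 1, 0, 0, 0)
  ser <- generateTestSeries(s, pr, tr, coefs = c(0, 1))
  yPct <- 100 * (ser$hr_bpm - s$hr_rest) / s$hrr_treadmill
  xPct <- 100 * (ser$vo2_mlkgmin - s$vo2_rest) / s$vo2r_treadmill
  expect_equal(yPct, xPct, tolerance = 1e-12)
  expect_equal(sort(unique(round(xPct, 9))), c(40, 55, 70, 85, 100))
})

test_that("default protocol yields 51 samples per graded test", {
  pr <- protocolConfig("treadmill")
  expect_identical(pr$n_samples, 51L)
  s <- generateSubject("female", cohortConfig(sdScale = 0))
  ser <- generateTestSeries(s, pr, truthParams())
  expect_identical(nrow(ser), 51L)
})

test_that("least squares on a long noiseless series recovers the truth", {
  cfg <- cohortConfig(sdScale = 0)
  set.seed(4)
  s <- generateSubject("male", cfg)
  pr <- protocolConfig("treadmill")
  ser <- generateTestSeries(s, pr, truthParams(18.26, 0.818, 0, 0, 0))
  y <- 100 * (ser$hr_bpm - s$hr_rest) / s$hrr_treadmill
  x <- 100 * (ser$vo2_mlkgmin - s$vo2_rest) / s$vo2r_treadmill
  co <- coef(lm(y ~ x))
  expect_equal(unname(co[1]), 18.26, tolerance = 1e-9)
  expect_equal(unname(co[2]), 0.818, tolerance = 1e-9)
})

test_that("a full cohort has 2 tests per subject and ~4184 samples total", {
  co <- generateCohort(masterSeed = 5)
  expect_identical(nrow(co$subjects), 41L)
  tests <- unique(co$series[c("subject_id", "mode")])
  expect_identical(nrow(tests), 82L)
  expect_lt(abs(nrow(co$series) - 4184) / 4184, 0.10)
})

test_that("cohorts are deterministic in the master seed and sensitive to it", {
  a <- generateCohort(cohortConfig(n_males = 3, n_females = 3), masterSeed = 11)
  b <- generateCohort(cohortConfig(n_males = 3, n_females = 3), masterSeed = 11)
  c <- generateCohort(cohortConfig(n_males = 3, n_females = 3), masterSeed = 12)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$series, b$series)
  expect_false(isTRUE(all.equal(a$series$hr_bpm, c$series$hr_bpm)))
})

test_that("physiologic-bound enforcement rejects impossible configurations", {
  p <- referenceCohortParams()
  p$mean[p$variable == "hr_max"] <- 40  # below resting HR
  expect_error(cohortConfig(params = p), "exceed resting")
  # hr policy: error mode raises when %HRR noise pushes HR out of band
  s <- generateSubject("male", cohortConfig(sdScale = 0))
  set.seed(8)
  expect_error(
    generateTestSeries(s, protocolConfig("treadmill"),
                       truthParams(0, 1, 0, 0, 40000), hrPolicy = "error"),
    "30-230")
})
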