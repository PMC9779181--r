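test_that("identity tests flag departures exactly when the CI excludes
           the reference", {
  # degenerate draws on the identity line: no flags
  it0 <- identityTest(list(mu_b0 = rep(0, 100), mu_b1 = rep(1, 100)))
  expect_false(it0$intercept_differs_from_zero)
  expect_false(it0$slope_differs_from_one)
  # Gaussian draws: CI matches the closed form
  set.seed(139)
  it <- identityTest(list(mu_b0 = rnorm(10000, 12, 2),
                          mu_b1 = rnorm(10000, 0.9, 0.02)))
  expect_equal(it$intercept[["lo"]], 12 - 1.959964 * 2, tolerance = 0.2)
  expect_equal(it$intercept[["hi"]], 12 + 1.959964 * 2, tolerance = 0.2)
  expect_true(it$intercept_differs_from_zero)
  expect_true(it$slope_differs_from_one)
  # flags must be consistent with the interval endpoints
  expect_identical(unname(it$slope[["hi"]] < 1), it$slope_differs_from_one)
})

test_that("fit comparisons estimate P(a > b) from paired draws", {
  same <- list(mu_b1 = rnorm(4000, 0.9, 0.02))
  self <- compareFits(same, same)
  expect_equal(self$p_a_gt_b, 0.5)  # identical draws: exact ties split
  expect_false(self$significant)
  set.seed(149)
  # female vs male treadmill slopes: Normal(0.943, 0.024) vs (0.876, 0.023)
  fem <- list(mu_b1 = rnorm(20000, 0.943, 0.024))
  mal <- list(mu_b1 = rnorm(20000, 0.876, 0.023))
  cmp <- compareFits(fem, mal)
  analytic <- pnorm(0.067 / sqrt(0.024^2 + 0.023^2))
  expect_equal(cmp$p_a_gt_b, analytic, tolerance = 0.015)
  expect_true(cmp$significant)
  # total separation
  far <- list(mu_b1 = rnorm(20000, 0.943 + 10 * 0.024, 0.024))
  expect_gt(compareFits(far, mal)$p_a_gt_b, 0.9999)
  # draw sets of unequal size are truncated to a common length
  expect_length(compareFits(list(mu_b1 = rnorm(100)),
                            list(mu_b1 = rnorm(50)))$diff, 50)
})

test_that("intensity predictions reproduce the plug-in arithmetic on
           degenerate draws", {
  # male treadmill %VO2max posterior means: 45% -> 51.84 -> displays 52
  d <- list(mu_b0 = rep(12.42, 50), mu_b1 = rep(0.876, 50))
  pt <- predictIntensity(d)
  expect_equal(pt$mode_raw[1], 12.42 + 0.876 * 45)
  expect_identical(pt$hrr_pct[1], 52)
  expect_identical(pt$hrr_pct[5], 87)  # 86.88 at 85%
  # identity draws reproduce the targets with no flags
  pid <- predictIntensity(list(mu_b0 = rep(0, 50), mu_b1 = rep(1, 50)))
  expect_equal(pid$mode_raw, c(45, 55, 65, 75, 85))
  expect_false(any(pid$flagged))
})

test_that("KDE mode and equal-tailed CI converge to the Gaussian closed
           form", {
  set.seed(151)
  d <- list(mu_b0 = rnorm(20000, 12.42, 2.24),
            mu_b1 = rnorm(20000, 0.876, 0.023))
  pt <- predictIntensity(d)
  y65 <- 12.42 + 0.876 * 65
  sd65 <- sqrt(2.24^2 + 65^2 * 0.023^2)
  expect_equal(pt$mode_raw[pt$target == 65], y65, tolerance = 0.3)
  expect_equal(pt$lo[pt$target == 65], y65 - 1.959964 * sd65,
               tolerance = 0.3)
  # flag pattern of an identity-approaching posterior: overestimation
  # flagged at 45-55%, gone by 85%
  expect_true(all(pt$flagged[pt$target %in% c(45, 55)]))
  expect_false(pt$flagged[pt$target == 85])
  # CI endpoints are affine-equivariant
  d2 <- list(mu_b0 = 2 * d$mu_b0 + 3, mu_b1 = 2 * d$mu_b1)
  pt2 <- predictIntensity(d2)
  expect_equal(pt2$lo, 2 * pt$lo + 3, tolerance = 1e-10)
})

test_that("report assembly requires all eight cells and names missing
           ones", {
  set.seed(157)
  mkFit <- function(b0, b1) list(mu_b0 = rnorm(500, b0, 1.5),
                                 mu_b1 = rnorm(500, b1, 0.02))
  fits <- list()
  for (sc in c("percent_vo2max", "percent_vo2r"))
    for (sx in c("male", "female"))
      for (md in c("treadmill", "cycle"))
        fits[[sc]][[sx]][[md]] <- mkFit(12, 0.88)
  rep1 <- buildReport(fits)
  expect_identical(nrow(rep1$identity), 8L)
  expect_identical(nrow(rep1$predictions), 40L)
  expect_identical(nrow(rep1$contrasts), 16L)
  fits$percent_vo2r$female$cycle <- NULL
  expect_error(buildReport(fits), "percent_vo2r, female, cycle")
})

test_that("display rounding rounds halves away from zero", {
  expect_identical(hrvo2:::roundHalfUp(51.5), 52)
  expect_identical(hrvo2:::roundHalfUp(52.5), 53)
  expect_identical(hrvo2:::roundHalfUp(-0.5), -1)
  expect_identical(hrvo2:::roundHalfUp(86.88), 87)
})
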