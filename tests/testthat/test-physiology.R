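test_that("resting extraction averages only the retained window", {
  expect_equal(extractResting(rep(60, 30), rep(3.6, 30))$hr_rest, 60)
  hr <- c(rep(80, 5), rep(60, 25))
  expect_equal(extractResting(hr, rep(3.5, 30))$hr_rest, 60)
  # invariance to the discarded prefix
  hr2 <- c(rep(999 / 10, 5), rep(60, 25))
  expect_equal(extractResting(hr2, rep(3.5, 30))$hr_rest, 60)
  expect_error(extractResting(rep(60, 5), rep(3.5, 5)), "no samples remain")
})

test_that("maximal extraction matches a brute-force window scan", {
  bruteForce <- function(t, hr, vo2, rer, k = 2, gate = 1.10) {
    best <- -Inf; found <- FALSE
    for (i in seq_len(length(t) - k + 1)) {
      win <- i:(i + k - 1)
      if (mean(rer[win]) >= gate && mean(vo2[win]) > best) {
        best <- mean(vo2[win]); found <- TRUE
      }
    }
    list(found = found, vo2_max = best, hr_max = max(hr))
  }
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(8:40, 1)
    fx <- testSeriesFixture(n,
                            vo2 = cumsum(runif(n, 0, 2)) + 20,
                            rer = runif(n, 1.0, 1.2),
                            hr = runif(n, 90, 200))
    oracle <- bruteForce(fx$t, fx$hr, fx$vo2, fx$rer)
    if (!oracle$found) {
      expect_error(extractMaximal(fx$t, fx$hr, fx$vo2, fx$rer),
                   class = "hrvo2_no_qualifying_window")
    } else {
      got <- extractMaximal(fx$t, fx$hr, fx$vo2, fx$rer)
      expect_equal(got$vo2_max, oracle$vo2_max)
      expect_equal(got$hr_max, oracle$hr_max)
    }
  }
})

test_that("maximal extraction honors the RER gate and monotone ramps", {
  fx <- testSeriesFixture(12)
  mx <- extractMaximal(fx$t, fx$hr, fx$vo2, fx$rer)
  expect_equal(mx$vo2_max, mean(fx$vo2[11:12]))  # last overlapping pair
  # highest-VO2 window disqualified by RER 1.05 -> next best qualifying
  vo2 <- c(30, 30, 30, 30, 50, 50, 40, 40)
  rer <- c(1.15, 1.15, 1.15, 1.12, 1.05, 1.04, 1.05, 1.15)
  mx2 <- extractMaximal(seq_len(8) * 15, rep(150, 8), vo2, rer)
  expect_equal(mx2$vo2_max, 40)
  expect_error(
    extractMaximal(fx$t, fx$hr, fx$vo2, rep(1.0, 12)),
    class = "hrvo2_no_qualifying_window")
})

test_that("maximal-effort validation applies the two-of-three rule", {
  # representative maximal male treadmill test: RER 1.20, HRmax 183 at age 25
  v <- effortValid(1.20, 183, 25, plateau = FALSE)
  expect_true(v$criterion_rer); expect_true(v$criterion_hr)
  expect_false(v$criterion_plateau); expect_true(v$valid)
  # all three fail
  expect_false(effortValid(1.00, 150, 25, plateau = FALSE)$valid)
  # every two-of-three combination validates
  expect_true(effortValid(1.20, 190, 25, plateau = FALSE)$valid)  # a, b
  expect_true(effortValid(1.20, 150, 25, plateau = TRUE)$valid)   # a, c
  expect_true(effortValid(1.00, 190, 25, plateau = TRUE)$valid)   # b, c
  # one criterion alone is insufficient
  expect_false(effortValid(1.20, 150, 25, plateau = FALSE)$valid)
})

test_that("percent scaling anchors at rest and max and is affine", {
  expect_equal(toPercent(54, 54, 183, "reserve"), 0)
  expect_equal(toPercent(183, 54, 183, "reserve"), 100)
  expect_equal(toPercent(57.3, 0, 57.3, "of_max"), 100)
  # reserve and of_max agree when rest = 0
  v <- seq(5, 50, by = 5)
  expect_equal(toPercent(v, 0, 57.3, "reserve"), toPercent(v, 0, 57.3, "of_max"))
  # affine and strictly increasing
  p <- toPercent(v, 3.7, 57.3, "reserve")
  expect_true(all(diff(p) > 0))
  expect_equal(diff(p), rep(diff(p)[1], length(p) - 1))
  # round trip
  expect_equal(fromPercent(p, 3.7, 57.3, "reserve"), v)
  expect_error(toPercent(50, 60, 60, "reserve"), "max > rest")
})

test_that("reserve arithmetic reproduces the reference cohort reserves", {
  # male treadmill: HRR denominator 129.1 bpm, VO2R 53.6 mL/kg/min
  rs <- reserves(53.9, 183.0, 3.7, 57.3)
  expect_equal(rs$hrr, 129.1)
  expect_equal(rs$vo2r, 53.6)
})

test_that("cohort derivation and scaling produce coherent model inputs", {
  co <- smallCohort(seed = 21)
  d <- deriveCohort(co)
  expect_identical(nrow(d), 16L)
  expect_true(all(d$hrr > 0 & d$vo2r > 0))
  sc <- scaleSeries(co, d, xScale = "percent_vo2r", mode = "treadmill")
  expect_identical(attr(sc, "x_scale"), "percent_vo2r")
  expect_true(all(sc$x >= 0 & sc$x <= 100 + 1e-9))
  # series-derived maxima stay close to the subject-record values
  d2 <- deriveCohort(co, maxSource = "series")
  expect_lt(max(abs(d2$vo2_max - d$vo2_max) / d$vo2_max), 0.15)
})
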