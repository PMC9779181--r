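test_that("MCMC bookkeeping follows the saved-draw contract", {
  cfg <- mcmcConfig()
  expect_identical(cfg$n_saved, 10000L)
  expect_error(mcmcConfig(thin = 3, n_iterations = 11000, burn_in = 1000))
  cfg2 <- quickMcmc()
  dat <- simScaled(4, truthParams(10, 0.9, 9, 0.004, 9), seed = 5)
  fit <- fitHierarchical(dat, modelSpec(), cfg2)
  expect_identical(nrow(fit$draws), cfg2$n_saved)
  expect_true(all(fit$draws$sigma2 > 0))
  expect_true(all(fit$draws$sigma2_slopes > 0))
  expect_identical(length(fit$chain), cfg2$n_saved)
})

test_that("noiseless identity data pins the posterior to the identity line", {
  xg <- rep(seq(30, 100, by = 10), each = 4)
  dat <- do.call(rbind, lapply(1:12, function(i)
    data.frame(subject_id = i, x = xg, y = xg)))
  # tiny jitter keeps the residual variance identified
  set.seed(7)
  dat$y <- dat$y + rnorm(nrow(dat), 0, 0.05)
  fit <- fitHierarchical(dat, modelSpec(), quickMcmc(seed = 2))
  expect_lt(abs(mean(fit$draws$mu_b0) - 0), 0.1)
  expect_lt(abs(mean(fit$draws$mu_b1) - 1), 0.01)
})

test_that("Gibbs draws match the analytic conjugate posterior in the
           known-variance single-subject sub-model", {
  set.seed(13)
  x <- runif(300, -30, 30)
  b0True <- 12; b1True <- 0.85; s2 <- 1
  y <- b0True + b1True * x + rnorm(300, 0, sqrt(s2))
  priorMean <- c(10, 1); priorVar <- c(25, 0.04)
  oracle <- conjugateLinePosterior(x, y, s2, priorMean, priorVar)
  fit <- fitHierarchical(
    data.frame(subject_id = 1, x = x, y = y),
    modelSpec(),
    mcmcConfig(n_chains = 1, n_iterations = 101000, burn_in = 1000,
               thin = 1, master_seed = 3),
    fixed = list(mu_b0 = priorMean[1], mu_b1 = priorMean[2],
                 sigma2 = s2, sigma2_intercepts = priorVar[1],
                 sigma2_slopes = priorVar[2]))
  b0d <- fit$subjects$b0[, 1]; b1d <- fit$subjects$b1[, 1]
  expect_lt(abs(mean(b0d) - oracle$mean[1]), 1.5e-3)
  expect_lt(abs(mean(b1d) - oracle$mean[2]), 1.5e-3)
  expect_lt(abs(sd(b0d) - sqrt(oracle$cov[1, 1])), 1.5e-3)
  expect_lt(abs(sd(b1d) - sqrt(oracle$cov[2, 2])), 1.5e-3)
})

test_that("log joint density matches a hand-summed fixture and respects
           the support", {
  dat <- data.frame(subject_id = rep(1:2, each = 3),
                    x = c(40, 60, 80, 45, 65, 85),
                    y = c(48, 64, 81, 52, 70, 89))
  par <- list(mu_b0 = 10, mu_b1 = 0.9, sigma2 = 4,
              sigma2_intercepts = 16, sigma2_slopes = 0.01,
              b0 = c(9, 11), b1 = c(0.95, 0.88))
  spec <- modelSpec()
  # hand sum: every Gaussian/Gamma term written out explicitly
  ln <- function(v, m, s2v) -0.5 * log(2 * pi * s2v) - (v - m)^2 / (2 * s2v)
  lg <- function(v, a, r) a * log(r) - lgamma(a) + (a - 1) * log(v) - r * v
  mu <- ifelse(dat$subject_id == 1, 9 + 0.95 * dat$x, 11 + 0.88 * dat$x)
  expected <- sum(ln(dat$y, mu, 4)) +
    ln(9, 10, 16) + ln(11, 10, 16) +
    ln(0.95, 0.9, 0.01) + ln(0.88, 0.9, 0.01) +
    ln(10, 0, 1000) + ln(0.9, 1, 10) +
    lg(4, 1.1, 0.01) + lg(16, 1.1, 0.01) + lg(0.01, 1.1, 1)
  expect_equal(logJoint(par, dat, spec), expected, tolerance = 1e-10)
  # outside support
  parBad <- par; parBad$sigma2 <- -1
  expect_identical(logJoint(parBad, dat, spec), -Inf)
  # full translation invariance: shift y, b0, mu_b0 and the hyperprior mean
  sh <- 7.5
  datS <- dat; datS$y <- dat$y + sh
  parS <- par; parS$b0 <- par$b0 + sh; parS$mu_b0 <- par$mu_b0 + sh
  specS <- modelSpec(muB0Prior = c(sh, 1000))
  expect_equal(logJoint(parS, datS, specS), logJoint(par, dat, spec),
               tolerance = 1e-10)
})

test_that("per-subject posterior means shrink from least squares toward
           the population mean", {
  # centred x decouples intercept and slope, making the interpolation
  # property exact (up to Monte-Carlo error) in the known-variance case
  dat <- simScaled(10, truthParams(15, 0.85, 36, 0.005, 49), seed = 17,
                   xGrid = rep(c(-30, -10, 10, 30), each = 4))
  fit <- fitHierarchical(dat, modelSpec(), quickMcmc(seed = 6, chains = 8),
                         fixed = list(mu_b0 = 15, mu_b1 = 0.85,
                                      sigma2 = 49, sigma2_intercepts = 36,
                                      sigma2_slopes = 0.005))
  postB0 <- colMeans(fit$subjects$b0)
  postB1 <- colMeans(fit$subjects$b1)
  olsB0 <- fit$ols$b0; olsB1 <- fit$ols$b1
  eps <- 0.2
  expect_true(all(postB0 >= pmin(olsB0, 15) - eps &
                    postB0 <= pmax(olsB0, 15) + eps))
  expect_true(all(postB1 >= pmin(olsB1, 0.85) - 0.01 &
                    postB1 <= pmax(olsB1, 0.85) + 0.01))
})

test_that("the posterior is exchangeable over subject order and
           deterministic in the seed", {
  dat <- simScaled(6, truthParams(12, 0.9, 25, 0.004, 25), seed = 23)
  fitA <- fitHierarchical(dat, modelSpec(), quickMcmc(seed = 9))
  fitB <- fitHierarchical(dat, modelSpec(), quickMcmc(seed = 9))
  expect_identical(fitA$draws, fitB$draws)
  # permuted subject blocks: same posterior up to Monte-Carlo error
  perm <- dat[order(match(dat$subject_id, c(4, 2, 6, 1, 5, 3))), ]
  fitP <- fitHierarchical(perm, modelSpec(), quickMcmc(seed = 10))
  expect_lt(abs(mean(fitP$draws$mu_b0) - mean(fitA$draws$mu_b0)), 0.5)
  expect_lt(abs(mean(fitP$draws$mu_b1) - mean(fitA$draws$mu_b1)), 0.01)
})

test_that("precision-scale gamma priors remain available and agree on the
           population means", {
  dat <- simScaled(8, truthParams(15, 0.85, 25, 0.004, 25), seed = 29)
  fitV <- fitHierarchical(dat, modelSpec(gammaOn = "variance"),
                          quickMcmc(seed = 4))
  fitP <- fitHierarchical(dat, modelSpec(gammaOn = "precision"),
                          quickMcmc(seed = 4))
  expect_lt(abs(mean(fitV$draws$mu_b0) - mean(fitP$draws$mu_b0)), 1.0)
  expect_lt(abs(mean(fitV$draws$mu_b1) - mean(fitP$draws$mu_b1)), 0.05)
  # the precision reading caps the slope precision near its prior scale,
  # inflating the slope dispersion relative to the variance reading
  expect_gt(mean(fitP$draws$sigma2_slopes), mean(fitV$draws$sigma2_slopes))
})

test_that("draw serialization round-trips draws, spec and config", {
  dat <- simScaled(4, truthParams(12, 0.9, 9, 0.004, 16), seed = 31)
  fit <- fitHierarchical(dat, modelSpec("percent_vo2max"), quickMcmc(seed = 8))
  path <- file.path(tempdir(), "draws.csv")
  writeDraws(fit, path)
  back <- readDraws(path)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_identical(back$spec$xScale, "percent_vo2max")
  expect_identical(back$config$n_saved, fit$config$n_saved)
  expect_identical(back$chain, fit$chain)
})

test_that("degenerate designs warn but NaN input fails", {
  dat <- rbind(data.frame(subject_id = 1, x = rep(50, 6),
                          y = rnorm(6, 60, 1)),
               data.frame(subject_id = 2, x = c(40, 50, 60, 70, 80, 90),
                          y = c(44, 55, 64, 76, 84, 95)))
  expect_warning(fitHierarchical(dat, modelSpec(),
                                 quickMcmc(seed = 3, chains = 2)),
                 "zero x-variance")
  datBad <- dat; datBad$y[1] <- NaN
  expect_error(fitHierarchical(datBad, modelSpec(), quickMcmc(seed = 3)))
})
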