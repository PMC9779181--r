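# shared fixture builders (all data generated in code at test time)

# small cohort for fast end-to-end runs
smallCohort <- function(seed = 3, nm = 4, nf = 4) {
  generateCohort(cohortConfig(n_males = nm, n_females = nf),
                 masterSeed = seed)
}

# light MCMC configuration for unit tests (400 saved draws)
quickMcmc <- function(seed = 1, chains = 4, iter = 1600, burn = 600,
                      thin = 10) {
  mcmcConfig(chains, iter, burn, thin, master_seed = seed)
}

# scaled data simulated directly from the hierarchical generating model
simScaled <- function(nSubjects, truth, seed,
                      xGrid = rep(c(40, 55, 70, 85, 100), each = 10),
                      flip = FALSE) {
  set.seed(seed)
  b0dev <- rnorm(nSubjects, 0, sqrt(truth$var_intercepts))
  b1dev <- rnorm(nSubjects, 0, sqrt(truth$var_slopes))
  if (flip) {  # antithetic partner: subject effects negated
    b0dev <- -b0dev
    b1dev <- -b1dev
  }
  rows <- lapply(seq_len(nSubjects), function(i) {
    data.frame(subject_id = i, x = xGrid,
               y = truth$mu_b0 + b0dev[i] + (truth$mu_b1 + b1dev[i]) * xGrid +
                 rnorm(length(xGrid), 0, sqrt(truth$var_resid)))
  })
  do.call(rbind, rows)
}

# graded-test series fixture with configurable RER profile
testSeriesFixture <- function(n = 20, interval = 15, vo2 = NULL, rer = NULL,
                              hr = NULL) {
  t <- seq_len(n) * interval
  list(t = t,
       hr = if (is.null(hr)) seq(100, 180, length.out = n) else hr,
       vo2 = if (is.null(vo2)) seq(20, 55, length.out = n) else vo2,
       rer = if (is.null(rer)) rep(1.15, n) else rer)
}

# AR(1) chain with marginal unit variance
ar1Chain <- function(n, rho, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = rho), n, sd = sqrt(1 - rho^2)))
}
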