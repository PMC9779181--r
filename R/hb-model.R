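#' MCMC configuration
#'
#' Defaults mirror the published sampling plan: 20 chains of 11,000
#' iterations with 1000 burn-in, thinned by 20, giving
#' 20 x (11,000 - 1000) / 20 = 10,000 saved draws per parameter.
#'
#' @param n_chains Number of chains.
#' @param n_iterations Total iterations per chain (including burn-in).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param master_seed Integer seed; per-chain seeds are derived from it.
#' @return A list of class `"mcmcConfig"` with a `n_saved` field.
#' @export
mcmcConfig <- function(n_chains = 20, n_iterations = 11000,
                       burn_in = 1000, thin = 20, master_seed = 1L) {
  stopifnot(n_chains >= 1, thin >= 1, burn_in >= 0,
            n_iterations > burn_in,
            (n_iterations - burn_in) %% thin == 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 master_seed = as.integer(master_seed),
                 n_saved = as.integer(n_chains *
                                        (n_iterations - burn_in) / thin)),
            class = "mcmcConfig")
}

#' Hierarchical model specification
#'
#' The likelihood is y_ij ~ Normal(b0_i + b1_i x_ij, sigma2) with
#' subject-level Normal priors b0_i ~ N(mu_b0, sigma2_intercepts),
#' b1_i ~ N(mu_b1, sigma2_slopes); hyperpriors mu_b0 ~ N(0, 1000) and
#' mu_b1 ~ N(1, 10) (second parameter a variance); and Gamma(1.1, 0.01)
#' priors on the residual and intercept dispersion components and
#' Gamma(1.1, 1) on the slope component. By default the Gamma priors are
#' read literally as priors on the variances (`gammaOn = "variance"`,
#' updated by slice sampling on the log variance); `gammaOn =
#' "precision"` instead places them on the precisions, the fully
#' conjugate convention of the usual Gibbs-sampling toolchain. The
#' variance reading is the default because a Gamma(1.1, 1) prior on the
#' slope precision caps that precision near its prior scale and inflates
#' the slope dispersion by an order of magnitude; see the methods
#' vignette.
#'
#' @param xScale `"percent_vo2r"` or `"percent_vo2max"` (bookkeeping tag).
#' @param gammaOn `"variance"` (default) or `"precision"`.
#' @param muB0Prior,muB1Prior Length-2 `c(mean, variance)` hyperpriors.
#' @param residPrior,interceptPrior,slopePrior Length-2
#'   `c(shape, rate)` Gamma priors for the dispersion components.
#' @return A list of class `"modelSpec"`.
#' @export
modelSpec <- function(xScale = c("percent_vo2r", "percent_vo2max"),
                      gammaOn = c("variance", "precision"),
                      muB0Prior = c(0, 1000), muB1Prior = c(1, 10),
                      residPrior = c(1.1, 0.01),
                      interceptPrior = c(1.1, 0.01),
                      slopePrior = c(1.1, 1)) {
  xScale <- match.arg(xScale)
  gammaOn <- match.arg(gammaOn)
  stopifnot(muB0Prior[2] > 0, muB1Prior[2] > 0,
            all(c(residPrior, interceptPrior, slopePrior) > 0))
  structure(list(xScale = xScale, gammaOn = gammaOn,
                 muB0Prior = muB0Prior, muB1Prior = muB1Prior,
                 residPrior = residPrior, interceptPrior = interceptPrior,
                 slopePrior = slopePrior),
            class = "modelSpec")
}

popParams <- function() c("mu_b0", "mu_b1", "sigma2", "sigma2_intercepts",
                          "sigma2_slopes")

# per-subject sufficient statistics and least-squares starts
subjectStats <- function(data) {
  stopifnot(all(c("subject_id", "x", "y") %in% names(data)),
            all(is.finite(data$x)), all(is.finite(data$y)))
  ids <- unique(data$subject_id)
  st <- lapply(ids, function(id) {
    d <- data[data$subject_id == id, ]
    n <- nrow(d)
    sxx <- sum(d$x^2)
    varx <- sxx / n - (sum(d$x) / n)^2
    # per-subject OLS; fall back to a flat line when x is degenerate
    if (varx > 1e-10) {
      b1 <- (sum(d$x * d$y) / n - mean(d$x) * mean(d$y)) / varx
      b0 <- mean(d$y) - b1 * mean(d$x)
    } else {
      warning("subject ", id, " has (near-)zero x-variance; its slope is ",
              "weakly identified", call. = FALSE)
      b1 <- 1; b0 <- mean(d$y) - mean(d$x)
    }
    c(n = n, Sx = sum(d$x), Sy = sum(d$y), Sxx = sxx,
      Sxy = sum(d$x * d$y), Syy = sum(d$y^2), olsB0 = b0, olsB1 = b1)
  })
  st <- do.call(rbind, st)
  rownames(st) <- as.character(ids)
  st
}

chainSeed <- function(masterSeed, chain) {
  as.integer((as.numeric(masterSeed) + 7919 * chain) %%
               (.Machine$integer.max - 1) + 1)
}

#' Fit the hierarchical %HRR-%VO2 model by Gibbs sampling
#'
#' Runs `config$n_chains` independent chains of a blocked Gibbs sampler:
#' each subject's (b0, b1) pair is drawn jointly from its bivariate
#' normal full conditional, the population means from their normal full
#' conditionals, and the three dispersion components from gamma full
#' conditionals on the precision scale (under `gammaOn = "precision"`;
#' slice sampling on the log variance otherwise). Chains start at the per-subject
#' least-squares estimates perturbed by chain-indexed Gaussian noise
#' (overdispersed starts, so the potential scale reduction factor is
#' meaningful), and each chain's RNG stream is seeded deterministically
#' from `config$master_seed`.
#'
#' @param data A data frame with columns `subject_id`, `x`, `y` (e.g.
#'   from [scaleSeries()]); at least 2 subjects with 2 points each.
#' @param spec A [modelSpec()].
#' @param config An [mcmcConfig()].
#' @param fixed Optional named list pinning parameters instead of
#'   sampling them (any of `mu_b0`, `mu_b1`, `sigma2`,
#'   `sigma2_intercepts`, `sigma2_slopes`); a validation harness for
#'   reduced conjugate sub-models.
#' @param sliceWidth Initial log-scale slice-sampler bracket width
#'   (variance mode only).
#' @return An object of class `"hrvo2Fit"`: list with `draws` (named
#'   list of n_saved-draw vectors for the population parameters),
#'   `chain` (chain index per draw), `raw` (unthinned post-burn-in
#'   population draws, chains stacked; used by run-length diagnostics),
#'   `subjects` (list with `b0`, `b1` draw matrices, one column per
#'   subject), `spec`, `config`, `subject_ids`.
#' @export
fitHierarchical <- function(data, spec = modelSpec(), config = mcmcConfig(),
                            fixed = list(), sliceWidth = 1) {
  stopifnot(inherits(spec, "modelSpec"), inherits(config, "mcmcConfig"))
  st <- subjectStats(data)
  m <- nrow(st)
  if (m < 2 && !length(fixed))
    stop("need at least 2 subjects", call. = FALSE)
  if (any(st[, "n"] < 2)) stop("each subject needs >= 2 points", call. = FALSE)
  badFixed <- setdiff(names(fixed), popParams())
  if (length(badFixed)) stop("unknown fixed parameter: ", badFixed[1])

  nSaveChain <- (config$n_iterations - config$burn_in) / config$thin
  nSave <- config$n_chains * nSaveChain
  draws <- matrix(NA_real_, nSave, 5,
                  dimnames = list(NULL, popParams()))
  b0Draws <- matrix(NA_real_, nSave, m)
  b1Draws <- matrix(NA_real_, nSave, m)
  chainIdx <- rep(seq_len(config$n_chains), each = nSaveChain)
  nRawChain <- config$n_iterations - config$burn_in
  rawDraws <- matrix(NA_real_, config$n_chains * nRawChain, 5,
                     dimnames = list(NULL, popParams()))

  # moment-based centre for overdispersed starts
  olsB0 <- st[, "olsB0"]; olsB1 <- st[, "olsB1"]
  s2Start <- max(1e-3, meanResidVar(st))
  for (ch in seq_len(config$n_chains)) {
    set.seed(chainSeed(config$master_seed, ch))
    spread <- 0.5 + 1.5 * (ch - 1) / max(1, config$n_chains - 1)
    b0Init <- olsB0 + stats::rnorm(m, 0, 2 * spread)
    b1Init <- olsB1 + stats::rnorm(m, 0, 0.05 * spread)
    muB0Init <- if (!is.null(fixed$mu_b0)) fixed$mu_b0 else
      mean(b0Init) + stats::rnorm(1, 0, 2 * spread)
    muB1Init <- if (!is.null(fixed$mu_b1)) fixed$mu_b1 else
      mean(b1Init) + stats::rnorm(1, 0, 0.05 * spread)
    jit <- function(v) v * exp(stats::rnorm(1, 0, 0.3 * spread))
    s2Init <- if (!is.null(fixed$sigma2)) fixed$sigma2 else jit(s2Start)
    s2IInit <- if (!is.null(fixed$sigma2_intercepts)) fixed$sigma2_intercepts
      else jit(max(stats::var(olsB0), 1e-3))
    s2SInit <- if (!is.null(fixed$sigma2_slopes)) fixed$sigma2_slopes
      else jit(max(stats::var(olsB1), 1e-4))

    res <- .gibbsHierChain(
      st[, "n"], st[, "Sx"], st[, "Sy"], st[, "Sxx"], st[, "Sxy"],
      st[, "Syy"],
      config$n_iterations, config$burn_in, config$thin,
      spec$muB0Prior[1], spec$muB0Prior[2],
      spec$muB1Prior[1], spec$muB1Prior[2],
      spec$residPrior[1], spec$residPrior[2],
      spec$interceptPrior[1], spec$interceptPrior[2],
      spec$slopePrior[1], spec$slopePrior[2],
      spec$gammaOn == "variance",
      b0Init, b1Init, muB0Init, muB1Init, s2Init, s2IInit, s2SInit,
      !is.null(fixed$mu_b0), !is.null(fixed$mu_b1),
      !is.null(fixed$sigma2), !is.null(fixed$sigma2_intercepts),
      !is.null(fixed$sigma2_slopes), sliceWidth)
    rows <- (ch - 1) * nSaveChain + seq_len(nSaveChain)
    draws[rows, ] <- res$pop
    b0Draws[rows, ] <- res$b0
    b1Draws[rows, ] <- res$b1
    rawDraws[(ch - 1) * nRawChain + seq_len(nRawChain), ] <- res$raw
  }

  out <- list(draws = as.data.frame(draws), chain = chainIdx,
              raw = rawDraws,
              subjects = list(b0 = b0Draws, b1 = b1Draws),
              subject_ids = rownames(st), spec = spec, config = config,
              ols = data.frame(subject_id = rownames(st),
                               b0 = olsB0, b1 = olsB1))
  class(out) <- "hrvo2Fit"
  out
}

# pooled residual variance around per-subject OLS lines
meanResidVar <- function(st) {
  sse <- sum(st[, "Syy"] - 2 * st[, "olsB0"] * st[, "Sy"] -
               2 * st[, "olsB1"] * st[, "Sxy"] +
               2 * st[, "olsB0"] * st[, "olsB1"] * st[, "Sx"] +
               st[, "olsB0"]^2 * st[, "n"] + st[, "olsB1"]^2 * st[, "Sxx"])
  max(sse, 0) / max(1, sum(st[, "n"]) - 2 * nrow(st))
}

#' Unnormalized log posterior density of the hierarchical model
#'
#' A validation harness for the sampler: evaluates the log joint density
#' (likelihood times all priors) at a given parameter configuration.
#' Returns `-Inf` outside the support (any non-positive variance).
#'
#' @param params Named list: `mu_b0`, `mu_b1`, `sigma2`,
#'   `sigma2_intercepts`, `sigma2_slopes`, and vectors `b0`, `b1` of
#'   per-subject coefficients (in `subject_id` sort order of `data`).
#' @param data Data frame with `subject_id`, `x`, `y`.
#' @param spec A [modelSpec()].
#' @return Scalar log density (unnormalized).
#' @export
logJoint <- function(params, data, spec = modelSpec()) {
  v <- c(params$sigma2, params$sigma2_intercepts, params$sigma2_slopes)
  if (any(!is.finite(unlist(params[c("mu_b0", "mu_b1")]))) ||
      any(!is.finite(v)) || any(v <= 0)) return(-Inf)
  ids <- unique(data$subject_id)
  stopifnot(length(params$b0) == length(ids),
            length(params$b1) == length(ids))
  i <- match(data$subject_id, ids)
  mu <- params$b0[i] + params$b1[i] * data$x
  ll <- sum(stats::dnorm(data$y, mu, sqrt(params$sigma2), log = TRUE))
  lp <- sum(stats::dnorm(params$b0, params$mu_b0,
                         sqrt(params$sigma2_intercepts), log = TRUE)) +
    sum(stats::dnorm(params$b1, params$mu_b1,
                     sqrt(params$sigma2_slopes), log = TRUE)) +
    stats::dnorm(params$mu_b0, spec$muB0Prior[1], sqrt(spec$muB0Prior[2]),
                 log = TRUE) +
    stats::dnorm(params$mu_b1, spec$muB1Prior[1], sqrt(spec$muB1Prior[2]),
                 log = TRUE)
  gpar <- rbind(spec$residPrior, spec$interceptPrior, spec$slopePrior)
  comp <- if (spec$gammaOn == "variance") v else 1 / v
  # Jacobian of the precision reparameterization: d(tau)/d(sigma2) = s2^-2
  jac <- if (spec$gammaOn == "variance") 0 else -2 * sum(log(v))
  lg <- sum(stats::dgamma(comp, shape = gpar[, 1], rate = gpar[, 2],
                          log = TRUE)) + jac
  ll + lp + lg
}

#' Analytic posterior for one subject's line with known variances
#'
#' Closed-form conjugate posterior of (b0, b1) for a single subject's
#' regression with known residual variance and independent normal priors
#' on the two coefficients. The independent oracle used to validate the
#' Gibbs sampler's subject-level update.
#'
#' @param x,y Data vectors.
#' @param sigma2 Known residual variance.
#' @param priorMean,priorVar Length-2: prior means and variances of
#'   (b0, b1).
#' @return List with `mean` (length 2) and `cov` (2x2 matrix).
#' @export
conjugateLinePosterior <- function(x, y, sigma2, priorMean, priorVar) {
  X <- cbind(1, x)
  P <- crossprod(X) / sigma2 + diag(1 / priorVar)
  h <- crossprod(X, y) / sigma2 + priorMean / priorVar
  cov <- solve(P)
  list(mean = drop(cov %*% h), cov = cov)
}

#' @export
print.hrvo2Fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical %%HRR-%%VO2 fit (x scale: %s, gamma priors on %s)\n",
    x$spec$xScale, x$spec$gammaOn))
  cat(sprintf("  %d subjects; %d chains x %d saved draws = %d draws\n",
              length(x$subject_ids), x$config$n_chains,
              nrow(x$draws) / x$config$n_chains, nrow(x$draws)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.hrvo2Fit <- function(object, probs = c(0.025, 0.975), ...) {
  d <- object$draws
  data.frame(parameter = names(d),
             mean = vapply(d, mean, 0),
             sd = vapply(d, stats::sd, 0),
             lo = vapply(d, stats::quantile, 0, probs = probs[1]),
             hi = vapply(d, stats::quantile, 0, probs = probs[2]),
             row.names = NULL)
}

#' Serialize posterior draws to CSV (with a JSON sidecar)
#'
#' Writes long-format draws (`chain`, `iteration`, `parameter`, `value`)
#' and a `.json` sidecar recording the model spec and MCMC config, so a
#' fit can be reloaded for diagnostics and reporting.
#'
#' @param fit An `hrvo2Fit`.
#' @param path CSV output path; the sidecar gets the same path with
#'   `.json` appended.
#' @param perSubject Include per-subject coefficient draws (default
#'   FALSE; population parameters carry all reported inference).
#' @return `path`, invisibly.
#' @export
writeDraws <- function(fit, path, perSubject = FALSE) {
  stopifnot(inherits(fit, "hrvo2Fit"))
  nSaveChain <- nrow(fit$draws) / fit$config$n_chains
  iter <- rep(seq_len(nSaveChain), fit$config$n_chains)
  long <- do.call(rbind, lapply(popParams(), function(p) {
    data.frame(chain = fit$chain, iteration = iter, parameter = p,
               value = fit$draws[[p]])
  }))
  if (perSubject) {
    for (j in seq_along(fit$subject_ids)) {
      long <- rbind(long,
        data.frame(chain = fit$chain, iteration = iter,
                   parameter = paste0("b0_", fit$subject_ids[j]),
                   value = fit$subjects$b0[, j]),
        data.frame(chain = fit$chain, iteration = iter,
                   parameter = paste0("b1_", fit$subject_ids[j]),
                   value = fit$subjects$b1[, j]))
    }
  }
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(x_scale = fit$spec$xScale, gamma_on = fit$spec$gammaOn,
               mcmc = unclass(fit$config), subject_ids = fit$subject_ids)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Reload serialized draws
#'
#' @param path CSV written by [writeDraws()].
#' @return An `hrvo2Fit`-like object (population draws, chain index,
#'   spec tag and config restored from the sidecar).
#' @export
readDraws <- function(path) {
  long <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pop <- popParams()
  draws <- lapply(pop, function(p) long$value[long$parameter == p])
  names(draws) <- pop
  cfg <- do.call(mcmcConfig, meta$mcmc[c("n_chains", "n_iterations",
                                         "burn_in", "thin", "master_seed")])
  out <- list(draws = as.data.frame(draws),
              chain = long$chain[long$parameter == pop[1]],
              subjects = NULL, subject_ids = meta$subject_ids,
              spec = modelSpec(xScale = meta$x_scale, gammaOn = meta$gamma_on),
              config = cfg)
  class(out) <- "hrvo2Fit"
  out
}
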