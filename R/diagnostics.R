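#' Potential scale reduction factor (Rhat)
#'
#' Classic Gelman-Rubin diagnostic from parallel chains: with m chains
#' of n draws, W the mean within-chain variance and B the between-chain
#' variance of the chain means (times n), Rhat is
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the chains
#' have mixed. This is the classic (non-split, non-rank-normalized)
#' variant; `split = TRUE` halves each chain first.
#'
#' @param chains An n x m matrix (one column per chain) or list of
#'   equal-length numeric vectors; m >= 2, n >= 4.
#' @param split Split each chain in half before computing (default
#'   FALSE).
#' @return Scalar Rhat. All-constant chains return the sentinel 1.0.
#' @export
rhat <- function(chains, split = FALSE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (split) {
    n2 <- floor(nrow(chains) / 2)
    chains <- cbind(chains[seq_len(n2), , drop = FALSE],
                    chains[nrow(chains) - n2 + seq_len(n2), , drop = FALSE])
  }
  n <- nrow(chains); m <- ncol(chains)
  stopifnot(m >= 2, n >= 4)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) return(1.0)  # degenerate: no within-chain variance
  sqrt(((n - 1) / n * W + B / n) / W)
}

# autoregressive estimate of the spectral density at frequency zero;
# order selected by AIC (the convention of the standard MCMC toolchain)
spectrum0ar <- function(x) {
  detrended <- stats::residuals(stats::lm(x ~ seq_along(x)))
  if (isTRUE(all.equal(stats::sd(detrended), 0)))
    return(0)
  fit <- stats::ar(x, aic = TRUE)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size of MCMC draws
#'
#' For a single chain: `n * var(x) / S(0)`, where S(0) is the
#' autoregressive spectral density estimate at frequency zero. For a
#' matrix or list of chains, per-chain sizes are summed.
#'
#' @param draws Numeric vector (one chain), n x m matrix, or list of
#'   chains; each chain needs n >= 10.
#' @return Scalar effective sample size; a constant chain contributes 0
#'   (with a warning).
#' @export
effectiveSize <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  if (is.matrix(draws))
    return(sum(apply(draws, 2, effectiveSize)))
  stopifnot(length(draws) >= 10)
  s0 <- spectrum0ar(draws)
  if (s0 == 0) {
    warning("constant chain: effective sample size is 0", call. = FALSE)
    return(0)
  }
  length(draws) * stats::var(draws) / s0
}

#' Raftery-Lewis run-length diagnostic
#'
#' Estimates how many MCMC iterations are needed to estimate the
#' `quantile` of the target distribution to within `accuracy` with
#' probability `prob`, by binarizing the chain at its empirical quantile,
#' choosing the smallest thinning at which the binary sequence is
#' adequately first-order Markov (BIC comparison against a second-order
#' chain), and reading burn-in and run length off the fitted two-state
#' transition matrix. The dependence factor I is the required run length
#' relative to what an independence sampler would need; values near 1
#' indicate low autocorrelation.
#'
#' @param draws Numeric vector of draws from one (possibly pooled) chain.
#' @param quantile Target quantile q (default 0.025).
#' @param accuracy Tolerated error r on the quantile (default 0.005).
#' @param prob Coverage probability s (default 0.95).
#' @param convergeEps Burn-in convergence tolerance (default 0.001).
#' @return A list: `burn_in` (M), `total` (N = M + keep), `n_min`
#'   (independence-sampler requirement), `dependence_factor` (I), and
#'   `thin` (selected k).
#' @export
rafteryLewis <- function(draws, quantile = 0.025, accuracy = 0.005,
                         prob = 0.95, convergeEps = 0.001) {
  n <- length(draws)
  phi <- stats::qnorm(0.5 * (1 + prob))
  nMin <- ceiling(quantile * (1 - quantile) * phi^2 / accuracy^2)
  if (n < nMin) {
    stop(structure(class = c("hrvo2_chain_too_short", "error", "condition"),
                   list(message = sprintf(
                     "chain too short: %d draws, pilot minimum is %d",
                     n, nMin), call = NULL)))
  }
  cut <- stats::quantile(draws, probs = quantile, names = FALSE)
  dichot <- as.integer(draws <= cut)

  # smallest thinning at which a first-order chain is BIC-preferred
  kThin <- 0L; bic <- 1
  repeat {
    kThin <- kThin + 1L
    z <- dichot[seq.int(1L, n, by = kThin)]
    nz <- length(z)
    tri <- table(factor(z[1:(nz - 2)], levels = 0:1),
                 factor(z[2:(nz - 1)], levels = 0:1),
                 factor(z[3:nz], levels = 0:1))
    tri <- array(as.double(tri), dim = dim(tri))
    g2 <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
      if (tri[i1, i2, i3] != 0) {
        fitted <- sum(tri[i1, i2, ]) * sum(tri[, i2, i3]) / sum(tri[, i2, ])
        g2 <- g2 + 2 * tri[i1, i2, i3] * log(tri[i1, i2, i3] / fitted)
      }
    }
    bic <- g2 - 2 * log(nz - 2)
    if (bic < 0) break
  }

  tr <- table(factor(z[1:(nz - 1)], levels = 0:1),
              factor(z[2:nz], levels = 0:1))
  alpha <- tr[1, 2] / (tr[1, 1] + tr[1, 2])
  beta <- tr[2, 1] / (tr[2, 1] + tr[2, 2])
  burn <- log(convergeEps * (alpha + beta) / max(alpha, beta)) /
    log(abs(1 - alpha - beta))
  nBurn <- ceiling(burn) * kThin
  keepPrec <- (2 - alpha - beta) * alpha * beta * phi^2 /
    ((alpha + beta)^3 * accuracy^2)
  nKeep <- ceiling(keepPrec) * kThin
  list(burn_in = nBurn, total = nBurn + nKeep, n_min = nMin,
       dependence_factor = (nBurn + nKeep) / nMin, thin = kThin)
}

#' Convergence diagnostics for a hierarchical fit
#'
#' Computes, for each population parameter, the potential scale
#' reduction factor across chains, the effective sample size summed
#' over chains, and the Raftery-Lewis dependence factor on the pooled
#' saved (thinned) draws — per-chain saved segments are shorter than the
#' Raftery-Lewis pilot minimum at the canonical settings. With
#' `rlOn = "raw"` the dependence factor is instead computed on the
#' pooled unthinned post-burn-in chains (`fit$raw`), which exposes the
#' raw sampler's autocorrelation — the dependence the thinning interval
#' exists to remove — rather than the quality of the saved output.
#'
#' @param fit An `hrvo2Fit`.
#' @param thresholds Named numeric reference thresholds (defaults:
#'   Rhat 1.002, ESS 8600, dependence factor 1.05).
#' @param rlOn `"saved"` (default) or `"raw"`.
#' @return A data frame of class `"hrvo2Diagnostics"`: one row per
#'   population parameter with `rhat`, `ess`, `raftery_I` and pass
#'   flags.
#' @export
diagnoseFit <- function(fit, thresholds = c(rhat = 1.002, ess = 8600,
                                            raftery = 1.05),
                        rlOn = c("saved", "raw")) {
  rlOn <- match.arg(rlOn)
  stopifnot(inherits(fit, "hrvo2Fit"))
  if (rlOn == "raw" && is.null(fit$raw))
    stop("fit carries no raw draws", call. = FALSE)
  out <- do.call(rbind, lapply(popParams(), function(p) {
    v <- fit$draws[[p]]
    ch <- split(v, fit$chain)
    rlDraws <- if (rlOn == "raw") fit$raw[, p] else v
    # pooled draws can be below the pilot minimum on deliberately small
    # runs; report NA rather than refusing the other diagnostics
    rlI <- tryCatch(rafteryLewis(rlDraws)$dependence_factor,
                    hrvo2_chain_too_short = function(e) NA_real_)
    data.frame(parameter = p,
               rhat = rhat(ch),
               ess = effectiveSize(ch),
               raftery_I = rlI)
  }))
  out$rhat_ok <- out$rhat <= thresholds[["rhat"]]
  out$ess_ok <- out$ess >= thresholds[["ess"]]
  out$raftery_ok <- out$raftery_I <= thresholds[["raftery"]]
  attr(out, "thresholds") <- thresholds
  class(out) <- c("hrvo2Diagnostics", "data.frame")
  out
}

#' @export
print.hrvo2Diagnostics <- function(x, ...) {
  cat("MCMC convergence diagnostics (population parameters)\n")
  print.data.frame(x, digits = 5)
  ok <- all(x$rhat_ok & x$ess_ok & x$raftery_ok)
  cat(if (ok) "All diagnostics within reference thresholds.\n"
      else "Some diagnostics exceed reference thresholds.\n")
  invisible(x)
}
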