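# display rounding: nearest integer, halves away from zero
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

drawsOf <- function(fit, param) {
  d <- if (inherits(fit, "hrvo2Fit")) fit$draws[[param]] else fit[[param]]
  if (is.null(d) || !length(d)) stop("no draws for ", param, call. = FALSE)
  d
}

#' Test the population line against the line of identity
#'
#' Summarizes the posterior of the population intercept and slope and
#' flags departure from the identity line: the intercept is declared
#' different from 0 if 0 lies outside its 95% equal-tailed credible
#' interval, and the slope different from 1 if 1 lies outside its
#' interval.
#'
#' @param fit An `hrvo2Fit`, or a list with draw vectors `mu_b0`,
#'   `mu_b1`.
#' @param level Credible level (default 0.95).
#' @return A list of class `"identityTest"`: `intercept` and `slope`
#'   summaries (mean, sd, lo, hi) plus `intercept_differs_from_zero` and
#'   `slope_differs_from_one`.
#' @export
identityTest <- function(fit, level = 0.95) {
  alpha <- (1 - level) / 2
  sm <- function(d) c(mean = mean(d), sd = stats::sd(d),
                      lo = stats::quantile(d, alpha, names = FALSE),
                      hi = stats::quantile(d, 1 - alpha, names = FALSE))
  b0 <- sm(drawsOf(fit, "mu_b0"))
  b1 <- sm(drawsOf(fit, "mu_b1"))
  out <- list(intercept = b0, slope = b1,
              intercept_differs_from_zero = b0["lo"] > 0 || b0["hi"] < 0,
              slope_differs_from_one = b1["lo"] > 1 || b1["hi"] < 1)
  class(out) <- "identityTest"
  out
}

#' @export
print.identityTest <- function(x, ...) {
  f <- function(s, ref, flag)
    sprintf("%.3f +/- %.3f (%.3f, %.3f)%s", s["mean"], s["sd"], s["lo"],
            s["hi"], if (flag) paste0(" [differs from ", ref, "]") else "")
  cat("Identity-line test of the population %HRR-%VO2 relationship\n")
  cat("  intercept:", f(x$intercept, "0", x$intercept_differs_from_zero), "\n")
  cat("  slope:    ", f(x$slope, "1", x$slope_differs_from_one), "\n")
  invisible(x)
}

#' Posterior comparison of a parameter between two fits
#'
#' Estimates P(parameter in `fitA` > parameter in `fitB`) as the
#' fraction of index-paired posterior draws with a positive difference
#' (draw sets are resampled to a common size if they differ), and flags
#' the comparison significant when that probability exceeds 0.95.
#'
#' @param fitA,fitB `hrvo2Fit` objects or draw lists.
#' @param parameter Population parameter name (default `"mu_b1"`).
#' @param threshold Posterior-probability cutoff (default 0.95).
#' @return A list: `p_a_gt_b`, `significant`, `diff` draw vector.
#' @export
compareFits <- function(fitA, fitB, parameter = "mu_b1", threshold = 0.95) {
  a <- drawsOf(fitA, parameter)
  b <- drawsOf(fitB, parameter)
  n <- min(length(a), length(b))
  if (length(a) != length(b)) {
    a <- a[seq_len(n)]; b <- b[seq_len(n)]
  }
  d <- a - b
  p <- mean(d > 0) + 0.5 * mean(d == 0)  # ties split (self-comparison: 0.5)
  list(p_a_gt_b = p, significant = p > threshold, diff = d)
}

#' Modal %HRR with credible intervals at prescribed %VO2 intensities
#'
#' For each target intensity x, forms the per-draw population value
#' `mu_b0 + mu_b1 * x`, estimates the posterior mode by Gaussian kernel
#' density (Silverman bandwidth, 512-point grid) and an equal-tailed
#' credible interval, and flags targets falling outside their interval
#' (i.e. intensities at which %HRR systematically misestimates the %VO2
#' value). Displayed modes are rounded to integer percent (halves away
#' from zero); full precision is retained in `mode_raw`.
#'
#' @param fit An `hrvo2Fit` or draw list with `mu_b0`, `mu_b1`.
#' @param targets Target intensities on the x-scale, percent (default
#'   45, 55, 65, 75, 85).
#' @param level Credible level (default 0.95).
#' @param pointEstimate `"kde_mode"` (default) or `"mean"` (sensitivity
#'   option for the mode-estimator choice).
#' @return A data frame of class `"predictionTable"`: `target`,
#'   `hrr_pct` (display-rounded mode), `mode_raw`, `lo`, `hi`,
#'   `flagged`.
#' @export
predictIntensity <- function(fit, targets = c(45, 55, 65, 75, 85),
                             level = 0.95,
                             pointEstimate = c("kde_mode", "mean")) {
  pointEstimate <- match.arg(pointEstimate)
  stopifnot(all(targets > 0), all(targets <= 100),
            !is.unsorted(targets, strictly = TRUE))
  b0 <- drawsOf(fit, "mu_b0")
  b1 <- drawsOf(fit, "mu_b1")
  alpha <- (1 - level) / 2
  rows <- lapply(targets, function(x) {
    y <- b0 + b1 * x
    mode <- if (stats::sd(y) == 0 || pointEstimate == "mean") mean(y) else {
      dens <- stats::density(y, n = 512)
      dens$x[which.max(dens$y)]
    }
    ci <- stats::quantile(y, c(alpha, 1 - alpha), names = FALSE)
    data.frame(target = x, hrr_pct = roundHalfUp(mode), mode_raw = mode,
               lo = ci[1], hi = ci[2], flagged = x < ci[1] | x > ci[2])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("predictionTable", "data.frame")
  out
}

#' Assemble the full results bundle for the eight analysis cells
#'
#' Takes the eight hierarchical fits (2 x-scales, 2 sexes, 2 modes),
#' runs the identity-line test and intensity prediction grid for each,
#' the sex and mode contrasts of intercepts and slopes, and bundles them
#' with the cohort comparison table.
#'
#' @param fits Nested list `fits[[x_scale]][[sex]][[mode]]` of
#'   `hrvo2Fit` objects; all eight cells must be present.
#' @param groupTable Optional output of [groupComparisonTable()].
#' @return A list of class `"hrvo2Report"`: `identity` (one row per
#'   cell), `predictions` (stacked prediction tables), `contrasts`
#'   (sex/mode posterior probabilities for intercept and slope),
#'   `groups`.
#' @export
buildReport <- function(fits, groupTable = NULL) {
  scales <- c("percent_vo2max", "percent_vo2r")
  sexes <- c("male", "female")
  modes <- c("treadmill", "cycle")
  for (sc in scales) for (sx in sexes) for (md in modes) {
    if (is.null(fits[[sc]][[sx]][[md]]))
      stop("missing fit for cell (", sc, ", ", sx, ", ", md, ")",
           call. = FALSE)
  }
  identity <- list(); preds <- list(); contrasts <- list()
  for (sc in scales) for (sx in sexes) for (md in modes) {
    fit <- fits[[sc]][[sx]][[md]]
    it <- identityTest(fit)
    identity[[length(identity) + 1L]] <- data.frame(
      x_scale = sc, sex = sx, mode = md,
      intercept = it$intercept[["mean"]], intercept_sd = it$intercept[["sd"]],
      intercept_lo = it$intercept[["lo"]], intercept_hi = it$intercept[["hi"]],
      slope = it$slope[["mean"]], slope_sd = it$slope[["sd"]],
      slope_lo = it$slope[["lo"]], slope_hi = it$slope[["hi"]],
      intercept_differs_from_zero = it$intercept_differs_from_zero,
      slope_differs_from_one = it$slope_differs_from_one)
    pt <- predictIntensity(fit)
    pt$x_scale <- sc; pt$sex <- sx; pt$mode <- md
    preds[[length(preds) + 1L]] <- pt
  }
  for (sc in scales) for (par in c("mu_b0", "mu_b1")) {
    for (md in modes) {  # female vs male within mode
      cmp <- compareFits(fits[[sc]][["female"]][[md]],
                         fits[[sc]][["male"]][[md]], par)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        x_scale = sc, parameter = par, contrast = "female > male",
        within = md, p = cmp$p_a_gt_b, significant = cmp$significant)
    }
    for (sx in sexes) {  # cycle vs treadmill within sex
      cmp <- compareFits(fits[[sc]][[sx]][["cycle"]],
                         fits[[sc]][[sx]][["treadmill"]], par)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        x_scale = sc, parameter = par, contrast = "cycle > treadmill",
        within = sx, p = cmp$p_a_gt_b, significant = cmp$significant)
    }
  }
  out <- list(identity = do.call(rbind, identity),
              predictions = do.call(rbind, preds),
              contrasts = do.call(rbind, contrasts),
              groups = groupTable)
  rownames(out$identity) <- rownames(out$predictions) <- NULL
  class(out) <- "hrvo2Report"
  out
}

#' @export
print.hrvo2Report <- function(x, ...) {
  cat("Population %HRR-%VO2 lines (8 analysis cells)\n")
  print.data.frame(x$identity, digits = 4)
  cat("\nModal %HRR at target intensities (flag: target outside 95% CI)\n")
  print.data.frame(x$predictions, digits = 4)
  invisible(x)
}

#' Write a report bundle to CSV files plus a JSON manifest
#'
#' @param report An `hrvo2Report`.
#' @param dir Output directory (created if needed).
#' @param manifest Extra fields stored in the manifest (e.g. seeds).
#' @return Invisibly, the manifest list.
#' @export
writeReport <- function(report, dir, manifest = list()) {
  stopifnot(inherits(report, "hrvo2Report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(identity = "identity_tests.csv",
                predictions = "intensity_predictions.csv",
                contrasts = "contrasts.csv")
  if (!is.null(report$groups)) files$groups <- "group_comparisons.csv"
  for (nm in names(files))
    utils::write.csv(report[[nm]], file.path(dir, files[[nm]]),
                     row.names = FALSE)
  manifest <- c(manifest, list(files = files, created = "hrvo2"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
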