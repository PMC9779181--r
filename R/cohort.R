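#' Cohort configuration for the synthetic-data generator
#'
#' Sex-specific means and SDs of demographics, resting values and
#' per-mode maximal values. The defaults reproduce the published summary
#' statistics of a 41-subject cohort of recreationally active young
#' adults (see [referenceCohortParams()]): e.g. male resting HR
#' 53.9 +/- 6.3 bpm, male treadmill VO2max 57.3 +/- 7.1 mL/kg/min.
#'
#' @param n_males,n_females Cohort sizes (default 21 and 20).
#' @param params A data frame in the shape of [referenceCohortParams()];
#'   override individual rows to change the generating population.
#' @param sdScale Multiplier applied to every SD (0 gives a deterministic
#'   cohort at the configured means; useful for exact checks).
#' @return A list of class `"cohortConfig"`.
#' @export
cohortConfig <- function(n_males = 21, n_females = 20,
                         params = referenceCohortParams(), sdScale = 1) {
  stopifnot(n_males >= 1, n_females >= 1, sdScale >= 0,
            all(params$sd >= 0))
  params$sd <- params$sd * sdScale
  # maximal means must exceed resting means for both sexes and modes
  for (sx in c("male", "female")) {
    rest <- params[params$variable %in% c("hr_rest", "vo2_rest") &
                     params$sex == sx, ]
    for (md in c("treadmill", "cycle")) {
      mx <- params[params$sex == sx & params$mode %in% md, ]
      if (mx$mean[mx$variable == "hr_max"] <=
            rest$mean[rest$variable == "hr_rest"] ||
          mx$mean[mx$variable == "vo2_max"] <=
            rest$mean[rest$variable == "vo2_rest"])
        stop("maximal means must exceed resting means", call. = FALSE)
    }
  }
  structure(list(n_males = n_males, n_females = n_females, params = params),
            class = "cohortConfig")
}

#' Generating truth for the hierarchical %HRR-%VO2 line
#'
#' Population intercept and slope of the %HRR-on-x regression used by the
#' generator, plus between-subject and residual variances. The generator
#' works on the %VO2R x-scale; the companion %VO2max relationship then
#' follows from each subject's resting and maximal values. Defaults for
#' the intercept and slope are the published %VO2R posterior means for
#' the matching (sex, mode) cell (see [referenceModelEstimates()]).
#' The published analysis does not report the dispersion components, so
#' the defaults (between-subject SDs of 8 %HRR points for intercepts and
#' 0.08 for slopes; residual SD 5 points) are a fixed, documented choice
#' of physiologically plausible inter-individual spread.
#'
#' @param mu_b0 Population intercept, %HRR points.
#' @param mu_b1 Population slope (dimensionless).
#' @param var_intercepts,var_slopes Between-subject variances.
#' @param var_resid Residual variance of %HRR around the subject line.
#' @return A list of class `"truthParams"`.
#' @export
#' @examples
#' truthParams(18.26, 0.818)   # male treadmill %VO2R cell
truthParams <- function(mu_b0 = 18.26, mu_b1 = 0.818,
                        var_intercepts = 64, var_slopes = 0.0064,
                        var_resid = 25) {
  stopifnot(var_intercepts >= 0, var_slopes >= 0, var_resid >= 0)
  structure(list(mu_b0 = mu_b0, mu_b1 = mu_b1,
                 var_intercepts = var_intercepts, var_slopes = var_slopes,
                 var_resid = var_resid),
            class = "truthParams")
}

#' Default per-cell generating truths
#'
#' One [truthParams()] per (sex, mode) cell, with intercept and slope set
#' to the published %VO2R posterior means for that cell.
#'
#' @param var_intercepts,var_slopes,var_resid Dispersion components
#'   shared across cells (see [truthParams()]).
#' @return Nested list: `truth[[sex]][[mode]]`.
#' @export
defaultTruth <- function(var_intercepts = 64, var_slopes = 0.0064,
                         var_resid = 25) {
  ref <- referenceModelEstimates()
  ref <- ref[ref$x_scale == "percent_vo2r", ]
  out <- list()
  for (i in seq_len(nrow(ref))) {
    out[[ref$sex[i]]][[ref$mode[i]]] <-
      truthParams(ref$intercept[i], ref$slope[i],
                  var_intercepts, var_slopes, var_resid)
  }
  out
}

#' Graded-test protocol configuration
#'
#' Describes the stage structure of a graded exercise test on the
#' generator's intensity scale (%VO2R). Stages are 3 min sampled every
#' 15 s; the final stage, at maximal intensity, is cut short by
#' volitional fatigue. The defaults (stages at 40/55/70/85/100 %VO2R,
#' with 45 s sustained at the top) give 51 samples per test, matching the
#' roughly 51 fifteen-second samples per test observed with this kind of
#' small-increment protocol. For the treadmill the first stages play the
#' role of the walking/jogging lead-in on a level grade; exact speeds and
#' grades are not emulated because only the intensity scale enters the
#' model.
#'
#' @param mode `"treadmill"` or `"cycle"`.
#' @param stageDuration Stage length, seconds (default 180).
#' @param sampleInterval Sampling interval, seconds (default 15).
#' @param intensities Strictly increasing per-stage %VO2R targets, last
#'   value at most 100.
#' @param finalStageSeconds Time sustained at the final stage before
#'   fatigue (default 45 s).
#' @return A list of class `"protocolConfig"` with an `n_samples` field.
#' @export
protocolConfig <- function(mode = c("treadmill", "cycle"),
                           stageDuration = 180, sampleInterval = 15,
                           intensities = c(40, 55, 70, 85, 100),
                           finalStageSeconds = 45) {
  mode <- match.arg(mode)
  stopifnot(stageDuration %% sampleInterval == 0,
            finalStageSeconds %% sampleInterval == 0,
            all(diff(intensities) > 0), max(intensities) <= 100,
            finalStageSeconds >= sampleInterval)
  perStage <- stageDuration / sampleInterval
  n <- perStage * (length(intensities) - 1L) +
    finalStageSeconds / sampleInterval
  structure(list(mode = mode, stageDuration = stageDuration,
                 sampleInterval = sampleInterval, intensities = intensities,
                 finalStageSeconds = finalStageSeconds,
                 n_samples = as.integer(n)),
            class = "protocolConfig")
}

# truncated-normal draw by bounded rejection; errors after maxTries
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        maxTries = 1000L) {
  if (sd == 0) {
    if (any(mean < lower | mean > upper))
      stop("configured mean outside physiologic bounds", call. = FALSE)
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tr in seq_len(maxTries)) {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
      v <- NA_real_
    }
    if (is.na(v))
      stop("retry budget exhausted drawing a bounded value", call. = FALSE)
    out[i] <- v
  }
  out
}

#' Draw one synthetic subject
#'
#' Demographics, resting values, and per-mode maximal values are drawn as
#' independent truncated normals at the configured means/SDs (HR bounded
#' to 30-230 bpm, VO2 positive). Draws violating rest < max are resampled
#' within a bounded retry budget.
#'
#' @param sex `"male"` or `"female"`.
#' @param config A [cohortConfig()].
#' @param subject_id Identifier stored in the record.
#' @param maxTries Retry budget for the rest < max rejection step.
#' @return A one-row data frame (subject record) with demographics,
#'   resting values, per-mode maximal values and per-mode reserves.
#' @export
generateSubject <- function(sex, config, subject_id = 1L, maxTries = 1000L) {
  stopifnot(inherits(config, "cohortConfig"), sex %in% c("male", "female"))
  p <- config$params
  g <- function(var, mode = NA) {
    r <- p[p$variable == var & p$sex == sex &
             (if (is.na(mode)) is.na(p$mode) else p$mode %in% mode), ]
    r[1, c("mean", "sd")]
  }
  drawVar <- function(var, mode = NA, lower = -Inf, upper = Inf) {
    m <- g(var, mode)
    rtruncnorm1(1, m$mean, m$sd, lower, upper)
  }
  age <- drawVar("age_yr", lower = 18, upper = 39)
  height <- drawVar("height_cm", lower = 120, upper = 220)
  mass <- drawVar("mass_kg", lower = 30, upper = 150)
  hr_rest <- drawVar("hr_rest", lower = 30, upper = 230)
  vo2_rest <- drawVar("vo2_rest", lower = 0.5)
  mx <- list()
  for (md in c("treadmill", "cycle")) {
    for (tr in seq_len(maxTries)) {
      hr_max <- drawVar("hr_max", md, lower = 30, upper = 230)
      vo2_max <- drawVar("vo2_max", md, lower = 1)
      if (hr_max > hr_rest && vo2_max > vo2_rest) break
      hr_max <- NA_real_
    }
    if (is.na(hr_max))
      stop("retry budget exhausted enforcing rest < max", call. = FALSE)
    mx[[md]] <- c(hr_max = hr_max, vo2_max = vo2_max,
                  rer_max = drawVar("rer_max", md, lower = 0.7, upper = 1.6))
  }
  data.frame(
    subject_id = subject_id, sex = sex, age_yr = age, height_cm = height,
    mass_kg = mass, hr_rest = hr_rest, vo2_rest = vo2_rest,
    hr_max_treadmill = mx$treadmill[["hr_max"]],
    vo2_max_treadmill = mx$treadmill[["vo2_max"]],
    rer_max_treadmill = mx$treadmill[["rer_max"]],
    hr_max_cycle = mx$cycle[["hr_max"]],
    vo2_max_cycle = mx$cycle[["vo2_max"]],
    rer_max_cycle = mx$cycle[["rer_max"]],
    hrr_treadmill = mx$treadmill[["hr_max"]] - hr_rest,
    vo2r_treadmill = mx$treadmill[["vo2_max"]] - vo2_rest,
    hrr_cycle = mx$cycle[["hr_max"]] - hr_rest,
    vo2r_cycle = mx$cycle[["vo2_max"]] - vo2_rest
  )
}

#' Generate one graded-test 15-s series for a subject
#'
#' Draws the subject's intercept/slope deviation from the population
#' truth, evaluates %HRR = b0 + b1 x + noise on the protocol's %VO2R
#' grid, and back-transforms to raw HR (bpm) and VO2 (mL/kg/min) using
#' the subject's resting and maximal values. The RER channel is a
#' deterministic monotone ramp in intensity, `0.80 + 0.45 (x/100)^1.5`,
#' plus small noise, which crosses the 1.10 maximal-effort gate near the
#' end of the test.
#'
#' @param subject A subject record row (see [generateSubject()]).
#' @param protocol A [protocolConfig()].
#' @param truth A [truthParams()].
#' @param hrPolicy What to do when back-transformed HR leaves the 30-230
#'   bpm physiologic band: `"clamp"` (default) or `"error"`.
#' @param coefs Optional `c(b0, b1)` forcing the subject's line (used for
#'   exact checks); if `NULL` they are drawn from the truth.
#' @return A data frame with columns `subject_id`, `mode`, `t_sec`,
#'   `hr_bpm`, `vo2_mlkgmin`, `rer`, and attributes `b0`, `b1`.
#' @export
generateTestSeries <- function(subject, protocol, truth,
                               hrPolicy = c("clamp", "error"),
                               coefs = NULL) {
  hrPolicy <- match.arg(hrPolicy)
  stopifnot(inherits(protocol, "protocolConfig"),
            inherits(truth, "truthParams"))
  md <- protocol$mode
  hrr <- subject[[paste0("hrr_", md)]]
  vo2r <- subject[[paste0("vo2r_", md)]]
  stopifnot(hrr > 0, vo2r > 0)

  perStage <- protocol$stageDuration / protocol$sampleInterval
  nStages <- length(protocol$intensities)
  reps <- c(rep(perStage, nStages - 1L),
            protocol$finalStageSeconds / protocol$sampleInterval)
  x <- rep(protocol$intensities, times = reps)       # %VO2R grid
  t_sec <- seq_along(x) * protocol$sampleInterval

  if (is.null(coefs)) {
    b0 <- stats::rnorm(1, truth$mu_b0, sqrt(truth$var_intercepts))
    b1 <- stats::rnorm(1, truth$mu_b1, sqrt(truth$var_slopes))
  } else {
    b0 <- coefs[1]; b1 <- coefs[2]
  }
  yPct <- b0 + b1 * x +
    if (truth$var_resid > 0) stats::rnorm(length(x), 0, sqrt(truth$var_resid))
    else 0

  hr <- subject$hr_rest + yPct / 100 * hrr
  vo2 <- subject$vo2_rest + x / 100 * vo2r
  if (any(hr < 30 | hr > 230)) {
    if (hrPolicy == "error")
      stop("back-transformed HR outside the 30-230 bpm band", call. = FALSE)
    hr <- pmin(pmax(hr, 30), 230)
  }
  rer <- 0.80 + 0.45 * (x / 100)^1.5 + stats::rnorm(length(x), 0, 0.01)

  out <- data.frame(subject_id = subject$subject_id, mode = md,
                    t_sec = t_sec, hr_bpm = hr, vo2_mlkgmin = vo2,
                    rer = rer)
  attr(out, "b0") <- b0
  attr(out, "b1") <- b1
  out
}

#' Generate a full synthetic cohort with both exercise tests
#'
#' Draws every subject, then one treadmill and one cycle test per
#' subject. Reproducibility: each (subject, mode) pair gets its own RNG
#' substream seeded from `masterSeed`, so cohorts are bit-identical under
#' a fixed seed and unchanged by reordering of generation.
#'
#' @param config A [cohortConfig()].
#' @param protocols Named list with `treadmill` and `cycle`
#'   [protocolConfig()]s.
#' @param truth Nested list `truth[[sex]][[mode]]` of [truthParams()]
#'   (default [defaultTruth()]).
#' @param masterSeed Integer master seed.
#' @param hrPolicy Passed to [generateTestSeries()].
#' @return An object of class `"hrvo2Cohort"`: list with `subjects`
#'   (one row per subject), `series` (long 15-s samples), `truth`,
#'   `seed`, and per-subject true coefficients in `coef_truth`.
#' @export
generateCohort <- function(config = cohortConfig(),
                           protocols = list(treadmill = protocolConfig("treadmill"),
                                            cycle = protocolConfig("cycle")),
                           truth = defaultTruth(),
                           masterSeed = 1L,
                           hrPolicy = "clamp") {
  stopifnot(inherits(config, "cohortConfig"),
            all(c("treadmill", "cycle") %in% names(protocols)))
  nTot <- config$n_males + config$n_females
  sexes <- rep(c("male", "female"), c(config$n_males, config$n_females))
  subjects <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    set.seed((masterSeed + 104729L * i) %% .Machine$integer.max)
    subjects[[i]] <- generateSubject(sexes[i], config, subject_id = i)
  }
  subjects <- do.call(rbind, subjects)

  series <- vector("list", 2L * nTot)
  coefs <- vector("list", 2L * nTot)
  k <- 0L
  for (i in seq_len(nTot)) {
    for (md in c("treadmill", "cycle")) {
      k <- k + 1L
      set.seed((masterSeed + 104729L * i + 15485863L *
                  (1L + (md == "cycle"))) %% .Machine$integer.max)
      ser <- generateTestSeries(subjects[i, ], protocols[[md]],
                                truth[[sexes[i]]][[md]], hrPolicy = hrPolicy)
      coefs[[k]] <- data.frame(subject_id = i, mode = md,
                               b0 = attr(ser, "b0"), b1 = attr(ser, "b1"))
      attr(ser, "b0") <- attr(ser, "b1") <- NULL
      series[[k]] <- ser
    }
  }
  out <- list(subjects = subjects,
              series = do.call(rbind, series),
              coef_truth = do.call(rbind, coefs),
              truth = truth, seed = masterSeed,
              protocols = protocols)
  rownames(out$series) <- NULL
  class(out) <- "hrvo2Cohort"
  out
}

#' @export
print.hrvo2Cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic graded-exercise cohort: %d subjects (%d male, %d female)\n",
    nrow(x$subjects), sum(x$subjects$sex == "male"),
    sum(x$subjects$sex == "female")))
  cat(sprintf("  %d test series, %d 15-s samples total (seed %d)\n",
              length(unique(paste(x$series$subject_id, x$series$mode))),
              nrow(x$series), x$seed))
  invisible(x)
}
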