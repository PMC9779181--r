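#' Resting heart rate and oxygen uptake from a supine minute series
#'
#' Computes resting HR (bpm) and VO2 (mL/kg/min) as the mean steady-state
#' value of a per-minute averaged supine series after discarding an initial
#' accommodation window.
#'
#' @param hr_bpm Numeric vector of per-minute HR averages.
#' @param vo2_mlkgmin Numeric vector of per-minute VO2 averages, same
#'   length as `hr_bpm`.
#' @param discardMinutes Number of leading minutes to discard (default 5).
#' @return A list of class `"restingProfile"` with elements `hr_rest` and
#'   `vo2_rest`.
#' @export
#' @examples
#' extractResting(rep(60, 30), rep(3.6, 30))
extractResting <- function(hr_bpm, vo2_mlkgmin, discardMinutes = 5) {
  stopifnot(length(hr_bpm) == length(vo2_mlkgmin), discardMinutes >= 0)
  if (length(hr_bpm) <= discardMinutes) {
    stop("no samples remain after discarding the first ", discardMinutes,
         " minutes", call. = FALSE)
  }
  keep <- seq.int(discardMinutes + 1L, length(hr_bpm))
  out <- list(hr_rest = mean(hr_bpm[keep]), vo2_rest = mean(vo2_mlkgmin[keep]))
  if (!all(is.finite(unlist(out))) || out$hr_rest <= 0 || out$vo2_rest <= 0)
    stop("resting values must be finite and positive", call. = FALSE)
  class(out) <- "restingProfile"
  out
}

#' Maximal values from a graded-test 15-s series
#'
#' VO2max is the highest mean VO2 over any contiguous window of
#' `windowS` seconds whose mean RER meets the maximal-effort gate
#' (ties broken to the earliest window); HRmax is the highest HR recorded
#' anywhere in the test. Windows are overlapping runs of consecutive
#' samples; with 15-s sampling and the default 30-s window each window is
#' a pair of adjacent samples.
#'
#' @param t_sec Sample times in seconds (regular grid).
#' @param hr_bpm,vo2_mlkgmin,rer Numeric vectors aligned with `t_sec`.
#' @param windowS Averaging window for VO2max, seconds (default 30).
#' @param rerGate Minimum mean RER for a window to qualify (default 1.10).
#' @param tailS If non-`NULL`, restrict the VO2max search to the last
#'   `tailS` seconds of the test. Off by default: the RER gate already
#'   pushes selection towards end-of-test effort.
#' @return A list of class `"maximalProfile"`: `hr_max`, `vo2_max`,
#'   `rer_max`, and `window_start_sec` (start time of the selected window).
#' @export
extractMaximal <- function(t_sec, hr_bpm, vo2_mlkgmin, rer,
                           windowS = 30, rerGate = 1.10, tailS = NULL) {
  n <- length(t_sec)
  stopifnot(n >= 2, length(hr_bpm) == n, length(vo2_mlkgmin) == n,
            length(rer) == n)
  dt <- diff(t_sec)
  interval <- dt[1]
  if (any(abs(dt - interval) > 1e-8))
    stop("samples must lie on a regular time grid", call. = FALSE)
  if (windowS %% interval != 0)
    stop("sample interval must divide the window length", call. = FALSE)
  k <- as.integer(windowS / interval)          # samples per window
  if (k > n) stop("series shorter than one window", call. = FALSE)

  idx <- seq_len(n - k + 1L)
  if (!is.null(tailS)) idx <- idx[t_sec[idx] >= t_sec[n] - tailS + interval]
  winMean <- function(v, i) mean(v[i:(i + k - 1L)])
  vo2w <- vapply(idx, function(i) winMean(vo2_mlkgmin, i), 0)
  rerw <- vapply(idx, function(i) winMean(rer, i), 0)
  ok <- rerw >= rerGate
  if (!any(ok)) {
    stop(structure(class = c("hrvo2_no_qualifying_window", "error",
                             "condition"),
                   list(message = paste0("no ", windowS,
                          "-s window reaches mean RER >= ", rerGate),
                        call = NULL)))
  }
  best <- idx[ok][which.max(vo2w[ok])]  # which.max -> earliest on ties
  out <- list(hr_max = max(hr_bpm), vo2_max = winMean(vo2_mlkgmin, best),
              rer_max = max(rer), window_start_sec = t_sec[best])
  class(out) <- "maximalProfile"
  out
}

#' Maximal-effort validation (two-of-three criteria)
#'
#' A graded test is accepted as maximal when at least two of three
#' criteria hold: (a) maximal RER at or above 1.10, (b) HRmax within
#' 15 bpm of the age-predicted maximum, and (c) a plateau in VO2 despite
#' increasing workload. The plateau judgement is supplied by the caller;
#' no numeric plateau detector is applied.
#'
#' @param rer_max Maximal respiratory exchange ratio.
#' @param hr_max Maximal heart rate, bpm.
#' @param age_yr Age in years (10-100).
#' @param plateau Logical: was a VO2 plateau observed?
#' @param predictedHrMax Function of age returning the predicted maximal
#'   HR; the conventional 220 - age by default.
#' @param hrTolerance Allowed shortfall below predicted HRmax, bpm.
#' @param rerGate RER criterion threshold.
#' @return A list of class `"effortValidation"`: `valid` plus logical
#'   `criterion_rer`, `criterion_hr`, `criterion_plateau`.
#' @export
effortValid <- function(rer_max, hr_max, age_yr, plateau,
                        predictedHrMax = function(age) 220 - age,
                        hrTolerance = 15, rerGate = 1.10) {
  stopifnot(age_yr >= 10, age_yr <= 100, is.logical(plateau))
  a <- rer_max >= rerGate
  b <- hr_max >= predictedHrMax(age_yr) - hrTolerance
  c3 <- isTRUE(plateau)
  out <- list(valid = (a + b + c3) >= 2,
              criterion_rer = a, criterion_hr = b, criterion_plateau = c3)
  class(out) <- "effortValidation"
  out
}

#' Express a value as a percentage of reserve or of maximum
#'
#' The reserve (Karvonen) scale is `100 * (value - rest) / (max - rest)`;
#' the of-max scale is `100 * value / max`. Percentages are carried on the
#' 0-100 scale throughout the package.
#'
#' @param value Raw HR (bpm) or VO2 (mL/kg/min); vectorised.
#' @param rest,max Resting and maximal values in the same units.
#' @param scale `"reserve"` or `"of_max"`.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' toPercent(118, rest = 54, max = 183, scale = "reserve")
toPercent <- function(value, rest, max, scale = c("reserve", "of_max")) {
  scale <- match.arg(scale)
  if (scale == "reserve") {
    if (max <= rest) stop("reserve scale requires max > rest", call. = FALSE)
    100 * (value - rest) / (max - rest)
  } else {
    if (max <= 0) stop("of_max scale requires max > 0", call. = FALSE)
    100 * value / max
  }
}

#' Invert a percentage back to the raw measurement scale
#'
#' @inheritParams toPercent
#' @param percent Percentage on the 0-100 scale; vectorised.
#' @return Raw values in the units of `rest`/`max`.
#' @export
fromPercent <- function(percent, rest, max, scale = c("reserve", "of_max")) {
  scale <- match.arg(scale)
  if (scale == "reserve") rest + percent / 100 * (max - rest)
  else percent / 100 * max
}

#' Heart-rate and VO2 reserves
#'
#' @param hr_rest,hr_max Resting and maximal HR, bpm.
#' @param vo2_rest,vo2_max Resting and maximal VO2, mL/kg/min.
#' @return A list of class `"reserveSet"`: `hrr` (bpm) and `vo2r`
#'   (mL/kg/min), each the maximal minus the resting value.
#' @export
#' @examples
#' reserves(53.9, 183.0, 3.7, 57.3)
reserves <- function(hr_rest, hr_max, vo2_rest, vo2_max) {
  out <- list(hrr = hr_max - hr_rest, vo2r = vo2_max - vo2_rest)
  if (any(unlist(out) <= 0))
    stop("reserves must be positive (max must exceed rest)", call. = FALSE)
  class(out) <- "reserveSet"
  out
}

#' Per-subject derived values for a cohort
#'
#' Applies the resting/maximal extraction and reserve arithmetic to every
#' subject and test in a cohort, producing the derived-values table the
#' model stage consumes.
#'
#' @param cohort An `hrvo2Cohort` (see [generateCohort()] or
#'   [readCohort()]).
#' @param maxSource `"subjects"` (default) takes each test's maximal
#'   values from the subject record (the measured values of the study
#'   design); `"series"` re-derives them from the 15-s series via
#'   [extractMaximal()].
#' @return A data frame with one row per (subject, mode): resting values,
#'   maximal values, reserves, and the effort-validation flag.
#' @export
deriveCohort <- function(cohort, maxSource = c("subjects", "series")) {
  maxSource <- match.arg(maxSource)
  stopifnot(inherits(cohort, "hrvo2Cohort"))
  sub <- cohort$subjects
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    s <- sub[i, ]
    do.call(rbind, lapply(c("treadmill", "cycle"), function(md) {
      ser <- cohort$series[cohort$series$subject_id == s$subject_id &
                             cohort$series$mode == md, ]
      if (maxSource == "series") {
        mx <- extractMaximal(ser$t_sec, ser$hr_bpm, ser$vo2_mlkgmin, ser$rer)
        hr_max <- mx$hr_max; vo2_max <- mx$vo2_max; rer_max <- mx$rer_max
      } else {
        hr_max <- s[[paste0("hr_max_", md)]]
        vo2_max <- s[[paste0("vo2_max_", md)]]
        rer_max <- max(ser$rer)
      }
      ev <- effortValid(rer_max, hr_max, s$age_yr,
                        plateau = FALSE)
      rs <- reserves(s$hr_rest, hr_max, s$vo2_rest, vo2_max)
      data.frame(subject_id = s$subject_id, sex = s$sex, mode = md,
                 hr_rest = s$hr_rest, vo2_rest = s$vo2_rest,
                 hr_max = hr_max, vo2_max = vo2_max, rer_max = rer_max,
                 hrr = rs$hrr, vo2r = rs$vo2r, effort_valid = ev$valid)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scale a cohort's series to percent form for model fitting
#'
#' Builds the per-subject (x, y) pairs of the hierarchical regression:
#' y is always %HRR; x is %VO2R or %VO2max depending on `xScale`.
#'
#' @param cohort An `hrvo2Cohort`.
#' @param derived Output of [deriveCohort()]; computed if missing.
#' @param xScale `"percent_vo2r"` or `"percent_vo2max"`.
#' @param mode Exercise mode to keep (`"treadmill"` or `"cycle"`).
#' @param sex Optional sex filter (`"male"`, `"female"`, or `NULL` for
#'   both).
#' @return A data frame of class `"scaledSeries"` with columns
#'   `subject_id`, `sex`, `mode`, `x`, `y`, and attribute `x_scale`.
#' @export
scaleSeries <- function(cohort, derived = NULL,
                        xScale = c("percent_vo2r", "percent_vo2max"),
                        mode = c("treadmill", "cycle"), sex = NULL) {
  xScale <- match.arg(xScale)
  mode <- match.arg(mode)
  if (is.null(derived)) derived <- deriveCohort(cohort)
  d <- derived[derived$mode == mode, ]
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  ser <- cohort$series[cohort$series$mode == mode &
                         cohort$series$subject_id %in% d$subject_id, ]
  i <- match(ser$subject_id, d$subject_id)
  y <- 100 * (ser$hr_bpm - d$hr_rest[i]) / (d$hr_max[i] - d$hr_rest[i])
  x <- if (xScale == "percent_vo2r") {
    100 * (ser$vo2_mlkgmin - d$vo2_rest[i]) / (d$vo2_max[i] - d$vo2_rest[i])
  } else {
    100 * ser$vo2_mlkgmin / d$vo2_max[i]
  }
  out <- data.frame(subject_id = ser$subject_id, sex = d$sex[i],
                    mode = ser$mode, x = x, y = y)
  attr(out, "x_scale") <- xScale
  class(out) <- c("scaledSeries", "data.frame")
  out
}

#' @export
print.restingProfile <- function(x, ...) {
  cat(sprintf("Resting profile: HR %.1f bpm, VO2 %.2f mL/kg/min\n",
              x$hr_rest, x$vo2_rest))
  invisible(x)
}

#' @export
print.maximalProfile <- function(x, ...) {
  cat(sprintf(
    "Maximal profile: HR %.1f bpm, VO2 %.2f mL/kg/min (window at %g s), RER %.2f\n",
    x$hr_max, x$vo2_max, x$window_start_sec, x$rer_max))
  invisible(x)
}
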