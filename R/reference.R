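#' Reference cohort parameters for recreationally active young adults
#'
#' Published summary statistics (mean and SD) for a cohort of 41
#' recreationally active adults (21 males, 20 females, 18-39 yr) who
#' completed a supine resting energy-expenditure assessment and maximal
#' graded exercise tests on both a treadmill and a cycle ergometer. These
#' values are the defaults for [cohortConfig()], so synthetic cohorts
#' reproduce the demographic, resting and maximal-test profile of that
#' study population.
#'
#' @return A data frame with columns `variable`, `sex`, `mode`
#'   (`NA` for rest/demographics), `mean`, `sd`.
#' @seealso [referenceModelEstimates()], [referenceIntensityTable()]
#' @export
#' @examples
#' subset(referenceCohortParams(), variable == "hr_rest")
referenceCohortParams <- function() {
  rbind(
    data.frame(
      variable = rep(c("age_yr", "mass_kg", "height_cm", "bmi"), 2),
      sex  = rep(c("male", "female"), each = 4),
      mode = NA_character_,
      mean = c(25.2, 72.9, 180.6, 22.3,  22.0, 58.8, 163.8, 21.9),
      sd   = c( 5.4, 10.8,   9.5,  2.4,   5.2,  6.8,   5.7,  2.3)
    ),
    data.frame(
      variable = rep(c("hr_rest", "vo2_rest"), 2),
      sex  = rep(c("male", "female"), each = 2),
      mode = NA_character_,
      mean = c(53.9, 3.7, 59.1, 3.4),
      sd   = c( 6.3, 0.35, 7.7, 0.37)
    ),
    data.frame(
      variable = rep(c("rer_max", "hr_max", "vo2_max"), 4),
      sex  = rep(rep(c("male", "female"), each = 3), 2),
      mode = rep(c("treadmill", "cycle"), each = 6),
      mean = c(1.20, 183.0, 57.3,  1.14, 188.6, 45.7,
               1.20, 180.0, 54.5,  1.18, 182.7, 43.7),
      sd   = c(0.09,  11.9,  7.1,  0.08,  12.4,  3.3,
               0.06,  11.5,  7.1,  0.05,  12.1,  5.8)
    )
  )
}

#' Reference posterior summaries for the %HRR-%VO2 population line
#'
#' Published posterior means, SDs and 95% credible intervals for the
#' population intercept and slope of the hierarchical %HRR-on-%VO2
#' regression, in each of the eight analysis cells (2 x-scales, 2 sexes,
#' 2 exercise modes) for the cohort described in
#' [referenceCohortParams()]. The %VO2R rows double as the default
#' generating truth of [truthParams()].
#'
#' @return A data frame with one row per cell and columns `x_scale`
#'   (`"percent_vo2max"` or `"percent_vo2r"`), `sex`, `mode`,
#'   `intercept`, `intercept_sd`, `intercept_lo`, `intercept_hi`,
#'   `slope`, `slope_sd`, `slope_lo`, `slope_hi`.
#' @export
referenceModelEstimates <- function() {
  data.frame(
    x_scale = rep(c("percent_vo2max", "percent_vo2r"), each = 4),
    sex  = rep(c("male", "female"), 4),
    mode = rep(rep(c("treadmill", "cycle"), each = 2), 2),
    intercept    = c(12.42,  8.44,  9.99, 10.78, 18.26, 15.38, 16.38, 18.06),
    intercept_sd = c( 2.24,  2.27,  1.87,  2.02,  2.09,  2.11,  1.83,  1.90),
    intercept_lo = c( 8.00,  3.98,  6.29,  6.78, 14.02, 11.20, 12.78, 14.19),
    intercept_hi = c(16.88, 12.96, 13.64, 14.80, 22.40, 19.54, 20.00, 21.92),
    slope    = c(0.876, 0.943, 0.912, 0.931, 0.818, 0.873, 0.849, 0.858),
    slope_sd = c(0.023, 0.024, 0.018, 0.021, 0.021, 0.023, 0.017, 0.019),
    slope_lo = c(0.831, 0.895, 0.876, 0.890, 0.777, 0.828, 0.815, 0.821),
    slope_hi = c(0.921, 0.990, 0.947, 0.973, 0.858, 0.918, 0.884, 0.896)
  )
}

#' Reference %HRR prediction table at prescribed intensities
#'
#' Published modal %HRR values (rounded to integer percent) with 95%
#' credible intervals at 45/55/65/75/85 %VO2max or %VO2R, for the same
#' eight analysis cells as [referenceModelEstimates()]. `flagged` marks
#' cells where the target intensity fell outside the credible interval,
#' i.e. where %HRR significantly overestimates the %VO2 value.
#'
#' @return A data frame with columns `x_scale`, `sex`, `mode`, `target`,
#'   `hrr_pct` (integer percent), `lo`, `hi`, `flagged`.
#' @export
referenceIntensityTable <- function() {
  cell <- function(x_scale, sex, mode, hrr, lo, hi, flagged) {
    data.frame(x_scale = x_scale, sex = sex, mode = mode,
               target = c(45, 55, 65, 75, 85),
               hrr_pct = hrr, lo = lo, hi = hi, flagged = flagged)
  }
  rbind(
    cell("percent_vo2max", "male", "treadmill",
         c(52, 61, 69, 78, 87),
         c(47.1, 55.7, 64.3, 72.8, 81.3), c(56.7, 65.6, 74.6, 83.6, 92.7),
         c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    cell("percent_vo2max", "male", "cycle",
         c(51, 60, 69, 78, 87),
         c(47.1, 56.1, 65.0, 73.9, 82.8), c(55.0, 64.3, 73.6, 82.8, 92.2),
         c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    cell("percent_vo2max", "female", "treadmill",
         c(51, 60, 70, 79, 89),
         c(46.0, 55.2, 64.4, 73.6, 82.7), c(55.7, 65.3, 74.9, 84.6, 94.3),
         c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    cell("percent_vo2max", "female", "cycle",
         c(53, 62, 71, 81, 90),
         c(48.4, 57.5, 66.6, 75.7, 84.8), c(57.0, 66.4, 75.9, 85.5, 95.1),
         c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    cell("percent_vo2r", "male", "treadmill",
         c(55, 63, 71, 80, 88),
         c(50.6, 58.6, 66.5, 74.6, 82.5), c(59.5, 67.8, 76.2, 84.6, 93.1),
         c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    cell("percent_vo2r", "male", "cycle",
         c(55, 63, 71, 80, 88),
         c(50.7, 59.1, 67.5, 75.7, 84.1), c(58.4, 67.0, 75.7, 84.4, 93.1),
         c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    cell("percent_vo2r", "female", "treadmill",
         c(55, 63, 72, 81, 90),
         c(50.2, 58.8, 67.3, 75.7, 84.2), c(59.2, 68.1, 77.1, 86.1, 95.1),
         c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    cell("percent_vo2r", "female", "cycle",
         c(57, 65, 74, 82, 91),
         c(52.7, 61.1, 69.5, 77.9, 86.2), c(60.8, 69.5, 78.3, 87.1, 95.9),
         c(TRUE, TRUE, TRUE, TRUE, TRUE))
  )
}
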