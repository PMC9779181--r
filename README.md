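# hrvo2

Bayesian hierarchical analysis of the heart rate-oxygen uptake
relationship during graded treadmill and cycle exercise.

Aerobic exercise intensity is usually prescribed as a percentage of
heart-rate reserve (%HRR, the Karvonen scale) on the assumption that it
matches the same percentage of oxygen-uptake reserve (%VO2R) or maximal
oxygen uptake (%VO2max) — i.e. that the regression of %HRR on %VO2 lies
on the line of identity (intercept 0, slope 1). `hrvo2` is for exercise
physiologists and biostatisticians who want to test that assumption the
way it should be tested: per subject, with all 15-s samples of a graded
test, in a Bayesian hierarchical model.

The model, for subject *i* and 15-s sample *j*:

    y_ij ~ Normal(b0_i + b1_i * x_ij, sigma^2)        y = %HRR, x = %VO2R or %VO2max
    b0_i ~ Normal(mu_b0, sigma^2_intercepts)          mu_b0 ~ Normal(0, 1000)
    b1_i ~ Normal(mu_b1, sigma^2_slopes)              mu_b1 ~ Normal(1, 10)

with Gamma(1.1, 0.01) priors on the residual and intercept dispersion
and Gamma(1.1, 1) on the slope dispersion (read on the variance scale;
see the methods vignette for why, and for the precision-scale option).
The package provides:

* a synthetic-cohort generator emulating a 41-subject study (21 males,
  20 females, both test modes, ~51 fifteen-second samples per test),
* extraction rules for resting and maximal values (5-min discard rule,
  30-s VO2max windows gated at RER >= 1.10, two-of-three maximal-effort
  criteria) and reserve/percent transforms,
* a compiled blocked Gibbs sampler (20 chains x 11,000 iterations,
  1000 burn-in, thin 20 by default -> 10,000 saved draws),
* native convergence diagnostics (Gelman-Rubin Rhat, spectral effective
  sample size, Raftery-Lewis dependence factor), cross-checked against
  coda,
* Bayesian two-group comparisons for cohort descriptions, and
* posterior reporting: identity-line tests, sex/mode contrasts, and
  modal %HRR with 95% credible intervals at 45-85% target intensities.

## Worked example

```r
library(hrvo2)

cfg <- pipelineConfig(synthetic = list(), outputDir = "hrvo2_run",
                      masterSeed = 7)
res <- runPipeline(cfg)
#> stage cohort        0.3 s
#> stage derive        0.1 s
#> stage fit           7.4 s
#> diagnostics worst case: Rhat 1.0008, min ESS 9579, max RL 1.054
#> stage report        0.2 s

subset(res$report$identity, x_scale == "percent_vo2r" & sex == "male")
#>        x_scale  sex      mode intercept intercept_lo intercept_hi  slope slope_lo slope_hi
#> 5 percent_vo2r male treadmill    17.993       14.876        21.23 0.8039   0.7670   0.8399
#> 6 percent_vo2r male     cycle    14.711       11.066        18.28 0.8618   0.8203   0.9030

subset(res$report$predictions,
       x_scale == "percent_vo2r" & sex == "male" & mode == "treadmill")
#>    target hrr_pct    lo    hi flagged
#> 21     45      54 50.81 57.52    TRUE
#> 22     55      62 58.69 65.71    TRUE
#> 23     65      70 66.57 73.93    TRUE
#> 24     75      78 74.42 82.14   FALSE
#> 25     85      86 82.25 90.39   FALSE
```

Reading the output: for males running on a treadmill, the %HRR-%VO2R
line fitted to this synthetic cohort has intercept ~18 points and slope
~0.80 — both credible intervals exclude the identity line, so a
prescription assuming %HRR = %VO2R overshoots. The prediction table
quantifies it: at 45% VO2R the modal %HRR is 54% and the 95% interval
(50.8, 57.5) excludes 45 (flagged); by 75-85% the interval contains the
target and the two scales agree within uncertainty. The cohort was
generated at intercept 18.26 and slope 0.818 for this cell, which the
fit recovers.

Lower-level entry points: `generateCohort()`, `deriveCohort()`,
`scaleSeries()`, `fitHierarchical()`, `diagnoseFit()`,
`identityTest()`, `predictIntensity()`, `compareMeans()`; cohorts and
draws round-trip through CSV (`writeCohort()`/`readCohort()`,
`writeDraws()`/`readDraws()`), and `readPipelineConfig()` reads a
YAML/JSON pipeline configuration.

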