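---
title: "Modelling the %HRR-%VO2 relationship: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the %HRR-%VO2 relationship: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvo2)
```

## The scientific question

Exercise intensity is commonly prescribed as a percentage of heart-rate
reserve (%HRR, the Karvonen scale), on the assumption that a given %HRR
corresponds one-to-one to the same percentage of oxygen-uptake reserve
(%VO2R) or, historically, of maximal oxygen uptake (%VO2max). If that
assumption held, the regression of %HRR on %VO2R would coincide with the
line of identity (intercept 0, slope 1). This package implements a
Bayesian hierarchical analysis of that question for cohorts who complete
graded exercise tests on both a treadmill and a cycle ergometer: reserve
scaling of the 15-s HR and VO2 samples, a random-intercept/random-slope
model per (x-scale, sex, mode) cell, convergence diagnostics, identity
line tests, sex and mode contrasts, and modal %HRR predictions with 95%
credible intervals at prescribed intensities (45-85%).

## The hierarchical model

For subject *i* with 15-s samples *j*:

$$y_{ij} \sim \mathrm{N}(b_{0i} + b_{1i} x_{ij},\ \sigma^2), \qquad
  b_{0i} \sim \mathrm{N}(\mu_{b0}, \sigma^2_{\text{int}}), \qquad
  b_{1i} \sim \mathrm{N}(\mu_{b1}, \sigma^2_{\text{slope}}),$$

where *y* is %HRR and *x* is %VO2R or %VO2max (both on the 0-100
scale; VO2 is the independent variable). Hyperpriors are
$\mu_{b0} \sim \mathrm{N}(0, 1000)$ and $\mu_{b1} \sim \mathrm{N}(1, 10)$
(second argument a variance), and the dispersion components carry
Gamma(1.1, 0.01) priors (residual, intercepts) and Gamma(1.1, 1)
(slopes). All inference is on the population parameters.

### Where the Gamma priors sit: variance, not precision

A Gamma prior written for "sigma-squared" is ambiguous in practice,
because the standard Gibbs-sampling toolchains parameterize the normal
by its precision and conventionally place Gamma priors there. We
implement both readings (`modelSpec(gammaOn = ...)`) and default to the
**variance** reading, for a quantitative reason rather than a stylistic
one: under the precision reading, a Gamma(1.1, 1) prior on the slope
precision gives that precision a posterior mean of at most
$(1.1 + n/2)/1 \approx 11$ for a 20-subject cell — no amount of data can
push it higher, because the likelihood contributes to the shape but the
rate stays at its prior value. The slope dispersion is then floored near
0.09, and the population slope cannot be estimated more precisely than
about $\pm 0.07$. Posterior slope uncertainties of the order actually
attainable with ~50 samples per subject (SD near 0.02) — and credible
intervals narrow enough to distinguish a slope of 0.85 from 1 — arise
only under the variance reading. The variance-scale components lose
conjugacy; they are updated by slice sampling on the log variance
(stepping-out plus shrinkage), which needs no step-size tuning and
leaves the thinned output effectively uncorrelated.

### Sampler

The sampler is a blocked Gibbs scheme operating on per-subject
sufficient statistics: each subject's $(b_{0i}, b_{1i})$ is drawn
jointly from its bivariate normal full conditional, the population
means from conjugate normal conditionals, and the dispersion components
from gamma conditionals (precision mode) or by slice sampling (variance
mode). The default configuration is 20 chains of 11,000 iterations,
1000 burn-in, thinned by 20 — 10,000 saved draws per parameter. Chains
start from per-subject least-squares estimates jittered with
chain-indexed Gaussian noise, so the potential scale reduction factor
compares genuinely overdispersed starting points; per-chain RNG streams
are derived deterministically from the master seed. Precisions are
floored at $10^{-12}$; there is no other regularization. The sampler
core is compiled (Rcpp) and uses R's RNG, so results are exactly
reproducible from `set.seed()` semantics.

Validation is dual-route throughout: the subject-level update is tested
against the closed-form conjugate posterior of the known-variance
single-subject sub-model; `logJoint()` provides the unnormalized log
posterior for hand-summed fixtures; and the full sampler is
cross-checked against an independent JAGS fit of the identical model.

## Convergence diagnostics

Three diagnostics are implemented natively and cross-checked against
the coda package on fixtures:

* **Rhat** — the classic (non-split) Gelman-Rubin potential scale
  reduction factor, $\sqrt{((n-1)/n\,W + B/n)/W}$, with a documented
  sentinel of 1.0 for all-constant chains and a `split = TRUE` variant.
* **Effective sample size** — $n \,\mathrm{var}(x)/S(0)$ with $S(0)$
  estimated by an AR model selected by AIC, summed across chains.
* **Raftery-Lewis** — binarization at the 0.025 quantile, BIC choice of
  the smallest adequate thinning for a first-order two-state chain, and
  burn-in/run-length read off the fitted transition matrix
  (q = 0.025, r = 0.005, s = 0.95, the method's canonical defaults).

`diagnoseFit()` computes Rhat and ESS on the thinned saved draws and
the dependence factor on the pooled saved draws, since the per-chain
saved segments (500 draws) are below the method's pilot minimum (3746).
Two measurement caveats matter and are worth stating plainly. First,
computing the dependence factor on the *raw* unthinned chains
(`rlOn = "raw"`) yields factors of roughly 2-10 here: the raw Gibbs
output is genuinely autocorrelated, which is exactly what the 20-fold
thinning removes; quoting a dependence factor near 1 is a statement
about the saved output. Second, at 10,000 draws the dependence factor
carries sampling noise with a standard deviation of about 0.022 even
for exactly independent draws, so the worst case over the 40
(parameter, cell) values of a full run fluctuates to ~1.05 and beyond
by chance; thresholds compared against it should be read with that
noise in mind.

## The synthetic cohort generator

No public individual-level data exist for this design, so the generator
is a first-class module that emulates the study conditions: 21 males
and 20 females; demographics, supine resting values and per-mode
maximal values drawn as independent truncated normals at the published
sex-specific means and SDs (HR bounded to 30-230 bpm, VO2 positive;
only marginal moments are published, so independence is the simplest
faithful choice); and per-test series built on the model's own
hierarchical structure. Each (subject, mode) pair has its own RNG
substream keyed to the master seed, so cohorts are bit-identical under
a fixed seed and stable under reordering.

Choices the published summaries do not pin down, fixed once here:

* **Generating scale and truth.** Series are generated on the %VO2R
  scale with per-cell truths set to the published %VO2R posterior
  means; the %HRR and VO2 samples are then back-transformed to raw
  units with the subject's own rest/max values. The %VO2max
  relationship follows deterministically (for the male treadmill cell
  the implied %VO2max line is 12.6 + 0.874x against a published
  12.42 + 0.876x), so one physical series serves both x-scales, as in
  a real test.
* **Dispersion defaults.** Between-subject SDs of 8 %HRR points
  (intercepts) and 0.08 (slopes), residual SD 5 points — plausible
  inter-individual spread consistent with the published posterior SDs
  of the population means at n around 20.
* **Protocol shape.** 3-min stages sampled every 15 s at
  40/55/70/85/100 %VO2R, with the final stage cut to 45 s by volitional
  fatigue: 51 samples per test and 4182 for a full cohort, matching the
  roughly 51 samples per test such protocols produce. The first
  treadmill stages stand in for the walk/walk/jog lead-in; speeds and
  grades are irrelevant to the model and not emulated.
* **RER channel.** A deterministic monotone ramp
  $0.80 + 0.45 (x/100)^{1.5}$ plus small noise, crossing the 1.10
  maximal-effort gate near test end so the extraction gates are
  exercisable.

What the generator deliberately does not emulate: VO2 on-kinetics and
the slow component, cardiovascular drift, day-to-day variation in
resting values, or any covariance between demographics and physiology.
Passing tests therefore demonstrate correctness of the statistical
machinery under the model's own assumptions, not robustness to the
physiological structure real data add on top.

## Measurement rules

Resting values are the mean of per-minute supine averages after
discarding the first 5 min. VO2max is the highest mean VO2 over any
contiguous 30-s window whose mean RER is at least 1.10 — windows are
overlapping pairs of 15-s samples, ties resolved to the earliest
window, and a "no qualifying window" condition is a distinct error;
an optional tail restriction exists but is off by default because the
RER gate already pushes selection late. HRmax is the highest recorded
HR. Maximal effort requires two of three criteria: RER at or above
1.10, HRmax within 15 bpm of the age-predicted maximum (220 − age by
default, configurable), and a caller-supplied VO2-plateau judgement —
no numeric plateau detector is applied, since no threshold is defined
for one. Percent scales are carried on 0-100 throughout; the pipeline
scales by the subject record's measured rest/max values by default,
with series-derived maxima available as an option.

## Reporting

Identity-line tests use equal-tailed 95% credible intervals
(2.5/97.5 percentiles); the intercept differs from 0, or the slope from
1, exactly when the reference value falls outside the interval. Sex and
mode contrasts are posterior probabilities from index-paired draws with
a 0.95 significance cutoff, ties split (so a self-comparison gives
exactly 0.5). Intensity predictions form the per-draw population value
$\mu_{b0} + \mu_{b1} x$ at x in {45, 55, 65, 75, 85}; the point
estimate is the kernel-density mode (Gaussian kernel, Silverman
bandwidth, 512-point grid — `pointEstimate = "mean"` is kept as a
sensitivity option since a mode estimator is a choice), the interval is
equal-tailed, and a target is flagged when it falls outside the
interval. Displayed values are rounded to integer percent, halves away
from zero; full precision is retained. Group comparisons (demographics,
resting and maximal values) use independent normal models per group
with Normal(50, 10000) mean priors on native units and no
equal-variance constraint; mode comparisons are unpaired, matching the
independent-prior formulation, although the same subjects performed
both tests — a simplification worth remembering when interpreting those
rows.

## Problem sizes used by the test-suite

The full study configuration (41 subjects, 10,000 saved draws, eight
cells) runs in seconds per fit, and the packaged checks use it directly
for the convergence re-run; parameter-recovery and identity-line checks
use 20 simulated replicates at study size with reduced chain counts,
and unit tests use small cohorts and short chains. Recovery replicates
are generated as antithetic pairs (subject-effect draws negated in the
partner), which removes the between-subject noise term from the
bias estimate without touching the estimand.

## Known limitations

* Truncated-normal marginals with independent components cannot
  reproduce correlations (e.g. fitness with mass) present in real
  cohorts.
* The generator's dispersion defaults are conventions, not published
  values; recovery behaviour at very different dispersion regimes
  should be re-verified before quantitative use.
* The x variable is treated as fixed; there is no measurement-error
  model for VO2, no heteroscedasticity, and no alternative likelihoods.
* Raftery-Lewis dependence factors near 1 should be interpreted with
  the sampling-noise caveat above.
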