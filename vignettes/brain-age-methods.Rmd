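---
title: "Estimating adiposity-related brain-age differences from white-matter trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adiposity-related brain-age differences from white-matter trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Cerebral white-matter volume follows an inverted-U over the adult lifespan:
it grows into middle age, peaks, and declines thereafter. If adiposity
accelerates or advances white-matter ageing, the trajectory of overweight
and obese adults should look like the lean trajectory evaluated at an older
age. `adipoage` implements the estimator built on that idea: fit a smooth
white-matter-volume-versus-age curve separately for lean (BMI in
[18.5, 25)) and overweight/obese (BMI >= 25) adults, then, for each volume
on the descending limbs, read off the *age difference* at which the two
groups attain the same volume. That age difference — positive when the
heavier group reaches a given (lower) volume younger — is the
"brain-age difference" reported per overweight/obese reference age.

The package covers the full analysis path: a synthetic cohort generator,
study inclusion/exclusion rules, penalized-spline trajectory models with
covariate adjustment and age-by-BMI interaction tests, the constrained
volume-matching estimator, and percentile bootstrap confidence bands.

## The trajectory model

Each outcome is modelled as

$$ y_i = f(\mathrm{age}_i) + x_i^\top \beta + \varepsilon_i $$

with `f` a penalized B-spline (P-spline): cubic B-splines on 20
equally-spaced knots over the observed age range, with a second-order
difference penalty on adjacent spline coefficients. The fit minimizes
`||y - B theta - X beta||^2 + lambda ||D2 theta||^2`; covariates are
mean-centered and unpenalized, so the fitted grid is the trajectory of a
reference subject with average covariates (sex at 1/2, i.e. sex-balanced).
The smoothing parameter is chosen by GCV by default; REML — motivated by
the mixed-model view of a penalized spline, with the penalty acting as a
random-coefficient precision — is available via `method = "REML"` and must
(and does, in the test suite) agree with GCV on noiseless polynomial
recovery. Because the study design is cross-sectional (one scan per
subject), no subject-level random effects are needed: the "mixed-effect"
component reduces to the spline's random-coefficient representation.

Numerical choices that matter:

* The final solve stacks `[C; sqrt(lambda) D]` and uses a QR factorization,
  so arbitrarily large `lambda` is handled exactly; at `lambda -> Inf` with
  the order-2 penalty the fit collapses onto the ordinary least-squares
  straight line in age (a property the test suite checks to 1e-6).
* The order-2 penalty has a two-dimensional null space (lines in age), so
  the smooth's effective degrees of freedom floor at 2, not 1; a constant
  outcome is still reproduced exactly at every `lambda` because constants
  lie in the null space.
* Inference is approximate by construction: the whole-smooth F statistic
  compares the penalized model with the covariates-only model using
  edf-based degrees of freedom, and linear-term t statistics use the
  model-based covariance with `n - edf_total` residual degrees of freedom.
  The test suite asserts *calibration by simulation* (the age-by-BMI
  interaction test rejects a true null at close to its nominal 5% level)
  rather than exact distributional identities.
* The age-by-BMI interaction uses continuous mean-centered BMI by default;
  lean-versus-overweight/obese group coding is available because the
  group-contrast formulation is what the two-trajectory estimator uses.

## The brain-age difference estimator

`fit_group_trajectories()` fits the two groups independently (same basis,
covariates centered at pooled means so the curves are comparable) and
evaluates both on a common age grid with a 0.1-year step.
`age_difference_curve()` then, for each overweight/obese reference age `a`
in the evaluation window (37–87 years by default):

1. takes the overweight/obese fitted volume `v(a)`,
2. inverts the *descending limb only* of the lean curve at `v(a)` by
   bracketing adjacent grid points and interpolating linearly (rule 1:
   matching never pairs post-peak decline in one group with pre-peak growth
   in the other — the reason the window starts at 37 rather than at the
   younger ages where the same volume also occurs on the ascending limb),
3. reports `delta(a) = lean age at matched volume - a`.

Rule 2 clamps negative deltas to zero (the heavier group holding *more*
volume than age-matched lean subjects is not evidence of accelerated
ageing under this estimand); rule 3 truncates the matched lean age at the
oldest observed age when no lean reference is old enough, which biases
delta toward zero at the oldest ages — those ages are flagged
`truncated_support` and excluded from summary means. Each applied rule is
flagged per age, and rule 2 can be toggled off to expose the unclamped
curve.

Because the generator shifts the overweight/obese trajectory horizontally
(`f(age + shift)`), the true brain-age difference on the descending limb is
exactly the configured shift — the recovery target the acceptance checks
use. Inversion between grid nodes is linear (no spline re-evaluation),
keeping the bootstrap cost linear in grid size; halving the grid step moves
delta by less than one prior grid step.

`bootstrap_brain_age()` resamples subjects with replacement within each
weight group (preserving group sizes; pooled resampling is available),
refits both trajectories, and recomputes the constrained curve inside every
iteration. Bands are elementwise percentile intervals — the minimal
assumption for "the 95% and 90% CIs of bootstrap replicates" — at 10,000
iterations by default. Iterations without descending-limb support at an age
contribute nothing there; ages with under 50% valid iterations have their
CI marked unavailable.

## What the synthetic generator emulates — and what it does not

Defaults were fixed once to the study conditions and are not tuning knobs:

* ages uniform on 20–87; expected weight-group proportions 51/31/18%
  (lean/overweight/obese);
* BMI drawn from a shifted-lognormal marginal (`18.5 + LN(1.856, 0.640)`)
  coupled to age by a Gaussian copula with latent correlation 0.275,
  calibrated once so the Pearson age-BMI correlation is near the cohort's
  reported 0.24. A Gaussian BMI marginal cannot produce both the mean
  (~26 kg m^-2) and the 51% lean share — the BMI distribution is
  right-skewed — which is why the copula model is the default; the additive
  Gaussian model remains available as `bmi_model = "linear"`;
* a concave-quadratic lean white-matter trajectory peaking at 43 years
  (465 cm^3, curvature 0.07 cm^3/y^2). The peak age follows from the
  worked-example geometry: a symmetric curve attaining 445 cm^3 at both 26
  and 60 years peaks at their midpoint; the curvature and peak volume then
  place 445 cm^3 at those ages while keeping volumes physiologic. The
  overweight/obese trajectory is the lean one shifted by
  `true_age_shift` (default 10) years; residual SD 15 cm^3. An optional
  piecewise-asymmetric variant (`trajectory_form = "piecewise"`) supports
  robustness tests;
* per-sex intracranial volume (1400/1550 +- 110 cm^3) scaling the
  white-matter mean, so the ICV covariate adjustment has real work to do;
* near-linear surface-area and thickness declines, a small positive
  thickness offset for the heavier group, gray-white contrast declining
  with age and feeding thickness, and a nonlinear (quadratic) Cattell
  decline with a brain-size effect;
* binary health/sociodemographic flags as independent Bernoulli draws given
  age (prevalences from the cohort's demographic table; hypertension and
  cholesterol mildly age-dependent) — their joint dependence is not
  modelled;
* quality ratings with a logistic age effect on "poor" (log-odds 0.04 per
  year around a 7% mid-age rate), mirroring the older-worse association.

One root seed drives one fixed substream per column, so adding a column
never perturbs existing ones, and identical (config, seed) pairs give
bit-identical CSVs. Recorded values are rounded to realistic measurement
precision and all downstream columns derive from the recorded values, so
the written table is an exact function of itself.

What passing tests on this generator do *not* show about real data: the
generator's trajectory family is exactly the estimator's target (shifted
smooth curves), its noise is homoscedastic Gaussian, covariates are
conditionally independent, there is no selection, scanner, or longitudinal
structure, and BMI is an error-free exposure. Recovery of the generating
shift therefore validates the estimator's logic and numerics, not the
substantive claim on any particular cohort; cohort-specific statistics
(F and t values of the source study) are deliberately not targets.

## Preprocessing conventions

* BMI bands are half-open with the boundary on the heavier side
  (25 is overweight, 30 is obese), following the operative grouping table.
* Exclusions apply in the fixed order age, underweight, quality, each
  subject counted once under its first triggering rule, making the
  exclusion report deterministic; the minimum age is a parameter
  (default 20).
* Bland-Altman agreement uses the conventional 1.96 SD limits, and the
  edit-effect test is a paired comparison reported as F = t^2 (the exact
  test form behind the published F values is not stated; a paired test of
  zero mean difference is the minimal reading).
* Box-Cox transformation is available per outcome (profile-likelihood MLE
  for the exponent); pipeline defaults leave outcomes untransformed since
  the generator's residuals are Gaussian on the natural scale.
* Missing covariate handling is complete-case with the dropped count
  logged on the fit object.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to make the Monte-Carlo answer
stable while staying cheap on a single CPU: 50 simulated cohorts (n = 473)
for shift recovery, 400 replicates (n = 300) for interaction-test size,
200 cohorts (n = 300) with 500 bootstrap iterations each for band coverage
— reduced from the 10,000 iterations used for final inference, which only
sharpens quantile estimates, not coverage. Percentile-band coverage at
these sizes can sit off nominal in either direction: finite resampling
usually costs a little coverage, while the zero-clamping rule widens the
effective band wherever clamping triggers; the checks therefore accept
central-age coverage between 88% and 99%.

## Known limitations

* The estimator is the volume-matching construction only; it is not a
  regression-based "brain age" predictor, and it is undefined on ascending
  limbs by design.
* Rule 3 truncation biases delta downward at the oldest ages; summaries
  exclude truncated ages and the flags make the truncation visible.
* Smoothing-parameter selection is not invariant to duplicating every
  subject k times (a known CV/REML degeneracy under duplicated rows); at
  fixed lambda scaled by k the fit is exactly invariant, which is what the
  suite asserts.
* Near the trajectory peak the inverse function is ill-conditioned (the
  derivative vanishes), inflating delta noise just above the peak age;
  the evaluation window's 37-year floor exists precisely to avoid the
  worst of this region.
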