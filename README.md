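# adipoage

Does carrying extra body weight make the brain look older? Cerebral
white-matter volume follows an inverted-U over the adult lifespan — rising
to a middle-age peak, declining thereafter — and if adiposity advances
white-matter ageing, the overweight/obese trajectory should resemble the
lean trajectory evaluated at an older age. `adipoage` is an R package for
biostatisticians and imaging epidemiologists that implements this analysis
end to end on cross-sectional cohort tables of brain morphometrics.

At its core is the **volume-matched brain-age difference**. Fit a smooth
volume-versus-age curve per weight group (lean: BMI in [18.5, 25);
overweight/obese: BMI ≥ 25) with penalized splines,

$$y_i = f(\mathrm{age}_i) + x_i^\top\beta + \varepsilon_i,
\qquad \min_\theta \; \lVert y - B\theta - X\beta\rVert^2
 + \lambda\lVert D_2\theta\rVert^2 ,$$

then, for each overweight/obese reference age $a$ on the descending limb,
invert the lean curve at the matched volume and report

$$\Delta(a) \;=\; \underbrace{f_{\mathrm{lean}}^{-1}\big(f_{\mathrm{ow}}(a)\big)}_{\text{descending limb only}} \; - \; a ,$$

with three constraint rules: matching is restricted to descending limbs,
negative differences are clamped to zero, and volumes below the lean
curve's oldest observed value are truncated at the oldest age (and
flagged). Percentile bootstrap bands come from within-group resampling with
the rules re-applied inside every iteration. A seeded synthetic cohort
generator with a known trajectory shift makes every stage testable: the
generating shift *is* the true brain-age difference, so recovery can be
checked exactly.

## Worked example

```r
library(adipoage)

coh <- generate_cohort(cohort_config(n_subjects = 473, seed = 1))
res <- apply_exclusions(coh)          # age >= 20, BMI >= 18.5, drop poor QC
res$report
#> Exclusions: 473 in -> 424 retained (0 age, 0 underweight, 49 quality)

pair <- fit_group_trajectories(res$cohort)
pair
#> Group trajectories of wm_volume on ages 20.1-85.8 (step 0.1)
#>   lean peak at 43.9 y; overweight/obese peak at 32.3 y

ba <- bootstrap_brain_age(res$cohort, n_iter = 1000, seed = 1,
                          eval_range = c(45, 80))
ba
#> Brain-age difference curve over 45-80 y (351 ages)
#>   mean delta 9.79 y; max 12.48 y at 49.3 y
#>   bootstrap: 1000 iterations, seed 1

it <- test_interaction(res$cohort)
sprintf("age:BMI interaction: t = %.2f, p = %.2g", it$t, it$p)
#> "age:BMI interaction: t = -8.69, p = 9.2e-17"
```

The generator's true trajectory shift is 10 years; the estimator recovers
a mean difference of 9.8 years over the 45–80-year window, peaking in the
late 40s, and the age-by-BMI interaction test flags the trajectory
modulation with a negative sign (heavier subjects hold less volume at older
matched ages). `run_pipeline(pipeline_config(...))` chains the same stages
for all four outcomes (white-matter volume, surface area, thickness,
Cattell score) and writes CSV/JSON artifacts plus a Markdown report; a thin
command-line wrapper lives at `inst/scripts/adipoage-cli.R` with
`generate`, `run`, `brainage` and `report` subcommands.

## Vignette

`vignettes/brain-age-methods.Rmd` documents the model and its assumptions,
the constraint rules and their reading, the generator's calibration, the
numerical choices, and known limitations.
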