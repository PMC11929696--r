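# odontomech

Analysis pipeline for destructive compression tests of odontoid (dens)
fracture fixations. The package is aimed at biomechanics labs running
paired intact/instrumented load-to-failure tests of C2 specimens: it turns
testing-machine logs into the three standard mechanical outcomes, expresses
the fixation's effect as percentages of stability restored, computes the
cortical cross-section ratio from traced contours, and runs the
covariate-adjusted two-group comparison. A synthetic-data generator with
known ground truth makes every stage testable without cadaveric data.

## The methods in brief

From each load-displacement curve (displacement in mm, load in N):

* **Stiffness** `S` — slope of the most linear portion: a 1 mm regression
  kernel moves sample-by-sample over windows starting after the toe region
  (1 mm initial displacement) and ending at or before the displacement of
  the ultimate load; the window maximising the Pearson correlation wins
  (earliest on ties), and `S` is its OLS slope.
* **Yield load** `F_YL` — onset of irreversible behaviour: the best
  window's right edge expands sample-by-sample and `F_YL` is the load where
  the correlation first drops below 0.85 (capped at the ultimate load, so
  `F_YL <= F_UL` always).
* **Ultimate load** `F_UL` — the absolute curve maximum; a curve with no
  major subsequent drop is flagged for review.

For paired states, each outcome `X` yields a percentage restored

```
(1 - (X_int - X_instr)/X_int) * 100%  =  100 * X_instr / X_int
```

and the group analysis is a one-way ANCOVA of each percentage on fixation
group, adjusted for the matching intact-state value, sex, age, vBMD and
Ct.Ar/Tt.Ar (the cortical-to-total area ratio,
`100 * (A_outer - A_inner)/A_outer`), after a homogeneity-of-slopes
pre-check, alongside Mann-Whitney group checks and bone-quality
regressions. Implausible curves are flagged (`nonlinear_curve`,
`no_load_drop`, `yield_not_found`, `manual_review`) rather than silently
dropped.

## Worked example

```r
library(odontomech)

## one synthetic curve with known truth: S = 181 N/mm, F_YL = 755 N, F_UL = 825 N
sim <- simulate_curve(curve_params(s_true = 181, f_yield = 755, f_ult = 825,
                                   sample_spacing = 0.01), seed = 1)
extract_outcomes(sim$curve)
#> <mech_outcomes>
#>   stiffness:      181.00 N/mm
#>   yield load:     797.63 N
#>   ultimate load:  824.93 N
```

Stiffness and ultimate load are recovered essentially exactly; the yield
load (797.6 N) lies inside the post-yield softening band [755, 825] N —
the correlation-decay criterion marks the loss of linearity, which on a
gently hardening curve is crossed somewhat above the true yield point.

```r
## a study-sized cohort (25 cannulated vs 22 allograft), restoration analysis
coh <- simulate_cohort(simulation_config(), seed = 1)
pair_and_restore(coh)$group_summary
#> # A tibble: 6 x 5
#>   fixation_group outcome       n mean_pct sd_pct
#> 1 allograft      stiffness    22     36.4   22.9
#> 2 allograft      ultimate     22     31.5   13.4
#> 3 allograft      yield        22     29.6   15.1
#> 4 cannulated     stiffness    25     61.8   34.9
#> 5 cannulated     ultimate     25     52.9   28.5
#> 6 cannulated     yield        25     51.3   33.7

rep <- run_study_analysis(coh)
rep$ancovas$stiffness
#> ANCOVA on pct_stiffness: F(1,28) = 2.199, p = 0.149
#>   allograft   adj. mean 27.3 +- 18.7 (n = 10)
#>   cannulated  adj. mean 64.4 +-  9.0 (n = 25)
```

The unadjusted means sit near the configured restoration fractions
(57/48/50% cannulated, 32/27/29% allograft); after covariate adjustment
the group difference in restored stiffness is not significant at this
seed. Per-cell `n` reflects listwise deletion over missing imaging
covariates.

A thin CLI wraps the same functions
(`inst/exec/odontomech {simulate|extract|restore|ctr|analyze}`), and
`vignettes/odontoid-fixation-pipeline.Rmd` documents the model, parameter
choices and limitations.

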