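---
title: "Quantifying restored mechanical stability of odontoid fracture fixations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying restored mechanical stability of odontoid fracture fixations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontomech)
```

## The problem

Fractures of the odontoid process (dens) of the second cervical vertebra
are common in older adults and are typically fixed with anterior screws.
A destructive paired-test design measures how much of the intact
mechanical stability a fixation restores: each cadaveric specimen is
compressed to failure in its intact state, the fracture is fixed, and the
instrumented construct is loaded to failure again under the same
alignment. The machine logs displacement (actuator-controlled, nominally
0.1 mm/s) and load (nominally digitised at 128 Hz). `odontomech`
implements the full computational chain from those machine logs to the
covariate-adjusted group comparison, plus a synthetic-data generator that
stands in for cadaveric data, which are not publicly distributable.

## Curve features

Three quantities summarise one load-displacement curve:

* **Ultimate load** $F_{UL}$: the absolute maximum of the curve. If the
  record never falls below $(1-\delta)\,F_{UL}$ afterwards (default
  $\delta = 0.2$), there was no catastrophic drop and the curve is flagged
  `no_load_drop` for review; the maximum is still reported.
* **Stiffness** $S$: the slope of the most linear portion. A kernel of
  width 1 mm moves sample-by-sample over all windows that start at or
  after the end of the toe region (1 mm of initial displacement) and end
  at or before the displacement of $F_{UL}$; each window is fitted by
  ordinary least squares and the window with the highest Pearson
  correlation wins, earliest window on ties. Sample-wise stepping makes
  this an exact arg-max over the sampled data; the tests verify equality
  with a brute-force scan, including tie-breaks.
* **Yield load** $F_{YL}$: the onset of irreversible behaviour, detected
  as loss of linearity. Starting from the best stiffness window, the
  window's right edge grows sample-by-sample with the left edge anchored
  at the window start, and the correlation is recomputed; $F_{YL}$ is the
  load at the first right edge where $r < 0.85$. The search is capped at
  the displacement of $F_{UL}$, which guarantees $F_{YL} \le F_{UL}$; if
  the threshold is never crossed the yield is absent and
  `yield_not_found` is flagged.

Two geometric conventions deserve a note. First, "ending at the highest
load level before inducing plasticity" is operationalised as *windows end
at or before* $d(F_{UL})$: plasticity onset is unknown before the yield is
computed, and the load maximum is a conservative, well-defined cap.
Second, the yield search *expands* rather than slides, because the yield
must lie after the most linear region; a sliding-window policy is
available (`pipeline_config(yield_policy = "slide")`) for sensitivity
analyses. An expanding window needs a substantial stretch of post-yield
data before the pooled correlation decays below 0.85 -- with $L$ mm of
elastic data inside the window, roughly $1.4 L$ to $1.7 L$ mm of shallow
post-yield data must accumulate -- so the detected yield displacement sits
well beyond the true kink even on noise-free curves, while the detected
yield *load* stays close to the true yield load because the post-yield
slope is shallow. The extraction therefore reports the softening band of
the simulator alongside, and accuracy is asserted on the load, within
that band.

Curves are not smoothed by default (an optional odd-width moving average
exists). Any flag raised additionally marks the specimen
`manual_review`, mirroring the visual verification step used with real
tests, and an audit trail (chosen window, correlation trace, drop check)
accompanies every extraction.

```{r extract-example}
sim <- simulate_curve(curve_params(s_true = 181, f_yield = 755, f_ult = 825,
                                   sample_spacing = 0.01), seed = 1)
extract_outcomes(sim$curve)
```

## Restoration percentages

For each outcome $X \in \{S, F_{YL}, F_{UL}\}$ with intact value $X_{int}$
and instrumented value $X_{instr}$, the percentage restored is

$$\left(1 - \frac{X_{int} - X_{instr}}{X_{int}}\right)\times 100\% =
  100\,\frac{X_{instr}}{X_{int}}.$$

Each outcome is normalised by its *own* intact value; the alternative
convention of normalising all three differences by the intact ultimate
load is available explicitly (`pair_and_restore(..., normalise_by =
"ultimate")`) but is not the default, since the per-outcome equations are
the operative definitions. A percentage is absent whenever either paired
value is absent or the intact value is non-positive, and absences
propagate as reduced per-cell *n*, never as zeros. Group summaries are
means over per-specimen ratios (mean of ratios), which is the only
reading consistent with reporting a per-specimen normalised outcome.

## Cross-sectional cortical ratio

The cortical bone of an odontoid cross-section is the shell between two
manually traced closed polylines. With shoelace areas $A_{outer}$ and
$A_{inner}$,

$$\mathrm{Ct.Ar/Tt.Ar} = 100\,\frac{A_{outer}-A_{inner}}{A_{outer}}\ \%.$$

Containment of the inner contour is checked only through the area
inequality; manual contours are assumed simple. Image segmentation and
vBMD computation are scanner-side and out of scope.

## Statistical pipeline

`run_study_analysis()` executes the full plan at $\alpha = 0.05$ per test
(no multiplicity correction by default; Holm is available):

1. Mann-Whitney U on donor age between fixation groups. The test is
   exact by full enumeration when the combined sample is at most 16
   without ties, otherwise a tie-corrected normal approximation is used.
2. For each restored percentage, a homogeneity-of-regression-slopes
   pre-check (partial F-tests of every group-by-covariate interaction),
   then a one-way ANCOVA of the percentage on fixation group adjusted
   for the matching intact-state value, sex, age, vBMD and Ct.Ar/Tt.Ar.
   The group effect is the partial (type-III) F-test; with two groups and
   five covariates the denominator df is $n_{used} - 7$. Adjusted means
   are model predictions at the grand covariate means of the included
   cases, factor covariates at their observed proportions (equivalent to
   proportionally weighted estimated marginal means); their SEs come from
   the coefficient covariance. Missing covariates cause listwise deletion
   per analysis, with per-cell *n* always reported; a covariate observed
   for no specimen is dropped with a message rather than emptying the
   analysis. Age is included by default (`include_age = FALSE` drops it).
3. A linear-regression grid of age, vBMD and Ct.Ar/Tt.Ar against
   stiffness, yield and ultimate load in both states, yield-vs-ultimate
   regressions pooled and per group, and -- when failure modes are
   recorded -- a Mann-Whitney comparison of intact and instrumented
   ultimate load between implant-breakage and other failures within the
   allograft group.

Violated slope homogeneity warns but does not block, so the adjusted
means remain inspectable; the warning is the analyst's cue.

## The synthetic-data generator

`simulate_curve()` builds a piecewise curve: a power-law toe on
$[0, 1\,\mathrm{mm}]$ joined C1-continuously to the elastic segment
(exponent 2 by default), a linear elastic segment of slope $S$, a shallow
linear post-yield segment of slope $0.04\,S$ from the yield to the
ultimate load, an abrupt drop to $0.25\,F_{UL}$ and a short residual
plateau. Noise is additive Gaussian on load only, since displacement is
actuator-controlled. The post-yield slope fraction and the derived
segment length were calibrated once from the correlation-decay geometry
above: with a shallower or shorter post-yield segment the expanding
window's correlation never reaches 0.85 before the load peak and the
yield would be systematically undetectable on clean curves, defeating the
generator's purpose of exercising every extractor. The true toe shape of
odontoid tests is not characterised; the power-law ramp is a modelling
choice exposed as a parameter.

`simulate_cohort()` draws two groups emulating a cadaveric
odontoid-fixation cohort of older donors: 25 cannulated-screw and 22
allograft-screw specimens; donor
age 82.5 +- 8.4 vs 71.2 +- 5.6 years; vBMD 531.4 +- 139.3 vs
556.6 +- 115.9 mg HA/cm^3; Ct.Ar/Tt.Ar 39.6 +- 10.0 vs 41.9 +- 9.1 %
(truncated normals); female fractions 0.60 vs 0.27. Intact ultimate load
is linear in vBMD (1.84 N per mg HA/cm^3, residual SD 228 N, chosen to
put the vBMD-strength coefficient of determination near 0.5); intact
stiffness is linear in vBMD and Ct.Ar/Tt.Ar; the intact yield/ultimate
ratio is uniform on 0.85-0.92. Instrumented outcomes are
`restoration_fraction * intact * lognormal` with mean-one noise, so the
expected restored percentage equals the configured fraction; the default
fractions (0.570/0.481/0.500 cannulated, 0.320/0.268/0.290 allograft)
are the observed unadjusted group means scaled to fractions. Yield and
ultimate share one specimen-level noise factor and stiffness loads it at
0.7 -- the same trabecular bed carries the implant -- which reproduces the
strong observed yield-ultimate correlation and keeps load/stiffness
ratios physiological. Small floors keep the piecewise curve realisable in
extreme noise tails; draws that still produce an elastic span shorter
than the regression kernel are extracted as implausible and carry review
flags, mirroring the few-per-group manual exclusions that destructive
cadaveric studies typically report. One global seed drives everything, with
per-specimen substreams for curve materialisation so individual
specimens can be regenerated in isolation.

What the generator does *not* emulate: visco-elastic rate effects,
machine compliance, cyclic or multi-directional loading, correlated
covariate structure beyond the linear outcome models, and the anatomical
judgement behind slice selection or fracture typing. Passing tests
demonstrate that the pipeline recovers known ground truth under this
idealised model, not that the biological conclusions generalise.

```{r cohort-example}
coh <- simulate_cohort(simulation_config(), seed = 1)
pair_and_restore(coh)$group_summary
```

## Numerical choices

* Window statistics use centred running sums, giving O(n) evaluation of
  all candidate windows; windows whose variance is at the level of
  accumulated rounding error are treated as degenerate rather than
  signal.
* Exactly collinear windows come out of floating-point arithmetic as
  $1 \pm$ a few ulp; correlations above $1 - 10^{-10}$ are snapped to 1
  so the earliest-window tie-break is deterministic and matches a plain
  `cor()`-based scan.
* Displacement jitter up to $10^{-6}$ mm (transducer noise) is clamped to
  a monotone axis at ingestion; larger decreases are errors.
* All internal units are fixed to mm and N; conversions happen only at
  ingestion via explicit options, and an optional re-zero flag handles
  machines that log absolute actuator position after preload.
* Validation problem sizes: oracle equivalence on 200 random curves at
  0.03 mm spacing; noise-free recovery on 100 curves at 0.02 mm;
  noisy-recovery and the full-cohort run at the nominal 0.1/128 mm
  spacing; ANCOVA type-I calibration on 500 replicates of the 22+25
  design; slope coverage on 300 replicates of n = 200 (large enough that
  a +-2 SE interval carries its Gaussian ~95% coverage -- at small n the
  t-quantile makes 2-SE coverage noticeably lower).

## Known limitations

* The expanding-window yield displacement is a threshold-crossing
  location, not an unbiased kink estimate; compare policies before
  interpreting yield displacements.
* The ANCOVA denominator df is $n_{used} - 7$ with age included, but
  per-cell n depend on the manual exclusion of implausible curves, which
  the flags can only mirror, not replicate exactly.
* The simulated intact yield/ultimate correlation is tighter than in
  real specimens because the ratio is drawn from a narrow uniform band.
* Mann-Whitney switches from exact enumeration to the tie-corrected
  normal approximation at combined n = 16; with many ties at small n the
  approximation is the only available route.
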