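---
title: "Methods: stratified upper reference limits for hs-cTnT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified upper reference limits for hs-cTnT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnref)
```

## The problem

The decision threshold for high-sensitivity cardiac troponin T (hs-cTnT) is
conventionally the 99th percentile of a cardiac-healthy reference
population — the *upper reference limit* (URL).  A single fixed URL ignores
three strong covariates: troponin rises with age, is higher in men than in
women at every age, and is associated with declining renal function.
`tnref` implements the full analysis pipeline for deriving age-, sex-, and
renal-function-stratified URLs from a population cohort, together with a
calibrated synthetic cohort generator so every estimator can be validated
against known ground truth.

## The statistical core

### Left-censoring at the reporting limit

The assay reports values below 3 ng/L as "< 3 ng/L"; `apply_detection_floor()`
substitutes the limit itself, so the analysed sample is left-censored with a
point mass at 3.  Medians of young female strata sit exactly on this floor.
All downstream statistics operate on floored values.

### Percentile point estimates

`percentile_point()` is the Hyndman–Fan type-7 quantile (linear
interpolation between order statistics), the default of both R and NumPy:
with `h = (n-1)p/100`, the estimate interpolates between `x_(⌊h⌋+1)` and
`x_(⌊h⌋+2)`.

### Exact order-statistic confidence intervals

For the CI the pipeline deliberately does *not* interpolate.  With
`B ~ Binomial(n, p/100)`, the interval `[x_(j), x_(k)]` covers the true
p-th quantile with probability `P(j ≤ B ≤ k−1)`, exactly and free of any
distributional assumption (under continuity).  `exact_quantile_ci()`
searches all pairs `1 ≤ j < k ≤ n` and returns the pair of **minimal width
k − j** among those whose coverage reaches the nominal level, breaking ties
by maximal coverage, then by smallest `j`.  If no pair attains the level
(e.g. `n = 1`, or the 99th percentile below `n ≈ 299` at 95%, since the
widest pair's coverage is `1 − 0.99^n − 0.01^n`), the CI is reported
unavailable rather than approximated.

Two documented asymmetries follow:

* the point estimate interpolates while the CI does not, so for extreme
  percentiles at small `n` the point can fall outside its own CI — this is
  logged, not raised;
* the exact method also admits symmetric-tail constructions; minimal width
  is this package's documented default, since the analysis the package
  reproduces does not pin the variant down.

Coverage statements are exact only for continuous data; the simulation
tests therefore validate coverage on strata whose 99th percentile is far
above the censoring floor.

### CKD-EPI eGFR

`ckd_epi_egfr()` implements the 2009 creatinine equation,
`141·min(Scr/κ,1)^α·max(Scr/κ,1)^−1.209·0.993^age·1.018[female]` with
κ = 0.7/0.9 and α = −0.329/−0.411 (female/male), Scr converted from µmol/L
by division by 88.4.  The race coefficient (1.159) is available behind a
flag but off by default: the emulated cohort is described as predominantly
white, and the source analysis gives no indication it was applied.

### Exclusion cascade

`apply_exclusions()` applies three fixed stages: (1) prevalent cardiac
disease or angina; (2) NT-proBNP above an age-dependent limit (125 ng/L
below 75 years, 450 ng/L at or above — the published rule's "< 5 years" is
an evident typo for "< 75 years") or HbA1c > 42 mmol/mol; (3) eGFR below
60 mL/min/1.73 m² (90 for the stricter sensitivity analysis).  Stage-2
survivors form *cohort 2* (used for the renal analyses), stage-3 survivors
*cohort 1* (used for the age/sex reference table).  All comparisons are
strict, mirroring the printed inequality signs; age exactly 75 uses the
450 ng/L limit.  The per-stage counts form an audit trail
(`filter_report`).

### Stratified tables, bins, and the minimum-group-size rule

Printed integer bin labels ("41–50", "91–120", …) are mapped to contiguous
half-open real intervals `(lo, hi]`, the lowest bin closed at its lower
edge, so real-valued ages and creatinines bin without gaps: age 40 is in
"20-40", age 40.5 in "41-50", eGFR 90.5 in "91-120".  Whether the original
analysis put age exactly 40 in the lower or upper group is not derivable
from the published tables; the convention here is documented, not claimed.
Out-of-range values are reported in an `"unbinned"` row, never dropped, so
per-sex counts always sum to the cohort size.

Following reference-interval guidance, the 99th percentile is only
tabulated in creatinine/eGFR strata with at least 300 subjects (`min_n`);
the age table reports it for all strata because the published age table
itself does (n = 196 in the youngest female group) — the rule as practised
rather than the rule as stated.  The sparse upper creatinine bins can be
merged ("151-250") via `merge_upper` to reproduce the published layout.

### Floating curves and the surface

`floating_stat_curve()` recomputes a statistic in a plain closed
rectangular window sliding along a covariate axis: age in 1-year steps with
a ±5-year window, creatinine in 10 µmol/L steps with ±15, eGFR in
3 mL/min/1.73 m² steps with ±10.  The extreme-percentile band
(`percentile_band()`, defaults 97th–99.4th) uses its own ±10 window, as in
the published figure captions — the ±5 and ±10 choices are both honoured
and separately configurable.  `floating_surface()` evaluates the 99th
percentile in rectangular (age × creatinine) windows (±5 years, ±15 µmol/L;
the original surface windows are unstated, so the surface is validated by
structural properties rather than against the figure).

`min_window_n` (default 20) masks grid nodes with fewer contributing
subjects.  No published value exists for this; 20 suppresses wild extreme
percentile estimates in sparse windows while leaving the age range
essentially fully covered at cohort sizes of a few thousand.  Masked nodes
carry their count, so the masking is auditable.

### Association tests

`spearman_cor()` computes rho as the Pearson correlation of mid-ranks and a
two-sided p-value from the t-approximation on n − 2 degrees of freedom
(exact permutation enumeration available for n ≤ 10).
`sex_difference_test()` is a two-sided Mann–Whitney U with normal
approximation and tie correction and no continuity correction, so identical
groups give p = 1 exactly.  The published per-stratum sex comparison never
names its test; Mann–Whitney is this package's documented assumption,
consistent with the otherwise nonparametric analysis.  Measured against
full permutation enumeration, the approximation is within ~0.05 at 8 + 8
subjects and should not be trusted below that.

## The synthetic cohort generator

No individual-level data from the original cohort are public, so
`generate_cohort()` draws cohorts with the *structure* the analysis
assumes, calibrated to the published summary tables:

* **hs-cTnT** is log-normal given age and sex.  Per-sex knots at the
  age-group midpoints (30, 45.5, 55.5, 65.5, 75.5) carry `(mu, sigma)`;
  between knots both parameters interpolate linearly, beyond the outer
  knots they are constant.  Starting values were `mu = log(stratum median)`
  and `sigma = (log(stratum P99) − mu)/2.326`; `mu` was then refined by a
  damped fixed-point iteration (at n = 500,000) so that the *filtered*
  cardiac-healthy cohort reproduces the target stratum medians — the
  decade-wide age mixture and the cascade's mild within-bin age tilt
  otherwise leave bin medians a few percent below their knot values.  In
  the two youngest female strata the printed median equals the censoring
  floor, so the underlying median is unidentifiable; `mu = log(2.8)` (just
  below the floor) keeps the floored median at 3.0 with `sigma` set from
  the P99 alone.  Diseased subjects have troponin multiplied by 2.0 before
  flooring — large enough that leaving them in visibly distorts the upper
  percentiles, which is exactly what the cascade is for.
* **Ages** are uniform within the sampled age group.  The group weights and
  female fraction are *pre-filter* values calibrated so the post-cascade
  composition matches the published cohort-1 shares (49.4% female; group
  shares 0.076/0.357/0.265/0.193/0.109): the cascade removes the elderly
  disproportionately (per-group survival falls from 0.60 to 0.48), so the
  enrolment-stage weights are tilted old.
* **Creatinine** is truncated normal (at 30 µmol/L) with a +0.25 µmol/L/year
  age slope; female mean 66, sd 8 and male mean 85, sd 9 at age 50.  The
  means are chosen so both sexes have the same Scr/κ ratio, i.e. the eGFR
  distributions of healthy men and women coincide, as the CKD-EPI constants
  intend and the published cohort medians (eGFR 87.1, creatinine 77)
  reflect.  The spreads are the designated calibration knob for the pooled
  eGFR–troponin correlation: with these values the generated cohort-2 gives
  Spearman rho(eGFR, TnT) ≈ −0.32 and per-sex rho(creatinine, TnT) ≈
  0.12–0.18, matching the published values.  eGFR is always *derived* from
  creatinine/age/sex, never sampled.
* **NT-proBNP** is a log-normal base component whose log-mean rises
  0.02/year, plus an elevated component (fraction 0.08) emulating occult
  heart failure; **HbA1c** is normal (34.4 ± 3) plus an elevated component
  (fraction 0.105) emulating diabetes.  Together these make ~18% of
  generated subjects fail the biomarker stage, reproducing the published
  cascade counts (cardiac 2460 → here 2459; biomarker 1786 → 1783;
  cohort 2 5636 → 5640).  The renal stage removes fewer subjects than in
  the real cohort (~80 vs 208): a heavier renal tail would break the eGFR
  sex parity above, and no downstream result depends on it.
* **Randomness**: one global seed drives deterministic per-variable
  sub-streams, so cohorts are reproducible and two parameter sets differing
  in a single model share everything upstream of it.

`true_stratum_quantile()` computes ground-truth stratum quantiles of the
floored age-mixture by numerically integrating the mixture CDF over the
age density (midpoint rule, 20,000 points) and inverting by root-finding
to 1e-6 ng/L, including the diseased component at its mixture weight.  It
is validated against a 2×10⁶-draw Monte-Carlo oracle and anchors the
estimator-recovery tests: over repeated cohorts, exact 95% CIs for the
stratum 99th percentile contain the true value at at least their nominal
rate.

### What a green test does and does not establish

The generator emulates marginal stratum medians/99th percentiles, the
cascade flow, and the pooled rank correlations.  It does **not** emulate:
heavier-than-log-normal troponin tails (the real P99 confidence intervals
are wider and more skewed than log-normal strata produce), any direct
creatinine→troponin effect (none was found in the source analysis — the
surface's creatinine-flatness is a modelling *input* here, not a finding),
assay imprecision near the limit, repeated measures, or race structure.
Green calibration tests therefore establish that the *pipeline recovers
what the generator put in* at the published operating points — not that
the published values are externally correct.

### Numerical and degenerate-input choices

* Percentile levels are validated to (0, 100) for CIs; `p = 0/100` are
  allowed for point estimates only.
* Empty cohorts filter to empty cohorts with an all-zero report; empty
  strata appear with `n = 0` and `NA` statistics.
* `sigma = 0` knots are honoured exactly (point-mass troponin), which the
  degenerate tests exploit.
* Ties: mid-ranks for Spearman, tie-corrected variance for Mann–Whitney,
  and CI coverage claims restricted to continuous regions.
* Cohort CSVs serialize doubles with `%.17g`, so statistics recomputed
  from a re-read file reproduce the in-memory values bit for bit.

### Known limitations

* The within-stratum log-normal form is an assumption of this generator;
  the source analysis makes no distributional claim.
* At the default cohort size the male 71–80 stratum holds ≈330 subjects
  and its sample median has a seed-to-seed sd of ≈0.37 ng/L; a ±0.5 ng/L
  calibration band is therefore ~1.35σ and an individual seed can
  legitimately land outside it even though the generator is centred (mean
  8.26 over 50 seeds against a target of 8.3).
* The pooled age–troponin correlation of the calibrated world centres at
  ≈0.39 against the published 0.42 (within the ±0.05 acceptance band): a
  log-normal tail calibrated to the printed P99 implies more within-age
  spread than the real data appear to have, which dilutes rank
  correlation.  Raising it further would require breaking the P99
  calibration.
* Mann–Whitney p-values use the normal approximation; do not use them for
  strata below ~10 subjects per group.
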