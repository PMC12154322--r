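---
title: "Methods: sigmoid trajectories, CI scoring and age-banded risk zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sigmoid trajectories, CI scoring and age-banded risk zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrisk)
```

## The model

`adrisk` rests on a simple axiom: Alzheimer's-related pathology
accumulates gradually and non-linearly — subtle at first, accelerating in
midlife, plateauing late.  Each core biomarker (CSF amyloid-beta 42,
amyloid PET, CSF Tau, MRI FDG-PET) is therefore given a logistic age
trajectory

$$S(x) = \frac{L}{1 + e^{k(x - x_0)}},$$

bounded in $(0, L)$ with its steepest change at $x_0$.  We keep the
formula in this exact form and let the *sign of $k$* select the
direction: $k > 0$ gives a decreasing curve (amyloid-beta 42, which falls
as plaques sequester it), $k < 0$ an increasing one (PET, Tau, FDG-PET).
We deliberately do not rewrite the exponent to make $k > 0$ mean
"increasing": one verbatim formula with a documented sign convention is
less error-prone than two dialects of it.

A second interpretive choice: when the curve is used for *trajectory
simulation*, $x$ is age and $x_0$ an age (the default parameter sets put
it near the midpoint of the modeled lifespan).  The same functional form
could instead standardise a biomarker column around its mean; both
readings are accommodated because $x_0$ is free configuration, and the
package takes no position beyond its defaults.

The closed-form derivative $S'(x) = -k\,S(x)\,(1 - S(x)/L)$ is exposed
(`sigmoid_derivative()`) for locating the steepest segment of a
trajectory; tests hold it to a central finite difference at relative
error below $10^{-6}$.

### The cognitive-impairment score

Risk is summarised by a composite cognitive-impairment score

$$CI(A) = \alpha e^{\beta A} + \sum_{i=1}^4 w_i\,B_i,$$

an exponential ageing term plus a weighted linear combination of
biomarker contributions.  In the *model-based* form (`ci_from_age()`)
each $B_i = k_i e^{-m_i A}$ is an exponential trajectory; negative $m_i$
yields the rising trajectories.  In the *observation-based* form
(`ci_from_observation()`) the measured value replaces $B_i$, making CI
linear in each biomarker at fixed age.  The two forms coincide exactly
when measurements sit on their modeled trajectories — a consistency
identity the tests assert.  The protective role of amyloid-beta 42 is
encoded as $w_1 < 0$: all four terms keep the same written form, and
direction lives entirely in the signs of $w_i$ and $m_i$.

### Age-banded zones

A CI score is zoned against the age band covering the instance:
Safe when $CI \le \gamma$, Mild Risk when $\gamma < CI \le \delta$,
Unsafe when $CI > \delta$.  The default registry has four decade bands,
(30, 40] through (60, 70], with $(\gamma, \delta)$ = (3, 6), (4, 7),
(5, 8), (6, 9).  Two boundary conventions are fixed once and used
everywhere:

* **Bands are left-open, `(lower, upper]`.**  Age 40 belongs to the
  30–40 band.  This is the only convention consistent with a worked
  boundary case in the bundled example (the age-40 instance with CI 3.37
  is Mild Risk, which requires the strict $\gamma = 3$ cut).
  A side effect is that age 30 — the lower edge of the lowest band — is
  covered by no band and classification there is an error; the default
  synthetic pool therefore spans ages 31–60.
* **Both CI cut-points belong to the less severe zone** ($\le$ in the
  zone definitions): $CI = \gamma$ is Safe, $CI = \delta$ is Mild Risk.

Each band also carries display edges (Safe floor, Unsafe ceiling, e.g.
0 and 10 for the 30–40 band).  These are plausibility annotations only:
classification uses $\gamma$ and $\delta$ alone, and a CI below the Safe
floor still classifies Safe, with a warning.  The optional four-level
relabeling (`classify_ci_four()`) splits Unsafe at the display ceiling
into High Risk versus MCI for lifespan plots; it is not the default
output because only the two cut-points are formally defined.

### Threshold templates and the two unit scales

Independently of CI zoning, single biomarker values can be flagged
Normal / Low Risk / High Risk against per-age-group templates
(`default_threshold_tables()`, groups 30–40, 40–50 and 55–65).  Three
points deserve emphasis:

* The template age groups are the templates' own and are looked up
  independently of the CI band registry — the 55–65 group aligns with no
  CI band, and we do not force the two systems to agree.
* Amyloid-beta 42's ranges run opposite to the others (higher is safer);
  a per-row direction flag encodes this rather than reordering the
  ranges.
* Ranges are scanned along the risk direction with the shared boundary
  belonging to the riskier range (a value exactly at the Normal/Low-Risk
  edge flags Low Risk).  Values beyond the risky extreme remain
  High Risk; beyond the safe extreme they flag Out-of-Range rather than
  silently "Normal".

The templates are on a sigmoid-scaled unit system (values roughly 0–22).
Clinical laboratory cut-offs (amyloid-beta 42 480/600–800 pg/mL, Tau
300/450 pg/mL by age, Centiloid 0–100) ship separately in
`clinical_reference_ranges()` and are never mixed with the template
scale: no published conversion exists between the two, and pretending
one does would be worse than keeping them apart.  Cohort tables store
values verbatim on whichever scale they arrive in; unit harmonisation is
the configuration's responsibility.  (The bundled example cohort has
pg/mL amyloid and Tau values next to template-scale PET and FDG-PET
values, which is exactly how such data arrive in practice.)

## The synthetic cohort generator

`generate_cohort()` emulates the cross-sectional data the screening
workflow expects: per-age draws around each biomarker's sigmoid
trajectory, with

* additive Gaussian noise (default sd 0.5 on the template scale, floored
  at 0) — the simplest noise model consistent with non-negative
  measurements.  Noise is unspecified in the source material for such
  generators; this is our choice, and it is configurable per run;
* a Tau–amyloid coupling: CSF Tau receives `tau_coupling` (default
  −0.5) times the amyloid-beta 42 residual from its mean trajectory, so
  that amyloid-low instances are Tau-high — reproducing the inverse
  relationship seen in scatter plots of real cohorts;
* one root seed with per-biomarker child streams derived
  deterministically from it, so results do not depend on the order in
  which columns are generated, and equal seeds give byte-identical CSVs.

The default pool is 150 instances (5 per age, ages 31–60), matching the
scale of pool a screening study of younger adults would assemble.  The
default curve parameters are labelled *illustrative*: they were chosen
once so the four curves have the right qualitative shapes and sit inside
the template threshold ranges at representative ages, and they are
configuration, not constants.

What the generator does **not** emulate: longitudinal within-person
dynamics (every record is an independent cross-sectional draw), cohort
effects, assay- or scanner-specific measurement offsets, covariation
beyond the single Tau–amyloid coupling, and genetic or lifestyle
modifiers.  Passing tests on synthetic pools therefore demonstrates that
the pipeline computes its model faithfully — not that the model's
thresholds are clinically calibrated.

## Numerical choices

* **Sigmoid overflow.**  `exp()` saturation is relied on explicitly: for
  arguments beyond the double range the curve returns its exact
  asymptote (0 or $L$) instead of NaN.
* **Duplicate aggregation.**  Records are duplicates when their ages
  round to the same integer (age is the instance identifier and cohort
  tables print integer ages); the collapsed record takes the arithmetic
  mean of each column, missing cells excluded.  Rounding keys make the
  operation idempotent.
* **Imputation.**  Whole missing ages and isolated missing cells are
  filled by the same sigmoid simulation path — one mechanism, one code
  path — noiseless by default so fills are reproducible.
* **Exponential fitting.**  `fit_trajectory_params()` is a log-linear
  least-squares fit, exact (to solver tolerance $10^{-9}$) on clean
  exponentials; it requires strictly positive values and at least two
  distinct ages.
* **Calibration.**  The CI weights are under-determined by small
  calibration sets (a handful of records cannot pin $\alpha$, $\beta$
  and four weights), so `calibrate_ci_params()` profiles $\beta$ over a
  fixed grid (0 to 0.1, step 0.001) and solves a ridge system (default
  penalty $10^{-3}$) for the linear coefficients at each grid point,
  taking the lowest-loss (ties: lowest-$\beta$) candidate.  This is
  deterministic and order-invariant.  A negative fitted $\alpha$ is
  reset to 0 and the weights refit, keeping the ageing scale
  non-negative.  Calibrated parameters carry unit trajectory terms: they
  are for observation-based scoring, not for extrapolating trajectories.
* **Intervention window.**  `intervention_window()` scans the model CI
  trajectory at a coarse step (default 0.25 years), then refines each
  zone crossing by bisection to $10^{-6}$ years.  Crossings can come
  from CI growth or from cut-point jumps at band edges; bisection on the
  zone predicate handles both.  When the trajectory never turns Unsafe
  the window's upper end falls back to the scanned range end.
* **Safe-biomarker bounds.**  The Safe inequality is linear in any one
  biomarker at fixed age, so `safe_biomarker_bounds()` solves it in
  closed form and intersects with $[0, \infty)$; a brute-force grid
  oracle verifies the bound in the tests.

## Problem sizes

The shipped test-suite and reproduction script run at deliberately
modest sizes — 150-instance pools, 10,000-draw property sweeps,
dense-grid oracles at $10^{-4}$ years over a 40-year span — which
complete in seconds while still exercising every code path at the scale
the workflow targets.

## Limitations

The package computes the model it documents; it does not validate that
model clinically.  Cut-points, threshold templates and default
parameters are illustrative or literature-derived, not fitted to
longitudinal outcomes; the CI score has no uncertainty quantification;
and the discrete zones discard within-zone gradation.  Any scientific
use requires explicitly configured, externally validated parameters.
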