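---
title: "Modelling amino-acid effects on insulin kinetics during a mixed-meal tolerance test"
author: "insukin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amino-acid effects on insulin kinetics during a mixed-meal tolerance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insukin)
```

## The modelling problem

During a mixed-meal tolerance test (MMTT), plasma glucose, insulin and
amino-acid (AA, typically the branched-chain aggregate) concentrations are
sampled on a fixed schedule: two fasting samples at −10 and −1 min, then
10, 20, 30, 60, 90, 120 and 180 min after meal start. Glucose is the main
driver of insulin secretion, but amino acids also stimulate (or, in some
metabolic states, fail to stimulate) the beta cell. The question the
package addresses is whether a subject's insulin curve carries a
quantifiable AA contribution, summarised by a single transfer coefficient —
the *beta-cell AA sensitivity*, `k_aa` — which can be positive, negative,
or statistically indistinguishable from zero.

The package treats glucose `G(t)` and amino acids `AA(t)` as *known
forcing inputs* (piecewise-linear through the samples, flat outside the
sampled range) and models only the insulin concentration `I(t)`, in
uU/ml. Five candidate structures are implemented:

* **M1** — `dI/dt = k_gl G + k_aa AA − k_i I + BR_I`: linear fluxes from
  glucose and AAs, first-order disappearance.
* **M2** — adds a glucose rate-of-change term `k_gl2 dG/dt`.
* **M3** — replaces the linear glucose flux by a power law
  `k_gl1 G^k_gl2`.
* **M4** — M1 with a *time-varying* AA sensitivity `k_aa(t)`.
* **M5** — glucose acts through a remote compartment `G_rem` (suprabasal,
  empty at basal) instead of plasma glucose directly.

Two quantities are fixed rather than estimated: the fractional insulin
disappearance rate `k_i = 0.14 /min` (a population value for insulin
clearance from plasma), and the basal appearance rate `BR_I`, which is
*derived* from the fasting steady state — at basal, all fluxes must cancel,
which pins `BR_I` as a function of the other parameters and the basal
values `G_b`, `I_b`, `AA_b` (means of the pre-meal samples). This closure
is what makes every model reproduce `I ≡ I_b` exactly under constant-basal
inputs, a property the test suite checks to 1e−6 uU/ml for all five
models. For M4 the closure uses the *basal node* of `k_aa(t)`; once
`k_aa(t)` departs from that value, constant-basal inputs legitimately move
insulin off `I_b` — that is model structure, not a defect.

## Conventions the data do not dictate

Several choices are not forced by the data or the model family; the
package fixes them once:

* **Basal values** are the arithmetic mean of all pre-meal samples
  (−10 and −1 min on the standard schedule).
* **Forcing interpolation** is piecewise-linear with flat extrapolation;
  any smoother would inject invented curvature between 9 samples.
* **M2's `dG/dt`** is the derivative of that interpolant: piecewise
  constant, left-continuous at the knots.
* **M4's `k_aa(t)`** is piecewise-linear through 3 free node values at
  0, 60 and 180 min (configurable). With only 9 data points, a
  per-sample parameterisation would make the small-sample information
  criterion undefined (`n − p − 1 ≤ 0`); three nodes keep the model
  comparable with the others.
* **M5's remote-compartment elimination**: the model as implemented uses
  `−k_gl·G_rem` by default (`m5_elimination = "as_printed"`), with a
  switch to `−k_glrem·G_rem` (`"k_glrem"`), the reading under which
  `k_glrem` is literally "the elimination rate from the remote
  compartment". The two readings genuinely differ and the ambiguity is
  surfaced as an option rather than silently resolved.
* **M3's exponentiation** acts on the numeric value of glucose in mg/dl,
  unnormalised, so `k_gl1`'s units depend on `k_gl2` and are reported as
  model-dependent.
* **Units** are fixed package-wide (mg/dl, uU/ml, umol/l, min); there is
  no conversion layer.

## Estimation

`fit_model()` minimises the unweighted sum of squared insulin residuals
over *all* sampling times (pre-meal predictions equal `I_b` by
construction, so those residuals are data-only). The local solver is a
bound-constrained Levenberg–Marquardt method; positivity is enforced for
the glucose-side parameters (`k_gl`-type, lower bound 0) while `k_aa`
remains sign-free. Conceptually infinite bounds are mapped to a numerical
box of ±1e3; a solution touching the box raises a warning because the true
optimum may lie outside the searched region.

To approximate the global optimum the solver is launched from a Cartesian
multistart grid: by default 10 log-spaced values in [1e−4, 1] per positive
parameter and 10 linearly spaced values in [−0.1, 0.1] per sign-free
parameter, i.e. `10^npar` starts. The grid brackets every parameter
magnitude this model family produces on MMTT-scale data by at least an
order of magnitude. The lowest-RSS start that meets the convergence
tolerances wins; starts that exhaust the iteration budget are kept as
*flagged* fallbacks (the model-selection surface of M3 in particular has a
long curved ridge in (`k_gl1`, `k_gl2`) along which step-tolerance
convergence is slow).

Numerical settings worth knowing about:

* objective/step tolerances 1e−20 and 1e−12 (deliberately stringent; in
  practice termination is by step tolerance or the tolerance-floor codes);
* the solver's internal finite-difference step is set to ~1e−4 relative
  (`epsfcn = 1e-8`). The default machine-epsilon step would sit *below*
  the ODE integration noise (relative tolerance 1e−8), making the
  Jacobian noise-dominated and stalling fits about 1% from the optimum —
  this was diagnosed against the noiseless-recovery oracle;
* integration uses a stiff-capable solver (lsoda) with compiled
  right-hand sides and C-level forcing interpolation; relative/absolute
  tolerances 1e−8/1e−10, at which halving the tolerances moves predicted
  insulin by less than 1e−6 relative;
* a failed integration during an exploratory step (e.g. overflow of
  `G^k_gl2`) returns large finite residuals, so the step is rejected and
  the search retreats instead of aborting the start.

Uncertainty is asymptotic: covariance `s²(JᵀJ)⁻¹` with
`s² = RSS/(n − p)` and `J` the residual Jacobian at the optimum (forward
differences, relative step 1e−6 with floor 1e−8). CV% is `100·SD/|estimate|`,
and 95% confidence intervals use the Student-t quantile with `n − p`
degrees of freedom — with n = 9 the t quantile is materially wider than
the normal one, which is the correct small-sample behaviour. A perfect
fit yields CV% = 0; a numerically singular `JᵀJ` is reported as
non-identifiability with infinite CV% rather than a crash. Note the
degenerate extreme: a completely flat insulin curve with basal inputs is
fitted exactly by *every* parameter vector (the steady-state closure
absorbs them all), so the fit carries a degenerate-fit warning and the
parameter values are meaningless by design.

## Model comparison

`aicc()` implements the Gaussian-error least-squares form

```
AICc = n ln(RSS/n) + 2p + 2p(p+1)/(n − p − 1)
```

with `p` counting only the estimated kinetic parameters (`k_i` is fixed,
`BR_I` derived; no extra term for the error variance). Whether the error
variance is counted shifts every model's AICc by the same amount at equal
`n`, so *differences* — and hence `relative_likelihood()`
(`exp(ΔAICc/2)`) and rankings — are unaffected; absolute AICc values are
convention-dependent and should not be compared across software.
`compare_models()` ranks fits of the same dataset with deterministic
tie-breaking by model id, and `mean_aicc()` provides the mean-over-datasets
aggregation used when one criterion value is wanted across two average
curves. With the published AICc values 20.53 (M1), 25.36 (M5), 25.86 (M2)
and 27.07 (M3), the relative likelihoods of the best model over the others
evaluate to 11.19, 14.37 and 26.31 — matching the published 11.19, 14.39
and 26.35 to within the two-decimal rounding of the printed inputs.

## Synthetic data: what it emulates, and what it does not

No individual-level MMTT dataset is shipped or downloadable, so the
`synthetic_data` functions generate the package's own study material.
`make_template()` produces mean ± SD curves on the standard schedule with
the qualitative MMTT shape: a basal plateau, a single postprandial peak
and a partial return toward basal by 180 min. The suprabasal excursion is
a gamma-like bump `A (t/tp)^a exp(a(1 − t/tp))` whose exponent is solved
in closed form from the requested residual fraction at 180 min. Two
stylised defaults are provided: `cnt_like` (basal glucose 90 mg/dl, early
sharp peak, ~90% return, brisk insulin response, relative SDs 8/22/10%
for glucose/insulin/AA) and `t2d_like` (basal 145 mg/dl, larger and later
excursion, ~55% return, blunted insulin response). These values were
chosen once as physiologically plausible for normal-glucose-tolerance and
type-2-diabetes groups; **they are package inventions for testing and are
not digitised from any published figure**, so quantitative agreement with
any particular study is neither expected nor claimed.

`make_known_parameter_dataset()` closes the loop: it builds glucose/AA
inputs from a template, forward-simulates insulin under chosen parameters,
samples the schedule and applies multiplicative Gaussian noise to insulin
only (inputs are treated as exactly known, matching the estimator's error
model). Noise deviates are truncated at ±3 CV so samples stay positive.
Passing recovery tests on these data shows the estimation machinery is
correct *given the model and error assumptions*; it does not validate the
model against real physiology, where inputs are noisy, errors are
correlated, and incretin and non-BCAA amino-acid effects are absorbed
into the residuals.

## Virtual populations

`generate_population()` draws subjects around a mean ± SD template under
the two constraints of the published generation recipe: every sample must
lie within the 95% band (±1.96 SD) of its template point, and every
consecutive-sample step must have the same sign as the template's step
(no constraint where the template is flat). Sampling is chronological and
the sign constraint is applied against the *subject's own* previously
accepted sample — the recipe is inherently sequential, and conditioning on
the subject's path keeps each curve internally consistent. Curves are
generated independently (no cross-correlation is described by the recipe),
by rejection sampling with a per-sample budget of 10,000; with SDs
proportional to the means (as in the shipped templates) a rising template
segment always has feasible continuation, so budget exhaustion indicates a
pathological template rather than bad luck.

Two distributional side effects of the recipe are worth knowing. The
truncation and sign conditioning *shrink* per-point dispersion (sample SDs
run at roughly 0.6–0.9 of the template SD), and the sequential sign
constraint *biases* post-meal per-point means — most strongly near the
curve peak where the required step direction flips, by up to about one
template SD in the shipped templates. Pre-meal plateau points carry no
sign constraint and remain unbiased. A population generated this way is
therefore a constrained emulation of the template's shape variability,
not an unbiased sampler of Normal(mean, SD) — which is also true of the
original recipe.

## Population statistics

`classify_kaa()` partitions estimates by their individual 95% CI: positive
(CI above 0), negative (CI below 0), negligible (CI containing 0,
endpoints inclusive). `summarize_population()` reports group means/SDs,
class percentages and the Pearson correlation between `k_gl` and `k_aa`.
`compare_groups()` uses Welch (unequal-variance) t-tests — the safer
default when group variances differ, as they visibly do between
normal-tolerance-like and diabetes-like populations — and a chi-square
test of independence without continuity correction on the 2×3 class
table, dropping classes empty in both groups. The log-transform rule for
skewed distributions is operationalised as: natural-log-transform `k_gl`
when its pooled sample skewness exceeds 1 and all values are positive;
the sign-free `k_aa` is never transformed. `regress_interaction()` fits
`k_aa ~ k_gl * group` by ordinary least squares to test whether the
`k_gl`–`k_aa` relationship differs between groups.

## Problem sizes used by the shipped studies

The test suite's stochastic studies use: 200 replicates at 5%
insulin noise for CI calibration and bias of the M1 parameters (multistart
reduced to 2 starts per parameter — M1's least-squares surface is
linear-in-parameters, so a dense grid adds nothing); 100 replicates for
the model-comparison sanity study over {M1, M2, M3, M5}; 1000 subjects
for the virtual-population moment checks and 100 for the constraint
checks. These sizes give Monte-Carlo standard errors comfortably inside
the asserted bands (e.g. ±2.2% on a 95% coverage estimate from 200
replicates).

## Known limitations

* Structural identifiability is checked numerically (singular `JᵀJ` at
  the optimum, CV% explosions), not symbolically; M4 in particular is
  known to be only locally identifiable and its node structure is a
  modelling choice.
* The asymptotic CIs rely on local linearisation and homoscedastic
  errors; the shipped noise model is multiplicative, so coverage is
  approximate (the calibration study bounds it empirically).
* Insulin secretion and clearance are not separated; `k_aa` summarises
  the net effect on insulin kinetics.
* Incretin effects, individual amino-acid species and C-peptide are out
  of scope; a single aggregate AA signal is modelled.
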