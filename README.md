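# insukin

Modelling the effect of amino acids on plasma insulin kinetics during a
mixed-meal tolerance test (MMTT).

## The problem

During an MMTT, blood is sampled at −10, −1, 10, 20, 30, 60, 90, 120 and
180 min (meal at t = 0) for plasma glucose (mg/dl), insulin (uU/ml) and
amino acids (AA, typically the branched-chain aggregate, umol/l). Glucose
is the dominant driver of insulin secretion, but amino acids also act on
the beta cell, and their contribution differs between people with normal
glucose tolerance and people with type 2 diabetes. `insukin` is for
modellers and metabolism researchers who want to quantify that
contribution in individual subjects from standard MMTT curves.

The package treats G(t) and AA(t) as known forcing inputs and fits
candidate compartmental models of I(t). The central model (M1) is a single
linear ODE:

    dI/dt = k_GL * G(t) + k_AA * AA(t) − k_I * I(t) + BR_I,    I(0) = I_b

with k_I fixed at 0.14 /min and the basal appearance rate BR_I closed from
the fasting steady state (BR_I = −k_GL·G_b − k_AA·AA_b + k_I·I_b). The
estimated `k_aa` — the *beta-cell AA sensitivity*, uU/ml per (umol/l·min),
deliberately sign-free — is the quantity of interest: its individual 95%
CI classifies a subject as AA-**positive**, AA-**negative** or
**negligible** (CI crossing zero). Four structural alternatives (glucose
derivative term, glucose power law, time-varying k_AA(t), remote glucose
compartment) are implemented for comparison by small-sample corrected
Akaike criterion (AICc) and relative likelihood exp(ΔAICc/2).

Around the core sit: multistart bound-constrained least squares with
asymptotic CV%/95% CI; constrained virtual-population generation from
mean ± SD template curves (95% truncation + trend-sign constraints); a
synthetic MMTT generator with known ground truth; and population-level
statistics (class percentages, Pearson correlation, Welch t, chi-square,
pooled interaction regression).

## Worked example

Fit M1 to the shipped synthetic fixture (generated by the package's own
generator with k_GL = 0.0974, k_AA = 0.0247; see
`inst/extdata/*.truth.json`):

```r
library(insukin)
fx <- system.file("extdata", "synthetic_m1_cnt_noiseless.csv", package = "insukin")
ds <- read_mmtt_csv(fx, label = "cnt_synth")
fit <- fit_model("M1", ds, ms = multistart_config(n_per_param = 3))
print(fit)
#> <model_fit> M1 on 'cnt_synth': RSS = 4.26101e-16 (uU/ml)^2, AICc = -332.3017
#>   9/9 multistart attempts converged (best: #8)
#>      estimate cv_percent ci95_low ci95_high
#> k_gl   0.0974  3.619e-08   0.0974    0.0974
#> k_aa   0.0247  3.262e-08   0.0247    0.0247
```

The generating parameters are recovered to machine precision on noiseless
data (RSS ~ 1e−16); `cv_percent` is the asymptotic coefficient of
variation of each estimate and `ci95_*` the Student-t 95% interval
(7 degrees of freedom here: 9 samples, 2 parameters). Because the
recovered `k_aa` CI lies entirely above zero, `classify_kaa()` labels this
subject AA-positive.

Model comparison works from fitted AICc values; with the published AICc
table for the four globally identifiable models (M1 20.53, M5 25.36,
M2 25.86, M3 27.07):

```r
relative_likelihood(20.53, c(25.36, 25.86, 27.07))
#> [1] 11.19 14.37 26.31
```

i.e. the single-ODE model M1 is 11–26 times more likely than its
competitors, matching the published 11.19 / 14.39 / 26.35 to the rounding
of the printed inputs.

A command-line interface covers the full pipeline
(`exec/insukin --help`): `fit`, `compare`, `simulate`, `synth`, `vpop`,
`fitpop`, `analyze`.

## Documentation

The methods vignette (`vignettes/insulin-aa-kinetics.Rmd`) documents the
model family and its assumptions, the steady-state closures, every
numerical choice (multistart grids, tolerances, finite-difference steps,
failure handling), what the synthetic-data generator does and does not
emulate, and the known limitations.
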