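---
title: "Modelling plant trace-metal bioindication with a full-factorial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plant trace-metal bioindication with a full-factorial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytodoe)
```

## The scientific problem

A *bioindicator* plant accumulates an element in its shoots in proportion to
the element's concentration in the growing substrate, so that a chemical
analysis of the plant reads out the soil level. Whether a species really
behaves this way is hard to establish in the field, because soils carry
several metals at once and their uptakes interfere. phytodoe implements the
design-of-experiment (DoE) route around that problem: grow the plant
hydroponically under a *full factorial* of medium concentrations, fit a
quadratic response-surface model per shoot metal, and decide bioindication
ability from which model terms are statistically significant.

The emulated study varies Cd, Pb and Cr in half-strength Hoagland's solution
at three levels each — countryside, urban and heavily polluted soil
concentrations — while Cu (0.5 uM) and Zn (2 uM) stay at their nutrient
levels. Five shoot metals (Cd, Cr, Pb, Cu, Zn) are the responses.

## The model

Factor concentrations are coded so each factor's low level is $-1$ and its
high level $+1$. For every response $y$ (shoot concentration, mg/kg) the
ten-term quadratic

$$y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \sum_i b_{ii} x_i^2 + \varepsilon$$

is fitted by ordinary least squares: linear effects $b_i$, binary
interactions $b_{ij}$ (how two metals influence each other's uptake), and
squared effects $b_{ii}$ (curvature, estimable because three levels are
used). Each coefficient gets a standard error from the residual variance and
$(X^\top X)^{-1}$, a two-sided Student-$t$ p-value, and the conventional
stars. At any coded point $x_0$ the mean response is $\hat y = x_0^\top b$
with standard error $s\sqrt{x_0^\top (X^\top X)^{-1} x_0}$; the *95%
confidence semiamplitude* is that standard error times
$t_{0.975,\mathrm{df}}$, and a prediction is "significantly different from
zero" where $|\hat y|$ exceeds it.

### Numerical choices

* The least-squares solve uses a QR decomposition; a rank-deficient design
  raises an error naming the aliased columns (e.g. squared terms in a
  two-level design) rather than silently pseudo-inverting.
* Coding is implemented in the endpoint-exact form
  $2(v - \mathrm{low})/(\mathrm{high} - \mathrm{low}) - 1$, so the design
  extremes are exactly $\pm 1$ in floating point.
* Coefficients are reported in coded units only; p-values carry no
  multiple-testing correction across the ten terms, matching standard DoE
  reporting practice.
* The fit uses all replicate observations (81 rows, 71 residual df for the
  default study), so pot replicates contribute pure-error information to the
  residual variance; `use_run_means = TRUE` fits the 27 run means instead
  and gives identical point estimates on balanced data.

### Two conventions for the central level

The central (urban) concentrations are not the arithmetic midpoints of low
and high, so their true coded values are $-0.08$ (Cd), $-0.07$ (Pb) and
$-0.18$ (Cr) rather than 0. The design and every fit always use the true
coded values — anything else would misplace the actual concentrations. For
presentation, surfaces fix the non-axis factor at coded 0 and
`display_coded()` maps the central label to 0, which is the convention used
in published response plots. Both conventions are available; the true value
is the default everywhere a model is fitted.

## Bioindication verdicts

The verdict rules in `classify()` formalize the narrative reading of a
coefficient table, at significance level $\alpha = 0.05$:

1. A varied metal is a candidate only if its own linear term is significant
   and positive (more in the medium, more in the shoot).
2. Among candidates, significant terms involving any other metal are
   interference. No interference: `bioindicator`. Interfering estimates all
   smaller in magnitude than the own linear estimate
   (`interference_ratio = 1`): `bioindicator_minor_interference` — still a
   positive verdict. Anything larger: `not_bioindicator`.
3. A metal held constant in the medium can only pass if *no* term is
   significant — its uptake must ignore the varied metals entirely.

The `interference_ratio` default of 1 draws the line the worked reference
tables imply: a weak cross-interaction (|−0.58| < 0.87 for Cd) is tolerated,
a dominant one (|8.9| ≫ 1.6 for Pb) is not. The status enum keeps "clean"
and "minor-interference" bioindicators distinct instead of collapsing them,
because the distinction matters for field use. With the packaged reference
models the positive verdicts are exactly Cd and Cr; Pb, Cu and Zn fail.

## The synthetic-data generator

The raw 81-sample measurement table of the emulated study is not publicly
deposited, so `simulate_study()` regenerates data with the statistical
structure the analysis assumes: responses drawn from the reference
coefficient surfaces at the true coded design points, plus independent
homoscedastic Gaussian replicate noise. The generator and the fitting code
share one model-matrix construction, so the generative mean *is* the fitted
model's mean function.

Choices a user should know about:

* **Noise scale.** No residual variance is published, so the default
  per-metal sd is 10% of the magnitude of that metal's intercept (Cd 0.31,
  Cr 0.014, Pb 0.59, Cu 0.32, Zn 3.3 mg/kg) — a coefficient of variation
  typical of replicated pot experiments, at which refitting the simulated
  study typically reproduces the reference significance pattern. It is a
  first-class knob, not a constant.
* **Truncation.** Gaussian noise can produce negative concentrations at
  low-mean runs. `truncate_at_zero = FALSE` is the default so OLS stays
  exactly unbiased in inference studies; switch it on for realistic-looking
  demonstration data only.
* **Seeding.** One master seed; each response uses a deterministically
  derived substream, so adding or removing a response never changes
  another's draws.
* **What it does not emulate.** Plant biology beyond the quadratic mean
  surface: no biomass feedback, no heteroscedasticity, no between-pot
  covariance, no measurement-chain error unless the AAS forward model is
  layered on. Passing tests therefore demonstrate correctness of the
  statistical machinery under the stated model, not field validity of the
  verdicts.

## The AAS quantification chain

`fit_calibration()` regresses blank-corrected peak area on standard
concentration per metal (three standards each, e.g. Cd at 2–4–6 ug/L).
Quantification is `((peak - blank) - intercept)/slope * dilution`, followed
by the digest conversion `tissue = c_solution * volume / mass` (100 mg in
4 mL: 1 mg/L is 40 mg/kg). Decisions where lab practice varies:

* **LoD** is unspecified in the emulated protocol beyond "below the lowest
  standard"; the package uses $3\,\mathrm{sd(blanks)}/\mathrm{slope}$ with
  at least three blank readings, else $3.3\,s_{res}/\mathrm{slope}$. A LoD
  above the lowest standard flags the line invalid (with a warning) instead
  of erroring, so a batch can be screened and re-calibrated.
* **Blank handling**: every signal (standards and samples) is
  blank-corrected first, then the line is applied; the two corrections are
  confounded when standards are blank-corrected, and this order is the
  self-consistent one.
* **QC windows** are closed intervals — spike recovery 90–110%, control
  solutions 95–105% — with a 1e-9 relative tolerance absorbing
  floating-point dust at the boundaries. Sub-LoD and negative net signals
  are flagged, never errors.
* The 0.6 AU peak-height linearity guard is a validity flag on records, not
  signal processing; matrix modifiers are metadata.

## Problem sizes and verification

The test-suite simulations use the study's own geometry (27 runs × 3
replicates): 1000 refits for the bias/coverage study, 2000 for the type-I
error of a true-zero coefficient, a few hundred draws for the
law-of-large-numbers and bootstrap comparisons — sizes at which Monte-Carlo
error is comfortably inside the asserted bands while the whole suite runs in
seconds. Every least-squares result is cross-checked against an independent
normal-equation oracle, and the quantification chain is verified as an exact
round trip of the forward instrument model.

## Known limitations

* Verdict rules are a formalization of a narrative procedure; other
  reasonable rule sets (e.g. judging interference on standardized rather
  than raw estimates) are not implemented.
* The generator's Gaussian, homoscedastic noise is a modelling convenience;
  a lognormal error option would better respect positivity at very low
  means.
* Fractional factorials, blocking and run-order randomization are out of
  scope: the design is a parallel-growth catalogue.
* The confidence semiamplitude is for the mean response;
  `interval = "prediction"` gives the wider single-observation band if
  that is what a monitoring application needs.

## A worked run

```{r pipeline}
report <- run_pipeline(seed = 1, resolution = 21)
report$verdict_summary[, c("metal", "status", "positive")]
```

```{r coefs}
coef_table(report$fits$Cd)
```
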