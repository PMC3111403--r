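---
title: "Methods: fixed-ratio synergy analysis and replicate-consistency filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-ratio synergy analysis and replicate-consistency filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drcombo)
library(dplyr)
```

drcombo answers two questions that arise together in cell-based drug
combination studies. First, given proliferation dose-response data for two
compounds alone and mixed at a fixed dose ratio, is the mixture more potent
than Loewe additivity predicts? Second, given triplicate microarray
feature tables per treatment, which genes respond consistently, and what do
their fold changes look like across treatments? This vignette documents the
models, the tunable parameters, the numerical choices, and what the
simulation-based tests do and do not establish.

## The dose-response model

All curve fitting uses the four-parameter logistic in the
"log(inhibitor) vs. response — variable slope" convention:

$$y(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{\,h\,(\log_{10}\mathrm{ED}_{50} - \log_{10} d)}}$$

with response $y$ in percent of vehicle control, dose $d$ in µM, and
hillslope $h < 0$ for inhibition curves (so $y(0) = \mathrm{top}$ and
$y(\mathrm{ED}_{50}) = (\mathrm{top}+\mathrm{bottom})/2$). "Percent
effect" always means percent of the fitted span suppressed, so a 50%
effect corresponds to the ED50 exactly and the closed-form inverse
(`inverse_dose()`) round-trips with `predict_effect()` to machine
precision. This makes the Tallarida additive construction well defined at
every effect level.

Fitting choices, and why:

* **Individual replicate points, not dose means.** Replicate wells enter
  the least-squares fit individually, giving `n − 4` residual degrees of
  freedom. Averaging first would shrink the apparent residual noise and
  narrow the confidence intervals artificially.
* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with cost
  tolerances of 1e-10, from a deterministic warm start: asymptotes from
  the data range, $\log_{10}\mathrm{ED}_{50}$ by interpolating the dose at
  half-span, hillslope from a logit-linear regression. No random restarts,
  so a fit is reproducible from the data alone.
* **Covariance and CIs.** Parameter covariance is $\hat\sigma^2 (J^\top
  J)^{-1}$ at the optimum; 95% intervals are Wald intervals with a
  Student-t quantile on the residual degrees of freedom. Profile
  likelihood is not implemented; Wald intervals are what standard
  dose-response software reports and what the comparison rule below
  consumes.
* **Degenerate inputs.** Zero response span is rejected before
  optimization (the model is unidentifiable); dose 0 is evaluated as the
  model limit and excluded from log-dose initialization; responses are
  used as given (no clipping of negative or >100% values, uniform
  weights). If the optimizer returns with the top below the bottom, the
  equivalent parameterization with the asymptotes swapped and the slope
  negated is reported, so `top > bottom` is a class invariant.

## Equal-potency fixed-ratio design

With monotherapy ED50s $E_a$ and $E_b$, the mixture fraction of compound
a is $f_a = E_a/(E_a + E_b)$: at the additive 50% effect point each
compound then contributes half the potency. `design_fixed_ratio()` also
carries a display ratio with each ED50 rounded to the nearest multiple of
5 µM, half to even — the convention that reproduces four of the five
published cell-line ratios this package's worked examples draw on; one
published row (63.8 → 60) does not follow nearest-5 rounding, and we do
not guess at its rule. All downstream arithmetic uses the exact
fractions; the rounded ratio is a label.

## The theoretical additive curve and the verdict

For a fixed-ratio mixture, Loewe additivity at percent effect $x$ requires

$$\frac{f_a Z}{D_{x,a}} + \frac{f_b Z}{D_{x,b}} = 1,$$

with $D_{x,\cdot}$ the equi-effective monotherapy doses. The additive
total dose is therefore $Z(x) = (f_a/D_{x,a} + f_b/D_{x,b})^{-1}$; at
$x = 50$ with equal-potency fractions this is exactly $(E_a + E_b)/2$.
`build_additive_curve()` evaluates $Z$ on an effect grid of 1–99% in 1%
steps — dense enough that the 4PL refit of the construction is stable and
clear of the asymptote singularities — places the responses on a percent
of control scale, and refits a 4PL. When the two hillslopes are equal the
additive isobole is exactly 4PL; otherwise it is not, and the refit's
maximum absolute residual is reported. The additive curve's asymptotes
are not dictated by theory when the two monotherapy curves disagree; we
anchor them to the means of the two tops and bottoms by default, with an
`asymptotes` switch for either compound's scale.

Because the construction is deterministic given the monotherapy fits, the
refit alone would carry near-zero residuals and meaninglessly narrow
intervals. `build_additive_curve()` therefore propagates the monotherapy
fits' parameter covariance into the additive refit with a numerical delta
method: the Jacobian of the refit parameters with respect to the eight
monotherapy parameters is estimated by finite differences (step 0.05
standard errors, floored at 1e-4), and the propagated covariance drives
the additive curve's intervals, with the t quantile on the summed
monotherapy residual degrees of freedom. This mirrors the practice of
fitting the additive curve like any other dataset and reading real
confidence intervals off it.

The Combination Index at effect $x$ for component doses $(d_1, d_2)$ is

$$\mathrm{CI} = \frac{d_1}{D_{x,1}} + \frac{d_2}{D_{x,2}},$$

with CI < 1 synergy, 1 additivity, > 1 antagonism. `compare_curves()`
evaluates it at the actual mixture's fitted ED50, decomposed by the exact
design fractions.

**Verdict rule.** A verdict other than "additive" requires statistical
evidence: non-overlap of the 95% intervals for $\log_{10}\mathrm{ED}_{50}$
or for the hillslope between the actual-mixture fit and the additive
refit. The direction then comes from the Combination Index (< 1
synergistic, > 1 subadditive/antagonistic; in the measure-zero tie the
shallower actual slope — a wider effective dose span than additive —
counts as synergy). A raw "CI point estimate below 1" rule was rejected
deliberately: on exactly additive data the estimated CI falls below 1
about half the time, so it would call synergy on noise. CI-interval
non-overlap is conservative (its effective per-parameter error rate is
well under 5%), which the power results below reflect.

## Synthetic data generators

The generators exist so every stage is testable with known ground truth;
no raw plate-reader or array data ship with the package.

* `simulate_monotherapy()`: 4PL responses plus additive Gaussian noise on
  the percent-of-control scale (default SD 5%, a typical plate-reader
  replicate scatter), 6 replicate wells at 8 log-spaced doses spanning
  1–100 µM by default — the dilution-series layout of the proliferation
  assays being emulated. Heteroscedastic noise is out of scope.
* `simulate_combination()`: a τ-Loewe surface — the noiseless effect at
  total dose $Z$ solves $f_a Z/D_{x,a} + f_b Z/D_{x,b} = \tau$, found by
  monotone root bisection to 1e-12. By construction the Combination Index
  of the noiseless surface equals τ at every achievable effect, so τ is
  the ground-truth interaction index (τ = 1 exactly additive). Default
  total doses are 8 log-spaced points over 2–200 µM: τ between 0.25 and 2
  scales an additive ED50 in the tens of µM into roughly 13–103 µM, and
  the mixture midpoint must stay interior to the design for its fit to be
  identified. Doses whose effect leaves (0, 100) are clamped to the
  asymptote with a warning.
* `simulate_feature_tables()`: multi-feature-per-gene array tables with
  planted consistent responders (magnitude ≥ 2-fold in all three
  replicates), optional planted contradictions (an opposing consistent
  sibling feature on a configurable fraction of planted genes), and null
  features with Gaussian log2 ratios (SD 0.25). P values come from a
  deterministic monotone map of |log2 ratio|
  ($p = \min(1, 10^{-1.5 - 3|l_2|})$), standing in for the proprietary
  intensity error model that produced the original P values — that model
  is consumed, never re-derived, so only its monotone character matters
  here. All generators draw from one explicit integer seed and restore
  the caller's RNG state.

## Replicate filtering and gene resolution

Thresholds are inclusive as printed in the workflow being reproduced:
responder means ratio ≥ 2 or ≤ 0.5 **and** P ≤ 0.01. A feature survives
only when it is a responder in the same direction in all three
replicates; its ratio and P are then averaged across replicates.
Contradiction is judged among *surviving* features of a gene only —
sub-threshold sibling features do not veto, matching the workflow order
in which the candidate lists were already thresholded. The representative
feature per gene is the one with the smallest mean P, ties broken
lexicographically by feature id for determinism. Signed fold change is
displayed as the mean ratio for up-regulation and −1/(mean ratio) for
down-regulation, so magnitudes are always ≥ 1; matrix cells are
log2(mean ratio). Both a feature-level and a gene-level counter are
exposed (`count_responders()`), since "transcripts" in a count can mean
either. Cells for genes significant elsewhere but not in a given
treatment are filled from that treatment's replicate-averaged whole-array
table (lowest mean-P feature per gene) and flagged `filled_in`, never
`significant`.

## Problem sizes and what the tests show

The test suite and the reproduction script run entirely on simulated
data at these sizes, chosen to estimate medians and coverage stably:

* ED50/hillslope recovery: 100–200 datasets of 48 observations each;
  median recovered ED50 within 5% of truth and 95% CI coverage ≥ 90%.
* Verdict recovery: 100 runs per τ ∈ {0.5, 1, 1.5}, each run fitting two
  monotherapy curves, the additive construction, and the mixture. For
  this experiment the monotherapy designs are 8 log-spaced doses centered
  on each drug's true ED50 (a factor of ~16 each side): a design that
  does not reach a drug's lower asymptote inflates the additive curve's
  ED50 uncertainty and costs power against τ > 1, which is a statement
  about experimental design, not about the comparison rule.
* Transcript filtering: equivalence with an independent brute-force
  reference on 50 random tables (~30 genes, ≤ 3 features per gene, two
  treatments), plus exact recovery of planted responder counts.

Passing these tests shows the arithmetic, the filtering logic, and the
statistical behaviour under the stated noise model. It does not validate
the biological assumptions: real plate-reader noise is heteroscedastic,
real array P values come from an intensity-dependent error model, real
probes cross-hybridize, and a real mixture need not follow a τ-Loewe
surface at every dose. Published transcript counts from the original
arrays are not reproducible here because the raw data were never
deposited; the filter is validated against its specification and oracle
instead.

## Known limitations

* Two-drug fixed-ratio designs only; no Bliss independence, HSA, ZIP or
  full response-surface models, and no non-equipotent fraction
  optimization.
* Wald intervals only; an extra-sum-of-squares F comparison would be a
  labelled extension.
* The CI carries no interval of its own; inference rests on the curve
  comparison, with the CI giving direction and effect size.
* The package is an R-function interface (plus the reproduction script);
  there is no shell command-line front end.

## A worked pipeline

```{r pipeline, eval = FALSE}
truth_a <- fourpl_params(0, 100, ed50 = 63.8, hillslope = -2)
truth_b <- fourpl_params(0, 100, ed50 = 39.2, hillslope = -2)
frac_a <- 63.8 / (63.8 + 39.2)

mono_a <- simulate_monotherapy(63.8, -2, seed = 1, compound = "DHA-like")
mono_b <- simulate_monotherapy(39.2, -2, seed = 2, compound = "CCM-like")
mix <- simulate_combination(truth_a, truth_b, frac_a, tau = 0.5, seed = 3)

fit_a <- fit_4pl(mono_a)
fit_b <- fit_4pl(mono_b)
design <- design_fixed_ratio(fit_a$ed50, fit_b$ed50)
additive <- build_additive_curve(fit_a, fit_b, design$fraction_a)
report <- compare_curves(fit_4pl(mix), additive, design,
                         fit_a = fit_a, fit_b = fit_b)
glance(report)
```
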