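---
title: "Causal inference for nodal gene regulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal inference for nodal gene regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalcausal)
```

## The scientific problem

At the onset of zebrafish zygotic transcription, the nodal-related genes
*ndr1* (*squint*) and *ndr2* (*cyclops*) are switched on in the embryo
margin, and three upstream inputs are candidate drivers: maternally
deposited Eomesa, Hwa-activated dorsal beta-catenin signaling, and Nodal's
own autoregulation through Smad2, all unfolding over developmental time.
Per-embryo double-FISH imaging yields two intensity readouts per embryo
(one per gene, in uncalibrated optical density, OD) across a factorial
design: wild-type, M*eomesa* and M*hwa* maternal mutants, with and without
the Nodal inhibitor SB431542, at several stages between 3.7 and 4.7 hours
post-fertilization (hpf). `nodalcausal` turns those tables into causal
claims: which factors *cause* each gene's expression, how strongly, and
how the balance shifts over time.

## The regression model

Each gene's intensity is modeled as a linear function of binary presence
indicators and time:

\[
Y_{ndr1} = \alpha_0 + \alpha_1 X_{eomesa} + \alpha_2 X_{\beta catenin}
         + \alpha_3 X_{smad2} + \alpha_4 X_{time} + \varepsilon,
\]

and symmetrically with coefficients \(\beta\) for \(Y_{ndr2}\). Indicators
are 0 exactly when the corresponding input is absent: `x_eomesa = 0` in
M*eomesa* embryos, `x_bcatenin = 0` in M*hwa* embryos, `x_smad2 = 0` under
SB treatment; time is continuous in hpf. Coefficients are estimated by
maximum likelihood (`fit_ols()`, a QR solve); standard errors use the
unbiased residual-variance estimator with \(n - p\) degrees of freedom —
the pure-ML variance divides by \(n\), but the coefficient t-tests require
the \(n - p\) form, so that is what the package reports. Two-sided
p-values come from the t distribution. A per-stage variant without the
time covariate (`fit_per_timepoint()`) yields coefficient trajectories
across stages; both per-stage equations are fitted exactly as written for
both genes, with screening applied downstream rather than baked into the
per-stage model.

Relative contribution (`relative_contributions()`) is not a standard
quantity; the package defines the share of factor \(k\) at stage \(i\) as
\(|c_k(i)| / \sum_j |c_j(i)|\) over the requested factors. The binary
factors share a common 0/1 scale, which makes their coefficients directly
comparable; an alternative (coefficient times factor mean) would weight by
prevalence and is deliberately not used. Shares sum to one per stage and
are undefined (an error) when every requested coefficient is exactly zero.

## Variable screening and the causal graph

A factor whose full-model coefficient has p-value strictly above the
screening threshold (default 0.2) is taken to have no significant direct
effect and becomes a candidate *common cause*; the others, plus time, are
*treatment variables*. The boundary case \(p = 0.2\) counts as a
treatment (strict ">"). Two caveats are worth stating plainly. First,
this is a heuristic, not a guaranteed structure-recovery procedure: for a
factor whose true effect is exactly zero, the p-value is uniform, so the
screen classifies it as a common cause with probability exactly
\(1 - 0.2 = 0.8\) per fit — repeated screens on independent datasets will
disagree about one run in five even when the underlying truth is fixed.
Second, no multiple-testing correction is applied across coefficients at
this stage, matching the source analysis.

The causal graph places the screened common causes — always joined by the
companion gene, since double FISH measures both transcripts in the same
embryo — upstream of both the treatments and the outcome, and the
treatments upstream of the outcome. With every common cause observed, the
backdoor criterion identifies the interventional contrast
\(E[Y \mid do(X{=}1)] - E[Y \mid do(X{=}0)]\) by adjustment:

\[
E[Y \mid do(X{=}x)] = E_W\, E[Y \mid X{=}x, W],
\]

and with a linear outcome model the adjusted effect of each treatment is
its coefficient in the regression of \(Y\) on treatments plus \(W\)
(`estimate_effect()`). Per-treatment effects are per unit intervention
(per hpf for time); the joint contrast — all binary treatments on versus
all off, at fixed \(W\) and fixed time — is the sum of the binary
treatment coefficients, and is the scalar the refutation tests track.

## Refutation tests

Three robustness checks probe whether the estimate behaves like a genuine
interventional quantity. Their pass thresholds are conventions of this
package (the analyses they mirror report the checks without numeric
criteria); all are configurable:

* **Random common cause** — append an independent standard-Gaussian
  covariate to \(W\) and re-estimate; pass when the mean refuted effect is
  within 10% relative change of the original. Linearly dependent added
  columns are dropped (never treatments), so a degenerate duplicate leaves
  the estimate unchanged.
* **Placebo treatment** — replace every treatment column by an independent
  random permutation of itself; permutation preserves the marginal
  distribution, which fresh Gaussian noise would not. Pass when the mean
  refuted effect is within 2 Monte-Carlo standard errors of zero
  ("statistically indistinguishable from zero"; the source analyses print
  the check as a bare 0). All treatments are replaced at once by default;
  whether one or all should be permuted is ambiguous in the source, and
  replacing all is the stricter null.
* **Data subset** — drop a random fraction (default 20%) of embryos and
  re-estimate; pass when the original estimate lies inside the
  2.5–97.5% band of the refuted effects.

Each refuter derives its repetition seeds from a single base seed by
counter, so any run can be replayed exactly.

## The synthetic generator

`simulate_dataset()` draws from a linear structural causal model whose
defaults *are* the study conditions: 3 genotypes x 2 treatments x 4
stages (3.7, 4.0, 4.3, 4.7 hpf), 7–10 embryos per group. Only the
endpoints 3.7 and 4.7 hpf are documented stages; the two intermediate
stages are an assumption, exposed in `design_config()`. The double mutant
is excluded from the default design but supported via configuration.
Gene-2 is drawn first; gene-1 may receive a structural cross-gene edge
from the realized gene-2 intensity (default weight 0 — enabling it
creates genuine confounding, which is how the tests demonstrate that the
backdoor adjustment beats the naive difference in means).

Default coefficients were chosen once, to mimic the quantified OD range
(intensities of a few thousand OD rising with stage) and the reported
causal structure: strong beta-catenin (800 OD) and Smad2 (600 OD) effects
on *ndr1* with a near-zero Eomesa effect (40 OD), the mirror pattern for
*ndr2* (Eomesa 700, Smad2 600, beta-catenin 40), time slopes of 900 and
800 OD/hpf, and noise SD 300 OD. Negative draws are clipped at zero
(measured OD cannot be negative); with the defaults the expected
intensities sit more than ten noise SDs above zero, so clipping is
essentially never triggered (the count is recorded in the `n_clipped`
attribute). `noise_sd = 0` is allowed as the deterministic limit used by
exact-recovery tests. Closed-form ground-truth effects accompany every
constant-coefficient dataset; per-stage coefficient schedules (used to
emulate a beta-catenin contribution that decays as Smad2's grows) carry
their own stage-wise truth instead.

What the generator does **not** emulate: light-sheet optics, embryo
curvature and segmentation error, heteroscedastic or non-Gaussian
intensity noise, stage-measurement error, and any nonlinearity or
saturation in the regulatory response. Passing recovery tests on this
generator therefore validates the estimators under the model's own
assumptions — linearity, additive homoscedastic noise, correctly observed
covariates — not those assumptions themselves on real embryos.

## Image quantification and ChIP-qPCR

`measure_embryo_intensity()` reproduces the manual measurement on
maximum-intensity projections: the raw total is the sum of pixel values
whose centers fall inside the outer ROI polygon (even-odd fill rule,
documented for bit-reproducibility), and the minimum pixel inside a
smaller blank ROI — a dot-free patch of the margin — estimates the
per-pixel background. The source procedure says the blank minimum "was
removed from the total intensity" without stating a scaling; subtracting
the scalar once from a summed total is dimensionally inconsistent, so the
package subtracts `blank_min x pixel_count` and floors at zero. This
makes the corrected total exactly invariant to adding a constant to every
pixel. Whether the original raw measure was a sum or mean x area is
equally ambiguous; the sum reading is implemented. 3-D stacks and
automated ROI proposal are out of scope; ROIs are inputs.

`percent_input()` applies
\(\%Input = 2^{-\Delta Ct_{norm}} \times 100\) with
\(\Delta Ct_{norm} = Ct_{ChIP} - (Ct_{Input} - \log_2 d)\), dilution
factor \(d = 10\) by default, computed in the algebraically identical
form \(2^{-(Ct_{ChIP}-Ct_{Input})}/d \times 100\), which is exact in
floating point for the canonical worked values (equal Cts at \(d=10\)
give exactly 10%; a 3-cycle shift gives exactly 1.25%). Note the
percentage *decreases* in \(d\) at fixed Ct values — a larger dilution
factor means a more concentrated original input. Antibody-vs-IgG
comparisons use the Student (equal-variance) two-sample t-test by
default, matching the named spreadsheet software's convention, with Welch
as an option and Bonferroni correction off by default (none is applied in
the source analysis). With only two replicates per group the test runs
but warns about its very low power; constant-data degeneracies follow the
convention t = 0, p = 1 for equal means.

## Numerical choices and problem sizes

QR decomposition (with pivot-aware recovery of \((X'X)^{-1}\)) is used
for all fits; rank deficiency is an error naming the collinear columns,
except inside refuters where redundant *adjustment* columns are dropped.
Exact-fit degeneracies (zero residual variance) yield zero standard
errors and `NA` t/p. Verification in the test suite runs at deliberately
modest sizes — the default 192-embryo design for single-dataset checks;
100–200 replicate datasets for oracle-equivalence, unbiasedness/coverage,
confounding-win-rate and screening-rate checks; 100 permutations per
refuter; convergence checked at roughly 72/240/960 embryos — sizes at
which Monte-Carlo error is small relative to the asserted margins while a
full run stays interactive.

## Known limitations

The pipeline is exactly the backdoor-plus-linear-estimator pathway: no
instrumental variables, front-door identification, nonlinear or
doubly-robust estimators, no GLS or robust standard errors, and no model
selection. Identification leans on the assumption that the screened
common causes plus the companion gene exhaust the confounding; nothing in
the data can certify that. The screening step inherits the finite-sample
behavior described above, and the contribution shares depend on the
(package-chosen) absolute-coefficient definition.
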