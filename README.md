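# nodalcausal

Causal inference for zebrafish *nodal* gene regulation from per-embryo
fluorescence intensities.

At the start of zygotic transcription, the zebrafish nodal genes *ndr1*
and *ndr2* are induced in the embryo margin by a small set of candidate
upstream inputs: maternal Eomesa, Hwa-activated dorsal beta-catenin
signaling, Nodal/Smad2 autoregulation, and developmental time. Given
per-embryo intensity tables from double FISH across genotypes (WT,
M*eomesa*, M*hwa*), treatments (DMSO vs the Nodal inhibitor SB431542) and
stages (3.7–4.7 hpf), this package answers: which of these factors
*cause* each gene's expression, how large is each interventional effect,
and how does the balance shift over developmental time?

For each gene it fits the multiple linear regression

    Y = a0 + a1*X_eomesa + a2*X_bcatenin + a3*X_smad2 + a4*X_time + e

by maximum likelihood with coefficient t-tests, screens factors into
treatment variables and common causes (p > 0.2 on the full-model
coefficient), builds the causal graphical model, identifies the effect by
the backdoor criterion — E[Y|do(X=x)] = E_W E[Y|X=x, W], with W the
common causes plus the companion gene measured in the same embryo — and
estimates it with a linear estimator. Three refutation tests (random
common cause, placebo treatment, data subset) probe the estimate's
robustness. Per-stage fits give coefficient trajectories and relative
contribution profiles. Companion modules quantify FISH images (ROI total
intensity with blank-minimum background subtraction), compute ChIP-qPCR
%input = 2^(-dCt[normalized]) with antibody-vs-IgG t-tests, and simulate
complete synthetic studies from a linear structural causal model with
known ground-truth effects.

## Worked example

```r
library(nodalcausal)

dat <- simulate_dataset(build_design(design_config(seed = 1)),
                        scm_params(), seed = 1)
fit <- fit_full_model(dat, "ndr1")
fit
#> Linear model fit for ndr1: n = 192, residual SD = 302.9
#>           Estimate Std. Error t value Pr(>|t|)
#> intercept  173.053    259.023  0.6681   0.5049
#> eomesa     -20.056     53.387 -0.3757   0.7076
#> bcatenin   791.262     53.366 14.8271   <2e-16 ***
#> smad2      606.314     43.784 13.8479   <2e-16 ***
#> time       918.840     59.524 15.4366   <2e-16 ***

screen <- screen_variables(fit)
screen
#> Variable screen for ndr1 (p > 0.2 -> common cause):
#>   treatments:    bcatenin, smad2, time
#>   common causes: eomesa

est <- estimate_effect(dat,
         identify_backdoor(build_causal_graph(screen, "ndr1"), dat))
est
#> Backdoor causal estimate for ndr1 (n = 192), W = {eomesa, ndr2}
#>   bcatenin      802.26  (SE 53.85)
#>   smad2         664.09  (SE 60.78)
#>   time         1006.82  (SE 87.58) per hpf
#>   joint all-on vs all-off (bcatenin+smad2): 1466.35  (SE 85.82)

refute_placebo_treatment(dat, est$estimand, n_rep = 100, seed = 1)
#> Refuter 'placebo_treatment': original 1466.350, refuted -9.881 (n_rep = 100)
#>   criterion: |mean refuted| = 9.88 <= 2 x MC SE = 21
#>   pass: yes
```

Reading the output: Eomesa's coefficient is indistinguishable from zero
(p = 0.71 > 0.2), so it is screened out as a candidate common cause of
*ndr1*, while beta-catenin and Smad2 act as treatments — their
backdoor-adjusted effects say a unit intervention (restoring the factor)
raises *ndr1* intensity by roughly 800 and 660 OD here. Replacing the
treatments by permuted placebos collapses the estimated effect from about
1466 OD to a value statistically indistinguishable from 0, as a genuine
causal effect should. The generating truth for this dataset was
beta-catenin 800, Smad2 600, Eomesa 40 OD.

`run_pipeline(pipeline_config(seed = 1), out_dir = "out")` performs the
whole sequence for both genes — simulation (or a user table via
`read_embryo_table()`), full fits, screening, graph, backdoor estimates,
all three refuters, per-stage trajectories and contribution shares — and
writes tidy CSV/JSON/YAML artifacts plus DOT graphs.

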