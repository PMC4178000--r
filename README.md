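# occugear

Bayesian occupancy and abundance modelling for two-gear
detection/non-detection surveys of marine fish — the design in which a
baited chevron trap and a trap-mounted video camera sample every site
simultaneously, so the replicate observations that occupancy models
require are collected without violating population closure. The package
is written for fisheries and quantitative-ecology analysts who have
site-level detection records from paired gears and want
detection-corrected estimates of where a species occurs, how abundant it
is, and what each gear can and cannot see.

## The models

At site *i*, occupancy state *z<sub>i</sub>* ~ Bernoulli(ψ<sub>i</sub>)
and gear *j* records *y<sub>ij</sub>* ~ Binomial(k<sub>j</sub>,
z<sub>i</sub> p<sub>ij</sub>) detections in its k<sub>j</sub> replicates
(chevron k = 1; camera either pooled, k = 1, or disaggregated into its 41
one-second snapshots, k = 41). The Royle–Nichols variant replaces *z* with
latent abundance *N<sub>i</sub>* ~ Poisson(λ<sub>i</sub>) and links
individual detection *r* to species detection via
p = 1 − (1 − r)<sup>N</sup>. Covariates act on logit ψ (or log λ) and on
each gear's detection logit; each effect is multiplied by a latent 0/1
inclusion indicator with a Bernoulli(0.5) prior (Kuo–Mallick), so
posterior indicator means are inclusion probabilities and all summaries
are model-averaged. Coefficients carry the Student-t(σ = 1.566,
ν = 7.763) prior whose back-transform is uniform on (0, 1). Fit adequacy
is checked by a chi-square detection-history statistic calibrated with a
parametric bootstrap, and fitted models yield prediction curves/surfaces
over depth and latitude plus gear-level detection summaries. A
synthetic-data generator reproduces the whole survey design — including
serially correlated snapshots and jointly detected groups of fish, the two
ways real data break the binomial assumptions — so every stage is testable
by simulation. See `vignette("two-gear-occupancy")` for the full account.

## Worked example

```r
library(occugear)

tbl <- simulate_sites(sim_scenario(S = 200, family = "basic", seed = 42))
naive_occupancy(tbl, "chevron")   # 0.195
naive_occupancy(tbl, "camera")    # 0.395

fit <- fit_occupancy(tbl, model_spec("basic", "pooled"),
                     settings = mcmc_settings_reduced(seed = 1))
fit
#> <occugear_fit> Bin(psi) Bin(p_chevron) Bin(p_camera) [camera pooled]
#>   sites: 200; retained draws: 15000 (3 chains)
#>   mean occupancy: 0.497 [0.416, 0.594]
#>   max split R-hat: 1.009

dplyr::filter(inclusion_probabilities(fit), supported)
#> # A tibble: 2 x 4
#>   submodel     term  inclusion_prob supported
#> 1 distribution lat            0.865 TRUE
#> 2 distribution lat2           1     TRUE

detection_summary(fit)
#> # A tibble: 4 x 5
#>   quantity               estimate std.error conf.low conf.high
#> 1 p_chevron               0.366      0.0709   0.228      0.504
#> 2 p_camera                0.781      0.0788   0.610      0.915
#> 3 camera_contrast_turb.h  0.0322     0.0735  -0.0650     0.228
#> 4 camera_contrast_cdir.a -0.00719    0.0592  -0.173      0.122

gof_test(fit, n_boot = 100, seed = 1)
#> <occugear_gof> observed chi-square 500.4, gof_p = 0.81 (100 bootstrap datasets)
```

Reading the numbers: the naive (uncorrected) chevron rate 0.195
understates occupancy badly; the detection-corrected posterior puts mean
occupancy at 0.497 with a 95% credible interval [0.416, 0.594] — close to
the generating value. The latitude terms (the simulated spatial gradient)
are the only covariates whose inclusion probability clears the 50%
support threshold; camera detection (~0.78) is roughly twice chevron
detection (~0.37); and `gof_p = 0.81` shows no evidence of misfit, as
expected for pooled, well-specified data. `tidy(fit)` and `glance(fit)`
give the full model-averaged parameter table and one-line summary;
`autoplot(predict_curve(fit, "depth"))` draws the depth response with its
credible ribbon.

The same pipeline runs from the shell via `inst/exec/occugear`
(`simulate`, `fit`, `gof`, `predict`, `report`, each taking `--config`,
`--seed`, `--out`), driven by a YAML config.

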