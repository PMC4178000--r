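---
title: "Two-gear occupancy and Royle-Nichols models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-gear occupancy and Royle-Nichols models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

occugear fits Bayesian hierarchical models to detection/non-detection data
collected simultaneously by two sampling gears at each site: a baited
chevron fish trap (one sample per deployment) and a video camera mounted on
the trap, whose 20-minute recording is examined as 41 one-second snapshots.
Deploying both gears at once produces the replicate samples occupancy
models need while keeping the population closed across replicates — the
main obstacle to occupancy modelling of mobile marine fish. This vignette
explains the models, the sampler, the validation strategy, and the design
decisions a maintainer would want to know about.

## The two model families

**Basic occupancy.** Site $i$ has a latent occupancy state
$z_i \sim \mathrm{Bernoulli}(\psi_i)$. Conditional on $z_i = 1$, gear $j$
detects the species in each of its $k_j$ replicates independently with
probability $p_{ij}$, so the observed detection count is
$y_{ij} \sim \mathrm{Binomial}(k_j,\, z_i\, p_{ij})$. The chevron trap
always has $k_1 = 1$; the camera contributes either one pooled binary
replicate ($k_2 = 1$, "was the species seen in any snapshot") or the 41
disaggregated snapshots ($k_2 = 41$).

**Royle-Nichols abundance.** Site abundance
$N_i \sim \mathrm{Poisson}(\lambda_i)$ is latent; each individual is
detected independently with gear-specific probability $r_{ij}$, so the
species-level detection probability is $p_{ij} = 1 - (1 - r_{ij})^{N_i}$.
Heterogeneity in detection across sites is thereby explained by abundance,
and covariates act on $\log \lambda_i$ rather than on $\mathrm{logit}\,\psi_i$.
The two quantities connect through $\Pr(N_i \ge 1) = 1 - e^{-\lambda_i}$.

Covariates enter through linear predictors: 15 occupancy/abundance terms
(year, depth and depth$^2$, latitude and latitude$^2$, temperature and
temperature$^2$, and three-level classifications of live-bottom cover,
hard-substrate cover and relief), 6 chevron detection terms (temperature,
temperature$^2$, soak time, current direction, current speed) and 4 camera
detection terms (turbidity, current direction, current speed). Continuous
covariates are centered and scaled to unit variance so coefficient
magnitudes are directly comparable.

Optionally, a site random effect $\varepsilon_i \sim N(0, \sigma_\varepsilon)$
enters the camera-detection logit (basic family) or $\log \lambda_i$
(Royle-Nichols). A single binary replicate per site carries no information
about a site-level detection random effect, so random effects are only
permitted with the disaggregated camera data; `model_spec()` enforces this.
Together these choices give six model structures: two families, pooled or
disaggregated camera data, with or without the random effect.

## Priors and model averaging

Every link-scale coefficient gets a Student-t prior with scale 1.566 and
7.763 degrees of freedom. For an intercept this is the "uniform on the
probability scale" choice: back-transforming a $t(0, 1.566, 7.763)$ draw
through the inverse logit gives approximately $\mathrm{Uniform}(0, 1)$, a
property the test suite verifies with a prior-only run (no sites) and a
Kolmogorov-Smirnov check. We apply the same prior to the Royle-Nichols
log-abundance coefficients; the package treats "all link-scale parameters
alike" as a single policy rather than switching priors by sub-model.
Random-effect SDs get $\mathrm{Uniform}(0, 100)$.

Covariate selection uses indicator variables in the Kuo-Mallick
construction: each non-intercept coefficient $\beta_m$ is multiplied by a
latent $w_m \in \{0, 1\}$ with an independent Bernoulli(0.5) prior, so the
linear predictor uses $w_m \beta_m$ and the posterior mean of $w_m$ is the
covariate's inclusion probability (supported if it exceeds 0.5). Parameter
summaries in `tidy()` average $w_m \beta_m$ over **all** draws — zeros from
excluded states included — which is the genuinely model-averaged estimate;
`average = "conditional"` gives the inclusion-conditional alternative,
since published tables do not always say which convention they use.

A deliberate consequence of carrying all three live-bottom (and
hard-substrate) indicator columns is that the all-included state is
collinear with the intercept. The indicator prior regularizes this: states
with redundant columns are visited but carry no extra likelihood, so their
inclusion probabilities stay near or below the prior. We implement the
covariate set as published rather than silently dropping a reference level.

## The sampler

The posterior is sampled by a purpose-built MCMC kernel (C++ core):

* latent occupancy $z_i$ by single-site Gibbs draws from its Bernoulli
  full conditional (forced to 1 at sites with any detection);
* latent abundance $N_i$ by a discrete Metropolis walk ($\pm 1$ steps,
  mixed with independence proposals from the Poisson prior, for which the
  prior and proposal cancel) on $\{0, \dots, N_{\max}\}$;
* coefficients by adaptive Gaussian random-walk Metropolis, with
  Robbins-Monro tuning toward 44% acceptance, frozen at the end of burn-in
  so the retained chain is a fixed Markov kernel;
* indicators $w_m$ by Gibbs on their two-point conditional; when a
  coefficient is excluded it is refreshed from its prior (its exact full
  conditional under Kuo-Mallick), keeping the joint chain irreducible;
* random effects by per-site Metropolis and $\sigma_\varepsilon$ by
  Metropolis under its uniform prior.

Full-scale settings (`mcmc_settings()`) retain 30,000 draws from 3 chains
of 100,000 iterations, 10,000 burn-in, thinned by 10. Desk-scale settings
(`mcmc_settings_reduced()`: 3 chains of 6,000 with 1,000 burn-in) are what
the test suite and examples use; the suite's heavier checks run 400-site
fits at those settings in roughly ten seconds each. Convergence is
monitored with a split-chain Gelman-Rubin statistic (`gelman_rubin()`,
threshold 1.1). Correctness of the kernel is established against a dense
grid enumeration of the posterior on a no-covariate toy — not against
another sampler — so the check is independent of MCMC implementation
choices.

All likelihoods are computed in log space; 41-replicate binomials at
extreme rates would underflow otherwise. $N_{\max}$ defaults to 100:
published mean abundances for this fishery are at most about 2 per site,
making the truncated Poisson tail mass negligible, and
`site_marginal_loglik_rn()` warns if the tail mass beyond $N_{\max}$
exceeds tolerance. $N_{\max}$ is a package construct (truncation is an
implementation necessity, not part of the model) and is configurable.

## Goodness of fit

`gof_test()` implements a chi-square detection-history check calibrated by
parametric bootstrap. Expected history probabilities per site come from
point estimates (model-averaged posterior means by default; medians
optionally): 4 cells (chevron $\times$ camera) for pooled data, $2 \times 42$
cells for disaggregated data, with sparse camera-count cells merged from
the tail until each aggregate expected count reaches 2 (no published
binning rule exists; this is the package's). The observed statistic
$\sum_i \sum_c (O_{ic} - E_{ic})^2 / E_{ic}$ is referred to statistics from
`n_boot` datasets simulated at the observed covariates from the same point
estimates; `gof_p` is the proportion of bootstrap statistics at least as
large. Near 0 means lack of fit; near 1, no evidence against the model.

With `refit = FALSE` (default) the bootstrap statistics reuse the original
estimates. This is fast but conservative: the observed statistic benefits
from estimates fitted to the observed data while the bootstrap statistics
do not, so `gof_p` runs high on well-specified data. `refit = TRUE` refits
each bootstrap dataset (with `refit_settings`, typically a single short
chain) and is approximately calibrated — the acceptance suite checks its
median behavior — at about a hundred times the cost. Both are offered
because the faster variant is entirely adequate for detecting the gross
misfit that serially correlated snapshots produce.

## Predictions

`predict_curve()` and `predict_surface()` evaluate occupancy or abundance
per retained draw over covariate grids, then summarize pointwise (mean,
2.5%, 97.5%), so bands carry both coefficient and model-selection
uncertainty. Non-focal covariates sit at reference: continuous at their
training mean (0 standardized), categories at reference levels
(relief low, current toward, low speed, clear water), year 2010. A focal
covariate's quadratic partner moves with it, processed by the identical
standardization pipeline as training. Reference settings for non-focal
covariates are a convention (no published statement pins them down) and
are deliberately centralized in one helper. A guard refuses grids more
than 4 SD outside the training data unless `extrapolate = TRUE`.
`detection_summary()` back-transforms detection intercept draws and forms
turbidity and current-direction contrasts per draw.

## The synthetic-data generator

`sim_scenario()` + `simulate_sites()` emulate the survey: depths uniform
on 16-83 m, latitudes uniform on 27-32°N, normal bottom temperatures
(22.5 ± 2.5 °C) and soak times (90 ± 10 min), and categorical frequencies
chosen as plausible for reef sites (e.g. relief 50/30/20). Default true
parameters sit near published estimates (occupancy ≈ 0.45, chevron
detection ≈ 0.39, camera ≈ 0.75; abundance ≈ 0.65 with chevron r ≈ 0.30,
camera r ≈ 0.61) so simulated data are in-regime; they are calibration
conveniences, not ground truth. Detection parameters are specified on the
pooled-replicate scale, and the generator solves for the per-snapshot rate
that preserves the pooled detection probability under the requested
snapshot dependence — so pooled analyses of clustered data see an
unchanged marginal rate, which is exactly what makes the pooled/
disaggregated contrast clean.

Two controlled assumption violations are built in:

* **Snapshot clustering** (`snapshot_rho`): the 41 snapshots follow a
  two-state Markov chain with lag-1 correlation $\rho$ (serial
  autocorrelation from too-short sampling intervals); a beta-binomial
  mechanism (`snapshot_mechanism = "betabinom"`) models exchangeable
  extra-binomial variation from schooling instead.
* **Clustered individuals** (`group_dispersion`, Royle-Nichols): fish
  arrive in groups of mean size $1 + d$ that are detected jointly, so the
  model perceives groups as individuals. Expected total abundance is held
  at $\lambda$ while the number of independent detection units shrinks,
  which biases $\hat\lambda$ downward by roughly the mean group size — the
  suite verifies the direction, not a specific magnitude.

What passing simulation tests do **not** show: real surveys have spatial
autocorrelation, gear interference, observer variation in snapshot reading
and non-random site selection, none of which the generator emulates.
Parameter recovery on generator output validates the estimator under the
model's assumptions, not the model's adequacy for any particular survey.

`synthetic_study_table()` deserves its own caveat: it is a synthetic
stand-in for the study's site table (which this package does not
redistribute), constructed by matching published observable summaries —
naive detection rates pinned exactly at 0.14 (chevron) and 0.31 (camera),
and a two-gear overlap consistent with camera detection ≈ 0.757 — with
occupancy structured by depth and quadratic latitude at published
conditional effect sizes. The two-gear identity then implies occupancy
near 0.41 and chevron detection near 0.34 for any dataset with those
observables and site-constant detection; published point estimates (0.45
and 0.39) cannot be reproduced simultaneously with the naive rates, and
analyses of this table should be read with that in mind.

## Numerical and interface choices

* Squared terms are the square of the standardized covariate,
  re-standardized (`square_terms = "scaled"`), keeping every column on a
  unit scale; `"raw"` squares first. The choice is configurable because
  either reading of "standardized quadratic covariates" is defensible.
* Initialization: $z_i$ = any detection, $N_i$ = max observed count + 1,
  coefficients 0, $\sigma_\varepsilon = 1$ — guarantees a finite starting
  likelihood.
* Chains are seeded `seed + chain - 1` through R's RNG, so every result in
  the package is exactly reproducible from one integer.
* Ties in `min_abundance_for_detection()` resolve to the smallest
  qualifying integer, with a guard against floating-point error in the
  closed-form ceiling.
* The pipeline commands (`run_simulate()` through `run_report()`) write
  outputs atomically and stamp them with a hash of the analysis
  configuration (excluding its filesystem location) plus the seed.

## Known limitations

Single-season (closed) models only; no spatial autocorrelation; no
binomial-mixture (count-based) models — incidence data only; the
disaggregated random-effect structures mix more slowly than the pooled
ones and may need longer chains than the reduced defaults; and the
indicator sampler's known weakness (excluded coefficients re-drawn from a
wide prior are rarely re-accepted when the likelihood is sharp) is
mitigated by the fairly tight t prior scale but not eliminated.
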