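---
title: "Bayesian habitat-use analysis for camera-trap surveys with camoccu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian habitat-use analysis for camera-trap surveys with camoccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

camoccu implements the full analysis chain used to infer habitat-use
drivers of an elusive forest felid from multi-year camera-trap surveys:
detection-history construction, Bayesian single-season occupancy modeling
on a stacked camera-year design, leave-one-out model ranking,
posterior-predictive goodness of fit, and gridded spatial projection. This
vignette is the package's account of the science: the model and its
assumptions, the defaults and why they were chosen, what the synthetic
generator does and does not emulate, and the limitations we know about.

## The model

For stacked site $i$ (one camera station in one calendar year) and
occasion $t$ (a block of 15 consecutive survey days), the data are binary
detections $y_{it}$ with per-occasion effort $e_{it}$ (active camera-days,
0–15). The single-season occupancy model separates the ecological and the
observational process:

$$z_i \sim \mathrm{Bernoulli}(\psi_i), \qquad
  y_{it} \mid z_i \sim \mathrm{Bernoulli}(z_i\, p_{it}),$$

$$\operatorname{logit}(\psi_i) = \beta_0 + \sum_j \beta_j x_{ij} + \alpha_{s(i)},
  \qquad \alpha_s \sim \mathrm{Normal}(0, \sigma),$$

$$\operatorname{logit}(p_{it}) = \gamma_0 + \gamma_e \hat e_{it} + \delta_{v(i)},$$

where $x_{ij}$ are z-scored site covariates (tree cover, distance to
water, distance to paved road, elevation, terrain ruggedness, distance to
settlements), $\hat e_{it}$ is z-scored effort, $\delta_v$ are offsets for
the survey database (reference level OC), and $\alpha_s$ is an optional
station-level random intercept that absorbs the pseudoreplication
introduced by stacking the same station across years. For a wide-ranging
species $\psi$ is read as habitat-use probability rather than closed-population
occupancy.

All likelihood computations marginalize the latent state analytically:

$$P(y_i) = \psi_i \prod_{t \in \text{obs}} p_{it}^{y_{it}}(1-p_{it})^{1-y_{it}}
  + (1-\psi_i)\,[\text{all observed } y_{it}=0],$$

with unsurveyed occasions (zero effort) contributing no factor. This
marginal form is what `occu_loglik()` evaluates, what the per-draw
pointwise log-likelihood matrix used by LOO and GOF is built from, and
what the test suite verifies against exhaustive latent-state enumeration
to $10^{-10}$. MCMC sampling (JAGS) samples the discrete $z_i$ directly;
the two routes are checked against each other.

### Assumptions

* Closure within the (at most) 120-day window per site: the use state
  $z_i$ does not change across its occasions.
* Detections are independent across occasions given $z_i$; the
  independence filter (default 30 min) removes within-occasion
  pseudo-replicates before histories are built, but the model itself uses
  only the binary occasion summary.
* Sites are independent given covariates and the station intercept; no
  residual spatial autocorrelation is modeled.

## Detection-history construction

`build_detection_history()` anchors occasion bins at each deployment's own
start date — a global calendar anchor would create fractional first
occasions — and truncates each site at
$\min(\text{deployment end}, \text{start} + 119\ \text{days})$ to respect
closure. Trailing partial occasions are retained with their true effort
(1–14 days); effort then enters detection as a covariate, which is exactly
why it is modeled. Occasions never surveyed are missing (NA), and the
effort matrix's zero cells coincide with the missing cells by
construction. Deployments crossing a calendar-year boundary are split at
the boundary (`stack_site_years()`); each (station, year) pair must be
unique after stacking, and overlapping deployments for the same
station-year are an error rather than silently merged.

## Covariate preparation

All modeled covariates are z-scored with the *stacked-site sample* mean
and SD (`z_transform()`, $n-1$ denominator); the parameters are stored so
that prediction-grid covariates are standardized with the training
moments — the only coherent choice for projection. Collinearity is
screened with Spearman rank correlations (`spearman_screen()`), flagging
$|\rho| \ge 0.70$; rank correlations are invariant to monotone transforms,
so the screen is unaffected by the skewness of distance covariates. When a
year trend is requested (`psi_terms = "year"`), year enters as a z-scored
numeric covariate; categorical coding can be emulated by pre-building
indicator columns.

## Priors

Defaults (`occu_priors()`), all overridable:

* slopes (occupancy and detection): Normal(0, 2.5) on z-scored predictors;
* intercepts: Logistic(0, 1), i.e. uniform on the probability scale;
* random-intercept SD: Exponential(mean 1).

The intercept and SD choices deserve comment because they matter in
exactly the regime camera-trap data occupy. With per-occasion detection
near 0.09, the likelihood is almost flat along a ridge that trades
baseline occupancy against baseline detection, and along a second ridge
that trades random-intercept variance against slope magnitude
(non-collapsibility of the logit link). A wide logit-normal intercept
prior is bathtub-shaped on the probability scale and actively pulls the
posterior towards degenerate solutions ($\psi \to 1$ with $p$ tiny); we
observed converged chains settling there under Normal(0, 5) intercepts.
The uniform-on-probability logistic prior and the light-tailed
exponential SD prior are the standard defaults of Bayesian occupancy
backends for this reason, and sensitivity to them should be reported
whenever detections are sparse.

## Sampling and convergence

`fit_occupancy()` builds the JAGS model on the fly from the specification
(`occu_spec()`): any subset of the six site covariates (plus year) on
occupancy, effort and/or survey on detection, optional random station
intercept. Defaults follow the field convention of four chains of 40,000
iterations with half discarded as burn-in; the examples, tests and
analysis scripts in this package run 2 chains of 1,200–8,000 iterations,
which is sufficient for the problem sizes they use — convergence is always
checked, never assumed. `check_convergence()` computes split-$\hat R$ per
parameter (each chain halved, so within-chain drift is penalized) against
the conventional 1.05 threshold, and flags degenerate (zero-variance)
parameters separately.

## Model ranking

`loo_elpd()` computes the expected log pointwise predictive density under
leave-one-out cross-validation from the per-site, per-draw log-likelihood
matrix, using Pareto-smoothed importance sampling: per site, the largest
20% of importance ratios are replaced by quantiles of a generalized Pareto
distribution fitted to them by the profile--posterior-mean method, with the
shape estimate shrunk towards 0.5 for small tail samples, and sites with
shape $k > 0.7$ reported as unreliable. The test suite validates the whole
construction against exact leave-one-out refitting on 25 sites (within
0.5 elpd).

`compare_models()` attaches model weights. The default is
Bayesian-bootstrap pseudo-BMA, which regularizes by the pointwise
variance of the elpd contributions; stacking of predictive distributions
is available as an option. Naive normalization of $\exp(\Delta\text{elpd})$
is deliberately not offered: it ignores the uncertainty of the elpd
estimates and produces overconfident weights. Published comparison tables
in this field are frequently inconsistent with any single estimator, so
the estimator used should always be stated alongside the table.

`backward_eliminate()` implements the parsimony search: repeatedly drop
the occupancy term with the smallest $|\text{posterior mean}|/\text{SD}$,
refit, and keep the reduction if elpd does not drop by more than a
configurable margin (default 0); the search stops at the first rejected
removal. Both the margin and the stopping rule are configuration, not
doctrine; the elimination trail is returned so the path can be inspected.

## Goodness of fit

`mb_gof()` is the MacKenzie–Bailey chi-square with a posterior-predictive
p-value. Sites are cohorted by their missingness pattern; within a cohort
all $2^{K_c}$ possible histories are enumerated and their expected
frequencies computed from the model, $X^2 = \sum (O_h - E_h)^2 / E_h$. For
each selected posterior draw the observed-data statistic and the statistic
of a replicate dataset simulated at that same draw are compared;
$p = \Pr(X^2_{\text{rep}} \ge X^2_{\text{obs}})$.

The pooling floor for small expected cells defaults to 0 (no pooling).
Pooling cells that were never observed does not change the statistic at
all — a pooled zero-observation cell contributes $\sum E_h$ either way — so
at $K = 8$ (256 possible histories per cohort) a floor of 2 merges
precisely the observed rare histories and removes most of the test's
power against detection heterogeneity; and the chi-square approximation
that pooling was invented to protect is not used, because the p-value is
simulation-based. We verified that strong unmodeled detection
heterogeneity is detected at floor 0 and missed at floor 2. The floor
remains configurable for users who want the tabular tradition.

## Spatial projection

`make_grid()` tiles a projected-meter extent with 500-m cells (row-major
from the top-left, partial edge cells kept with true centroids);
`predict_psi()` standardizes the cell covariates with the training
moments, pushes every posterior draw through the occupancy linear
predictor, and summarizes per cell (mean, 95% interval). The random
intercept is zero in `"conditional"` mode — the typical-station surface,
the default — or freshly drawn per draw and cell in `"marginal"` mode,
which averages over station heterogeneity and lifts the surface where the
linear predictor is negative (Jensen). Detection covariates play no role:
the surface is habitat use. Cells beyond 4 training SDs of any covariate
trigger an extrapolation warning. Output is delimited text; the package
does not write georeferenced rasters.

## The synthetic generator

`simulate_study()` emulates the statistical structure of a two-mountain-range
montane survey so the pipeline is testable end to end without field data:

* **Covariates.** Station-level draws with the study-scale moments (tree
  cover 86.13 ± 14.26 %, distance to water 485.4 ± 365.73 m, distance to
  road 2513.36 ± 2837.4 m, elevation 2489.4 ± 516.97 m, ruggedness
  25.43 ± 12.08 m, distance to settlements 4875.55 ± 4314.09 m). Tree
  cover uses a truncated normal on [0, 100] whose *truncated* moments are
  matched numerically. The distance covariates have SDs comparable to or
  exceeding their means, which a normal left-truncated at zero cannot
  attain (its SD/mean ratio is bounded by the exponential-tail limit), so
  they are drawn from moment-matched gamma distributions — right-skewed,
  as real distance-to-feature covariates are. Covariates are independent
  across columns and constant within a station across years.
* **Design.** 204 stations × 3 years = 612 stacked sites by default, one
  deployment per site-year of 75–120 days (uniform), kept inside the
  calendar year, giving 5–8 occasions of 15 days, about 59,700 trap-nights
  in total, and mean effort per surveyed occasion of about 14 days. The
  deployment-length range was calibrated so that the total effort *and*
  the posterior uncertainties of the best-model refit jointly match a
  study of this published scale; station count and deployment-length
  distribution are otherwise unidentified.
* **Truth.** Detection histories are generated from the model itself with
  slopes (per SD) of 0.69 (tree cover), 0.68 (elevation), −0.42 (water),
  0.23 (ruggedness), zero road and settlement effects, effort slope 0.34,
  and intercepts calibrated so the site-mean habitat use is about 0.30 and
  per-occasion detection about 0.09 ($\beta_0 = -1.03$ includes a
  logit-normal correction for the station SD of 0.5; $\gamma_0 = -2.31$).
  Latent states are attached to the output for recovery tests only.
* **Raw tables.** `simulate_records()` places one timestamped record
  uniformly inside the active days of each detected occasion, so
  rebuilding the history from records and deployments reproduces the
  simulated matrix exactly — the round-trip identity the builder tests
  rely on.

What the generator does **not** emulate: spatial autocorrelation among
stations; camera failure and theft; within-deployment outages (which is
why simulated per-occasion effort averages ~14 d where a real study
reports ~13.2 d, and why effort variance is mildly understated); multiple
independent events within one occasion (simulated event counts are
therefore occasion-level lower bounds); covariate correlation structure;
and real landscape gradients. Passing tests demonstrate that the
machinery is correct under the model's own assumptions, not that the model
is adequate for any particular field dataset — that is what the
goodness-of-fit stage is for.

## Numerical choices

* Likelihoods are accumulated in log space with a stable two-term
  log-sum-exp for the undetected-site mixture.
* Detection probabilities inside the GOF enumeration are clamped to
  $[10^{-12}, 1-10^{-12}]$; an observed history whose expected count is
  exactly zero yields an infinite statistic (the model calls it
  impossible) rather than being silently pooled away.
* PSIS tail size is $\lceil \min(S/5,\ 3\sqrt S) \rceil$ draws; smoothing
  is skipped below 25 draws or 5 tail points.
* Split-$\hat R$ is the classical between/within ratio on half-chains;
  zero-variance parameters return NaN and are reported as degenerate
  rather than convergent.
* Effort is z-scored over surveyed occasions only; a zero-variance effort
  matrix falls back to SD 1 (the slope is then unidentified and shrinks to
  its prior).
* Deterministic seeding throughout: the generator derives per-stage
  streams from one seed (covariates, deployments, states, record times),
  and each MCMC chain receives seed + chain − 1.

## Problem sizes used by the tests and scripts

Parameter-recovery checks run 20 replicates of 300 sites × 8 occasions at
2 × 3,000 iterations; the exact-LOO oracle refits 25 sites 26 times at
2 × 4,000; GOF calibration runs 10 replicates of 150 sites; the
study-scale emulation fits three candidate models to 612 sites at
2 × 4,000–8,000. These sizes are the package's own choices for routine
verification; they are not the field convention for a final analysis,
which remains 4 × 40,000.

## Known limitations

* **Sparse-detection regimes.** Under the emulated study's detectability
  (~0.09 per occasion, ~50–120 detection events per dataset), posterior
  means of occupancy slopes carry a small-sample inflation of roughly
  +0.1–0.25 (logistic skew; the posterior is asymmetric away from zero)
  even though 95% interval coverage is nominal, and with a random station
  intercept the weakly-identified SD can drift upwards, inflating slope
  magnitudes with it. Long-chain checks show this is a property of the
  posterior, not of the sampler. Interval summaries are trustworthy; point
  estimates at such event counts should be read with that asymmetry in
  mind. Under moderate detectability (~0.27 per occasion) all parameters,
  including the random-intercept SD, are recovered essentially without
  bias.
* **Single-interval deployments.** The deployment type carries one
  interval per site-year, so mid-deployment camera outages cannot be
  represented; real effort matrices with interior gaps must be supplied
  via the prebuilt-matrix readers.
* **No spatial dependence.** Neither the model nor the generator includes
  residual spatial autocorrelation; habitat-use surfaces inherit this.
* **Weights are estimator-dependent.** Pseudo-BMA and stacking can
  disagree noticeably when models are close in elpd; report which one a
  table uses.
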