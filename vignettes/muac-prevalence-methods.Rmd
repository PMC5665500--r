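---
title: "Estimating acute-malnutrition prevalence from MUAC: classic and PROBIT methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating acute-malnutrition prevalence from MUAC: classic and PROBIT methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muacprobit)
library(dplyr)
```

## The problem

Nutrition surveillance classifies children under five as acutely
malnourished when their mid-upper arm circumference (MUAC) falls below a
case-defining cutoff: 115 mm for severe acute malnutrition (SAM) and 125 mm
for global acute malnutrition (GAM). The standard ("classic") survey
estimator dichotomises every child at the cutoff and reports the sample
proportion with a design-adjusted confidence interval. Because cases are
rare — SAM prevalence is often below 5% — this throws away almost all of
the information in the continuous measurement, and the resulting surveys
need several hundred children to be informative.

The PROBIT alternative keeps MUAC continuous. MUAC in young children is
approximately normal, so the prevalence below a cutoff $c$ can be estimated
as the normal cumulative probability

$$\hat p = \Phi\!\left(\frac{c - \hat\mu}{\hat\sigma}\right),$$

with $\hat\mu$ the sample mean MUAC and $\hat\sigma$ either the sample SD
(**method II**) or an external SD taken from previous surveys in the same
region (**method I**). Estimating a mean is far easier than estimating a
tail proportion, which is why these estimators stay usable at sample sizes
(25–200 children) where the classic estimator's interval degenerates.

This package implements all three estimators, the machinery to compare
them by Monte-Carlo simulation (synthetic survey populations, two-stage
subsampling, bias/precision/coverage/classification metrics), and a
regional SD reference builder for method I.

## Estimators and intervals

**Classic.** $\hat p$ is the proportion below the cutoff (strict `<`; a
child exactly at the cutoff is not a case). For clustered samples the SE is
the Taylor-linearised between-cluster form, which for $k$ equal-size
clusters is $\mathrm{SE}^2 = \sum_j (p_j - \hat p)^2 / (k(k-1))$; for
simple-random samples it is $\sqrt{\hat p(1-\hat p)/n}$. The interval is
Wald, truncated to $[0,1]$. We deliberately use no continuity correction
and no exact interval: the plain Wald interval is what "cluster-adjusted
standard errors for the proportion" produces, and its small-sample
pathology at low prevalence (zero-case samples give a width-zero interval)
is part of what the simulation is designed to expose.

**PROBIT CIs.** Both PROBIT methods get their interval on the $z$-scale.
The sample is resampled `n_boot` times — whole clusters with replacement
for cluster samples, records for simple-random samples — and each
replicate yields $z_b = (c - \mu_b)/\sigma_b$, with $\sigma_b$ the
replicate SD (method II) or a draw from the regional reference's empirical
SD distribution (method I). The interval is normal-theory,
$\hat z \pm 1.96\,\mathrm{se}(z_b)$, mapped through $\Phi$. We use one
stream of paired replicates (each replicate pairs one mean resample with
one SD draw), not a product of two bootstrap loops: a single "standard
error from the bootstrap distribution" of $Z$ only makes sense for one
replicate stream. Percentile intervals were considered and rejected for
the same reason — the construction is explicitly SE-based.

Replicates with zero SD are redrawn and counted; if more than 10% of
replicates degenerate the sample is rejected with an error. A zero-SD
*sample* likewise errors rather than silently reporting 0% or 100%:
surveillance users must see that failure.

**The SD reference (method I).** Prior surveys are summarised by their
sample SD, weighted by effective sample size
$\mathrm{ESS} = n / (1 + (\bar m - 1)\hat\rho)$ — $\hat\rho$ the one-way
ANOVA intracluster correlation floored at zero — stratified by region, and
pooled by a weighted bootstrap (2000 replications of whole surveys,
selection probability proportional to weight; the regional mean SD is the
mean of replicate means). Whether the historical procedure weighted the
SDs themselves or the resampling probabilities is ambiguous; both give the
weighted mean in expectation, and we implement weighted resampling because
the SD is a survey-level statistic and resampling whole surveys preserves
its sampling distribution. `default_sd_reference()` ships the five
published regional means (12.3/12.8/13.0/12.8/12.0 mm) as point masses,
with an optional dispersion parameter for users without a survey corpus —
the original survey-level SD distribution is not recoverable, and the
point-mass default makes that explicit rather than inventing spread.

## The synthetic study

The original comparison ran on 852 field surveys that are not publicly
deposited, so the package generates its own populations and is explicit
about what they do and do not emulate.

`generate_population()` draws cluster effects from
$N(0, \sigma^2\rho)$ and child residuals with variance
$\sigma^2(1-\rho)$, normal by default, skew-normal (slant
parameterisation, moment-corrected back to the target mean and SD) when
asked. Defaults: 30 clusters × 27 children (~810 children, matching both
common 30-cluster field practice and the historical database's mean survey
size), mean MUAC 135 mm, SD 12.5 mm, ICC 0.05. Under those defaults true
GAM is about 21% and true SAM about 5.5%.

`subsample_clustered()` mirrors how the small surveys were simulated: 25
clusters sampled without replacement, then $m = n/25$ children per cluster
without replacement, for $n \in \{25, 50, \ldots, 200\}$ ($m$ from 1 to
8). Clusters holding fewer than $m$ children contribute everything and the
shortfall is topped up from additionally drawn clusters so the sample size
stays exact (the metric grid needs exact sizes); with the default
generator this path never triggers. Cluster selection is equal-probability
without replacement — the historical procedure does not state
with/without replacement or PPS, and self-weighting equal-probability
selection is the natural reading. `run_study()` crosses populations ×
sizes × replicates × methods × cutoffs, derives one RNG substream per cell
from the master seed (`substream_seed()`, a multiplicative hash modulo
$2^{31}-1$), and records per-row error codes instead of aborting, so a
single degenerate sample cannot kill a night-long run.

What the generator does *not* emulate: real MUAC heaping at round values,
age structure, spatial/seasonal structure, PPS first stages, and the wide
1–48% GAM range of the historical database (populations share one spec
unless you vary it). Passing calibration tests here therefore show the
estimators behave correctly *under their own assumptions*, not that field
data satisfy those assumptions.

## Metrics

For every (method, cutoff, sample size) cell, `summarize_metrics()`
reports, following the standard definitions:

* **bias** — mean of (estimate − truth), in percentage points, with the
  median alongside (the classic estimator's small-sample skew makes its
  mean bias positive while its median sits near zero);
* **precision** — mean CI half-width in percentage points (smaller is
  better);
* **coverage** — the fraction of 95% CIs containing the truth, closed
  intervals, so a truth of exactly 0 sitting on a `[0, x]` interval counts
  as covered.

`classify()` reads "probability of correctly classifying prevalence as at
or above a threshold" as sensitivity — among rows whose *truth* is at or
above the threshold, the fraction whose *estimate* is too — and emits
specificity and unconditional accuracy as well, because the historical
table caption does not pin the denominator down; reporting all three makes
the ambiguity harmless.

`bias_regression()` fits OLS of per-(population, size, method) mean GAM
bias on dummy-coded region, GAM category (<5, 5–9, 10–14, ≥15%),
livelihood, residence, sample size, date period and design, with the
conventional reference levels (East Africa, <5%, agriculture, rural, 25,
before 2006, simple random). The per-(population × size) mean is the
finest unit consistent with sample size being a predictor.

## A small benchmark

```{r benchmark, eval = FALSE}
bm <- benchmark_study(n_populations = 50,
                      design = simulation_design(reps = 100),
                      n_boot = 500, seed = 20171101)
metrics <- summarize_metrics(bm$results)
plot_metrics(metrics, "precision")
plot_metrics(metrics, "coverage")
```

`benchmark_study()` is the package's canned calibration experiment: 50
populations under the default spec (regions and other metadata assigned
round-robin), an SD reference built from those same populations, all three
estimators at both cutoffs. At 50 × 100 × 8 = 40,000 subsamples with 500
bootstrap replications it runs in a few minutes on one core; `n_boot`
defaults to 500 here (2000 elsewhere) because the CI-width error from 500
replicates is already well below the Monte-Carlo noise of a 100-replicate
study cell. The acceptance script and the test suite both run exactly this
experiment; the numbers quoted in the README come from it.

Three behaviours are worth knowing about before reading such output:

* At SAM-level prevalence and $n = 25$, about a quarter of classic-method
  samples contain zero cases, so their Wald intervals are exactly `[0, 0]`:
  classic coverage collapses (≈0.76 here, while both PROBIT methods stay
  above 0.93), and those zero-width intervals also *deflate* the classic
  mean half-width, letting it undercut the sample-SD PROBIT's half-width in
  that one cell even though both PROBIT methods are tighter everywhere
  else. Neither behaviour is a bug; both are the small-sample pathology
  the PROBIT approach exists to avoid.
* With every population at ~21% true GAM, classification at the 5% and 10%
  thresholds saturates: essentially every estimate clears them, so the
  "probability correct" ties at 1.0 and only the 15% threshold
  discriminates between methods.
* PROBIT coverage is near nominal but mildly conservative/anticonservative
  by cell, because the cluster bootstrap at $n = 25$ (25 singleton
  clusters) slightly underestimates the $z$-scale SE.

## Numerical choices and degenerate inputs

* Plausibility cleaning defaults to 80–220 mm (the physiological range for
  under-fives); the historical flagging rule behind "highly improbable
  values" is unstated, so these bounds are a configurable stand-in, not a
  reproduction. Cleaning is idempotent and missing MUAC is excluded and
  counted.
* Proportions are carried as fractions in `[0,1]` internally; displays
  round to one decimal in percent.
* The ANOVA ICC uses the unbalanced-design cluster-size constant
  $m_0 = (n - \sum_j n_j^2/n)/(k-1)$ and floors negative estimates at 0.
* Bootstrap CIs require ≥2 clusters (cluster designs) and `n_boot` ≥ 2;
  estimator errors inside `run_study()` become `error_code` strings.
* Confidence level is 0.95 throughout by default, z-quantile
  `qnorm(0.975)`, never 1.96 hard-coded.

## Limitations

The package evaluates estimators on synthetic populations; it does not
ship field data. Design effects beyond cluster resampling are not
propagated into the PROBIT intervals (matching the historical analysis,
which acknowledged possible CI underestimation from the same choice).
No normality transformation or smoothing is applied to MUAC before the
PROBIT step, and nothing here handles oedema or weight-for-height case
definitions: prevalence is MUAC-only by construction.
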