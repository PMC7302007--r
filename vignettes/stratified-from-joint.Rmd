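---
title: "Stratified and marginal genetic effects from joint GxE summary statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified and marginal genetic effects from joint GxE summary statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(joint2strat)
```

## The model and the derivation

For a trait $Y$, a SNP $G$ coded as the minor-allele count and a binary
exposure $E$, the joint interaction model is

$$g(\mathbb{E}[Y \mid G, E]) = \alpha + \beta G + \gamma E + \delta GE,$$

with $g$ the identity link for a quantitative trait and the logit link for
a binary one. Because $E$ is binary, the interaction model is *saturated*
in the exposure: plugging $E = 0$ or $E = 1$ into the fitted model gives
exactly the genetic effect a per-stratum regression would estimate,

$$\hat\beta_{unexp} = \hat\beta, \qquad
  \hat\beta_{exp} = \hat\beta + \hat\delta,$$

and averaging over the exposure distribution gives the SNP coefficient of
the no-interaction (marginal) model,

$$\hat\beta_{marg} = \hat\beta + \hat\delta \mu_E, \qquad \mu_E = N_e/N.$$

The standard errors follow from the variance of a linear combination of
the two estimates,

$$\sigma_{exp} = \sqrt{\sigma_{\hat\beta}^2 + \sigma_{\hat\delta}^2
    + 2\,\mathrm{cov}(\hat\beta, \hat\delta)}, \qquad
  \sigma_{marg} = \sqrt{\sigma_{\hat\beta}^2 + \mu_E^2 \sigma_{\hat\delta}^2
    + 2 \mu_E\,\mathrm{cov}(\hat\beta, \hat\delta)},$$

where the covariance is recovered from the correlation $r$ reported in
meta-analysis output as $r\,\sigma_{\hat\beta}\,\sigma_{\hat\delta}$ (an
explicit covariance column, when present, is used directly). For
$r \in [-1, 1]$ both variance expressions are completed squares and hence
non-negative; values within $-10^{-12}$ of zero are clamped to zero
(floating-point noise), anything more negative is reported as corrupt
input with the offending variant named.

Two assumptions matter. First, genotype and exposure are independent: the
marginal derivation averages the joint fit over the *population* exposure
frequency, which is only the within-genotype exposure frequency under
independence. Second, the per-variant exposure proportion equals the
study-wide $\mu_E$: genotype missingness that is exposure-imbalanced
breaks this, which is why variants with low relative sample size are
filtered (below).

The stratified point-estimate identities are exact for the linear model —
the package's tests assert agreement with per-stratum least-squares fits
to $10^{-10}$ relative error, and the observed agreement is at the level
of the differing QR factorisations ($\sim 10^{-15}$). The standard errors
are not exactly those of the per-stratum fits, because the joint model
estimates a single pooled residual variance while each stratum fit uses
its own; with equal stratum variances the difference vanishes as
$n \to \infty$.

## The tool

`read_joint_file()` reads tab-delimited (optionally gzipped) files in the
METAL interaction dialect; every column role is remappable because
consortium headers vary. Rows violating the numeric invariants (missing
estimates, negative SEs, correlation outside $[-1,1]$, non-positive
sample size) are kept, flagged with a reason and emitted with `NA`
sentinels — meta-analysed files routinely contain partial rows, and
silently dropping them would make output row counts untrustworthy.
Duplicate variant identifiers are processed row-wise; the derivation is
row-local.

Per-variant stratum sizes are reported as the real-valued expectations
$N_v (N - N_e)/N$ and $N_v N_e / N$; rounding would break their exact sum
to $N_v$. Wald $p$-values use the standard-normal reference, not a $t$
distribution: meta-analysed summary statistics carry no usable residual
degrees of freedom. Output numbers are serialised with 6 significant
digits.

**Sample-size filter.** A variant is flagged when its sample size falls
below $Q_{0.9}/1.5$, the 9th decile of the per-variant sample-size
distribution divided by 1.5. The quantile uses the linear-interpolation
order-statistic convention (`stats::quantile` type 7, the shared default
of mainstream numerics stacks); the tests verify it against a brute-force
order-statistic oracle, so the convention is pinned, not incidental.
Filtering flags rows rather than deleting them, and the writer drops
flagged rows by default (`keep_filtered = TRUE` retains them). Whether
the filter runs before or after derivation does not change any retained
value; the pipeline filters first and skips the dropped rows' arithmetic.

## The simulation framework

`sim_scenario()` fixes the study conditions; the defaults are the
conditions the validation is designed around:

| parameter | default | meaning |
|---|---|---|
| `n_individuals` | 10,000 | individuals per replicate (50,000-scale runs are reserved for bias studies on larger budgets) |
| `n_replicates` | 1,000 | replicates per study |
| `maf_range` | (0.01, 0.5) | MAF drawn uniformly per replicate; $G \sim \mathrm{Bin}(2, \mathrm{MAF})$ |
| `exposure_prob_range` | (0.1, 0.5) | exposure probability drawn uniformly; $E \sim \mathrm{Bern}(p)$ |
| `effect_range` | (0.05, 0.2) | magnitudes of $\beta_G$, $\beta_E$, $\beta_{GE}$, equiprobable random sign |
| `noise_sd` | 1 | residual SD $\sigma$; with it, the effect range corresponds to the small fractions of phenotypic variance typical of GWAS loci |
| `trait_type` | quantitative | binary traits use a logistic probability on the same linear predictor, with the same normal noise on the predictor scale |

A quantitative replicate is
$Y = \beta_G G + \beta_E E + \beta_{GE} GE + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$. For binary traits the conventional
logistic $P(Y{=}1) = 1/(1 + e^{-\eta})$ is the default; a `reversed`
option flips the sign of the linear predictor, since both sign
conventions circulate and the choice flips every effect direction while
leaving all agreement metrics invariant.

Each replicate is analysed twice: "true" statistics from per-stratum and
pooled regressions on the individual-level data (`lm`; `glm` with a logit
link for binary traits), and "estimated" statistics from the derivation
applied to that replicate's joint fit — including the estimate
correlation taken from the joint fit's covariance matrix, exactly what a
meta-analysis would carry. Replicates with an empty stratum or a
monomorphic genotype in a stratum are skipped and counted.

**Agreement** is the two-way random-effects, absolute-agreement,
single-measurement intraclass correlation (`icc()`), computed for effect
sizes, standard errors and Wald statistics separately. The
absolute-agreement variant is the point: a consistency-type coefficient
(or a Pearson correlation) would not penalise a systematic shift between
the true and derived statistics. The implementation is the closed-form
mean-squares expression and is cross-checked in the tests against an
independent `aov`-based ANOVA-table computation. When the total variance
is zero the coefficient is undefined and `NA` is returned.

### Bias mechanisms

Where the generating mechanism was genuinely open, the package fixes one
and documents it here:

* **Genotype–exposure dependence** (`ge_corr`): the target point-biserial
  correlation is drawn uniformly from $(0, \texttt{ge\_corr})$ per
  replicate and the exposure is generated as
  $E \mid G \sim \mathrm{Bern}(\mathrm{logistic}(a + bG))$. The slope $b$
  is calibrated by root-finding so the closed-form correlation over the
  three genotype classes hits the target, with $a$ re-solved at every $b$
  to hold the exposure frequency; this is the simplest monotone mechanism
  that produces a continuum of correlations for quintile analysis.
  Targets above the mechanism's achievable maximum for a low-MAF draw are
  clamped; the quintile analysis uses realised sample correlations, so
  the clamp only shapes the upper tail. The default target maximum of
  0.12 spans from negligible to clearly material dependence while staying
  achievable across the whole MAF range.
* **Misspecified exposure proportion** (`subsample_fraction`,
  `exposed_removal_fraction`): per replicate a retained fraction is drawn
  uniformly from $(\texttt{subsample\_fraction}, 1)$, then an additional
  uniformly drawn fraction of *exposed* individuals is removed. The
  derivation is fed the full-sample $\mu_E$ while the data are the
  subsample with exposure mean $m_E$ — emulating a variant whose
  genotype missingness is exposure-imbalanced. The bias magnitude is
  $|\mu_E - m_E|/\mu_E$. Defaults when engaged: retained fraction
  $\sim U(0.5, 1)$, removal fraction $\sim U(0, 0.5)$, spanning
  misspecifications from 0 to roughly 40%.
* **Exposure-dependent variance** (`exposed_extra_noise_sd`): extra
  normal noise with SD drawn uniformly from $(0, 2)$ (when engaged) is
  added to exposed individuals' phenotypes, i.e. up to twice the baseline
  residual SD, giving between-stratum SD differences from 0 to
  $\approx 1.2$ — from none to unmistakably heteroscedastic.

`run_bias_study()` reports ICCs within quintiles of the *realised*
per-replicate bias magnitude, plus the mean absolute error between true
and derived standard errors per quintile. The expected patterns:
genotype–exposure dependence leaves the stratified agreement at
$\approx 1$ and degrades only the marginal one, increasingly with the
correlation; exposure-proportion misspecification likewise touches only
the marginal analysis; heteroscedasticity leaves effect sizes and the
marginal analysis unbiased but distorts the stratified standard errors,
increasingly with the variance gap.

**Direction of the heteroscedastic SE bias.** Because the stratified
point estimates are exact, the only distortion is in the variance: the
joint fit estimates one pooled residual variance, which *exceeds* the
low-variance stratum's own residual variance and *falls short of* the
high-variance stratum's. The derived SE is therefore overestimated in the
low-variance stratum (deflated Wald statistics, conservative type-I
error) and underestimated in the high-variance stratum (inflated
statistics and type-I error). The null-model study reproduces this
signature: with extra noise on exposed individuals, the derived-statistic
rejection rate at $\alpha = 0.05$ falls significantly below nominal in
the unexposed stratum and above it in the exposed stratum, while the
individual-level fits stay calibrated.

`run_null_study()` sets $\beta_G = \beta_{GE} = 0$ (the exposure effect
is still drawn), reports empirical rejection rates at $\alpha = 0.05$ for
both routes, and a significance-discordance proportion under a Bonferroni
threshold of $\alpha$ divided by the number of replicates — mirroring a
per-SNP screening correction.

### Reproducibility and problem sizes

Every study seeds the RNG from the scenario, so identical scenarios give
bit-identical reports. The package's validation runs use 1,000 replicates
of $n = 10{,}000$ for the accuracy study, 2,000 replicates of
$n = 5{,}000$ for the null study and 1,000 replicates of $n = 5{,}000$
per bias study — sizes chosen so the full suite re-runs in a few minutes
on one CPU while leaving the Monte-Carlo error of each reported ICC and
rejection rate an order of magnitude below the effects being asserted
(the exact binomial 99% acceptance band at 2,000 replicates is
$[3.75\%, 6.25\%]$ around the nominal 5%).

## What the simulations do and do not show

The generator draws a single biallelic variant per replicate with
binomial genotypes in Hardy–Weinberg proportions, an exposure independent
of everything except where a mechanism is engaged, and i.i.d. normal
noise. It does not emulate linkage disequilibrium between variants,
population stratification, covariates, heterogeneity between
meta-analysed cohorts, genotype imputation uncertainty, or realistic
missingness patterns (missingness enters only through the subsampling
mechanism). Passing the accuracy and calibration studies therefore shows
that the *derivation* is faithful to the joint fit under the stated
assumptions — it does not certify behaviour on real consortium data,
where the bias studies indicate which diagnostics matter: check
exposure-imbalanced missingness (the sample-size filter is the blunt
instrument for this), known G–E correlated variants, and between-stratum
variance differences.

## Known limitations

* The marginal derivation needs $0 < \mu_E < 1$; degenerate designs are
  rejected rather than silently collapsed onto one stratum.
* For binary traits the derivation operates on the log-odds scale of the
  joint logistic fit; stratified logistic refits are approximated, not
  exact, since the logit marginal over strata is not the stratum-weighted
  coefficient average. The simulations show the approximation is
  excellent at GWAS-scale effects.
* The estimate correlation is taken at face value from the input file;
  meta-analysis artefacts in that column propagate directly into the
  derived SEs.
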