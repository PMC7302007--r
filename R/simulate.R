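#' Define a simulation scenario
#'
#' One scenario describes how individual-level gene-environment data are
#' generated across replicates. Per replicate: a minor allele frequency is
#' drawn uniformly from `maf_range` and genotypes as Binomial(2, MAF); an
#' exposure probability is drawn uniformly from `exposure_prob_range` and
#' exposures as Bernoulli (modified when genotype-exposure dependence is
#' engaged); effect magnitudes for the genetic, exposure and interaction
#' terms are drawn uniformly from `effect_range` with equiprobable random
#' signs; a quantitative trait is
#' \eqn{Y = \beta_G G + \beta_E E + \beta_{GE} G E + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, while a binary trait is Bernoulli
#' with a logistic probability built from the same linear predictor (plus
#' the same normal noise on the predictor scale).
#'
#' Three bias mechanisms can be engaged, one per study:
#' \describe{
#'   \item{genotype-exposure dependence}{`ge_corr > 0`: per replicate a
#'     target point-biserial correlation is drawn uniformly from
#'     `(0, ge_corr)` and the exposure is drawn as
#'     \eqn{E | G \sim Bernoulli(logistic(a + b G))}, with `b` calibrated
#'     by root-finding to the target correlation and `a` to the target
#'     exposure probability. Targets above the mechanism's achievable
#'     maximum for the drawn MAF are clamped; quintile analyses use the
#'     realised sample correlation, so the clamp only shapes the upper
#'     tail.}
#'   \item{misspecified exposure proportion}{`subsample_fraction < 1`
#'     and/or `exposed_removal_fraction > 0`: per replicate a retained
#'     fraction is drawn uniformly from `(subsample_fraction, 1)`, then an
#'     additional fraction of exposed individuals, drawn uniformly from
#'     `(0, exposed_removal_fraction)`, is removed. The derivation is fed
#'     the full-sample exposure frequency \eqn{\mu_E} while the data are
#'     the subsample with realised exposure mean \eqn{m_E}, emulating a
#'     variant whose genotype missingness is exposure-imbalanced.}
#'   \item{exposure-dependent phenotypic variance}{`exposed_extra_noise_sd
#'     > 0`: per replicate an extra noise SD is drawn uniformly from
#'     `(0, exposed_extra_noise_sd)` and added to exposed individuals'
#'     phenotypes (to the linear predictor for binary traits).}
#' }
#'
#' @param n_individuals Individuals per replicate.
#' @param n_replicates Number of replicates.
#' @param maf_range Minor allele frequency range, within (0, 0.5].
#' @param exposure_prob_range Exposure probability range, within (0, 1).
#' @param effect_range Range of |effect| for the genetic, exposure and
#'   interaction coefficients (trait units per allele; log-odds for binary
#'   traits).
#' @param noise_sd Residual SD \eqn{\sigma} of the trait (or of the noise
#'   on the predictor scale for binary traits).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param ge_corr Maximum target genotype-exposure correlation; 0 keeps
#'   genotype and exposure independent.
#' @param subsample_fraction Minimum retained fraction of individuals;
#'   1 disables subsampling.
#' @param exposed_removal_fraction Maximum additional fraction of exposed
#'   individuals removed from the subsample; 0 disables.
#' @param exposed_extra_noise_sd Maximum extra residual SD added to exposed
#'   individuals; 0 disables.
#' @param null_model If `TRUE`, the genetic and interaction effects are
#'   fixed at zero (the exposure effect is still drawn).
#' @param intercept Intercept \eqn{\alpha} of the generating model.
#' @param binary_link_sign `"conventional"` uses the standard logistic
#'   \eqn{P(Y=1) = 1/(1+e^{-\eta})}; `"reversed"` uses
#'   \eqn{1/(1+e^{+\eta})}, which flips every effect direction. Agreement
#'   metrics are invariant to the choice.
#' @param seed Integer seed; identical scenarios (including the seed)
#'   reproduce bit-identical study reports.
#' @return An object of class `sim_scenario` (a validated list).
#' @export
sim_scenario <- function(n_individuals = 10000,
                         n_replicates = 1000,
                         maf_range = c(0.01, 0.5),
                         exposure_prob_range = c(0.1, 0.5),
                         effect_range = c(0.05, 0.2),
                         noise_sd = 1,
                         trait_type = c("quantitative", "binary"),
                         ge_corr = 0,
                         subsample_fraction = 1,
                         exposed_removal_fraction = 0,
                         exposed_extra_noise_sd = 0,
                         null_model = FALSE,
                         intercept = 0,
                         binary_link_sign = c("conventional", "reversed"),
                         seed = 1L) {
  trait_type <- match.arg(trait_type)
  binary_link_sign <- match.arg(binary_link_sign)
  check_range <- function(r, lo, hi, name) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < lo || r[2] > hi) {
      stop(sprintf("`%s` must be an increasing interval within [%g, %g]",
                   name, lo, hi), call. = FALSE)
    }
  }
  check_range(maf_range, 1e-6, 0.5, "maf_range")
  check_range(exposure_prob_range, 1e-6, 1 - 1e-6, "exposure_prob_range")
  check_range(effect_range, 0, Inf, "effect_range")
  stopifnot(
    n_individuals >= 10, n_replicates >= 1,
    noise_sd > 0, ge_corr >= 0, ge_corr < 1,
    subsample_fraction > 0, subsample_fraction <= 1,
    exposed_removal_fraction >= 0, exposed_removal_fraction < 1,
    exposed_extra_noise_sd >= 0
  )
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_replicates = as.integer(n_replicates),
      maf_range = as.double(maf_range),
      exposure_prob_range = as.double(exposure_prob_range),
      effect_range = as.double(effect_range),
      noise_sd = as.double(noise_sd),
      trait_type = trait_type,
      ge_corr = as.double(ge_corr),
      subsample_fraction = as.double(subsample_fraction),
      exposed_removal_fraction = as.double(exposed_removal_fraction),
      exposed_extra_noise_sd = as.double(exposed_extra_noise_sd),
      null_model = isTRUE(null_model),
      intercept = as.double(intercept),
      binary_link_sign = binary_link_sign,
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: %d replicates x %d individuals, %s trait\n",
    x$n_replicates, x$n_individuals, x$trait_type
  ))
  knobs <- c(
    if (x$null_model) "null model (no genetic, no interaction effect)",
    if (x$ge_corr > 0) sprintf("G-E correlation up to %.3g", x$ge_corr),
    if (x$subsample_fraction < 1 || x$exposed_removal_fraction > 0)
      "misspecified exposure proportion (subsampling)",
    if (x$exposed_extra_noise_sd > 0)
      sprintf("exposure-dependent variance (extra SD up to %.3g)",
              x$exposed_extra_noise_sd)
  )
  if (length(knobs)) cat("  engaged:", paste(knobs, collapse = "; "), "\n")
  invisible(x)
}

# Calibrate the slope b of E | G ~ Bernoulli(plogis(a + b G)) so that the
# population point-biserial correlation between G and E equals rho_target,
# with a re-solved at each b to hold the exposure probability at p_target.
# All expectations are closed-form sums over the three genotype values.
# Returns list(a, b, rho) with rho the achieved (possibly clamped)
# correlation.
calibrate_ge_dependence <- function(maf, p_target, rho_target) {
  g <- 0:2
  pg <- stats::dbinom(g, 2, maf)
  mean_g <- 2 * maf
  var_g <- 2 * maf * (1 - maf)
  solve_a <- function(b) {
    stats::uniroot(
      function(a) sum(pg * stats::plogis(a + b * g)) - p_target,
      interval = c(-60, 60), tol = 1e-10
    )$root
  }
  rho_of_b <- function(b) {
    a <- solve_a(b)
    pi_g <- stats::plogis(a + b * g)
    (sum(pg * g * pi_g) - mean_g * p_target) /
      sqrt(var_g * p_target * (1 - p_target))
  }
  b_max <- 25
  rho_max <- rho_of_b(b_max)
  rho <- min(rho_target, 0.98 * rho_max)
  if (rho <= 0) {
    return(list(a = stats::qlogis(p_target), b = 0, rho = 0))
  }
  b <- stats::uniroot(function(b) rho_of_b(b) - rho, c(0, b_max),
                      tol = 1e-8)$root
  list(a = solve_a(b), b = b, rho = rho)
}

#' Simulate one replicate of individual-level gene-environment data
#'
#' Draws genotypes, exposure and trait for a single replicate of a
#' scenario, applying whichever bias mechanisms the scenario engages.
#' Uses the current RNG state unless `rep_index` is supplied, in which case
#' a per-replicate seed is derived from the scenario seed so that a single
#' replicate can be regenerated in isolation.
#'
#' @param scn A [sim_scenario()].
#' @param rep_index Optional replicate number used to derive a
#'   deterministic per-replicate seed.
#' @return A list with elements `G` (0/1/2 allele counts), `E` (0/1
#'   exposure), `Y` (trait) — the analysis sample after any subsampling —
#'   and `truth`, a list of the generating values: `maf`, `p_exposed`,
#'   `beta_g`, `beta_e`, `beta_ge`, `rho_ge_target`, `extra_noise_sd`,
#'   `n_full` and `n_exposed_full` (the pre-subsampling study design),
#'   `mu_e` (full-sample exposure mean) and `m_e` (analysis-sample
#'   exposure mean).
#' @export
simulate_replicate <- function(scn, rep_index = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (!is.null(rep_index)) {
    set.seed((scn$seed %% 1000003L) * 2011L + as.integer(rep_index))
  }
  n <- scn$n_individuals
  maf <- stats::runif(1, scn$maf_range[1], scn$maf_range[2])
  p_exposed <- stats::runif(1, scn$exposure_prob_range[1],
                            scn$exposure_prob_range[2])
  draw_effect <- function() {
    stats::runif(1, scn$effect_range[1], scn$effect_range[2]) *
      sample(c(-1, 1), 1)
  }
  beta_e <- draw_effect()
  if (scn$null_model) {
    beta_g <- 0
    beta_ge <- 0
  } else {
    beta_g <- draw_effect()
    beta_ge <- draw_effect()
  }

  G <- stats::rbinom(n, 2, maf)
  rho_target <- 0
  if (scn$ge_corr > 0) {
    rho_target <- stats::runif(1, 0, scn$ge_corr)
    cal <- calibrate_ge_dependence(maf, p_exposed, rho_target)
    E <- stats::rbinom(n, 1, stats::plogis(cal$a + cal$b * G))
  } else {
    E <- stats::rbinom(n, 1, p_exposed)
  }

  extra_sd <- 0
  if (scn$exposed_extra_noise_sd > 0) {
    extra_sd <- stats::runif(1, 0, scn$exposed_extra_noise_sd)
  }
  eps <- stats::rnorm(n, 0, scn$noise_sd)
  if (extra_sd > 0) {
    eps <- eps + E * stats::rnorm(n, 0, extra_sd)
  }
  eta <- scn$intercept + beta_g * G + beta_e * E + beta_ge * G * E + eps
  Y <- if (scn$trait_type == "quantitative") {
    eta
  } else {
    pr <- if (scn$binary_link_sign == "conventional") {
      stats::plogis(eta)
    } else {
      stats::plogis(-eta)
    }
    stats::rbinom(n, 1, pr)
  }

  mu_e <- mean(E)
  n_exposed_full <- sum(E)
  keep <- rep(TRUE, n)
  if (scn$subsample_fraction < 1 || scn$exposed_removal_fraction > 0) {
    retained <- stats::runif(1, scn$subsample_fraction, 1)
    keep <- stats::runif(n) < retained
    if (scn$exposed_removal_fraction > 0) {
      drop_frac <- stats::runif(1, 0, scn$exposed_removal_fraction)
      keep <- keep & !(E == 1 & stats::runif(n) < drop_frac)
    }
  }

  list(
    G = G[keep], E = E[keep], Y = Y[keep],
    truth = list(
      maf = maf, p_exposed = p_exposed,
      beta_g = beta_g, beta_e = beta_e, beta_ge = beta_ge,
      rho_ge_target = rho_target, extra_noise_sd = extra_sd,
      n_full = n, n_exposed_full = n_exposed_full,
      mu_e = mu_e, m_e = mean(E[keep])
    )
  )
}
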