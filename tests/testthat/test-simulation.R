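test_that("joint-model derivation reproduces stratified OLS point estimates exactly", {
  # Saturation identity: with a full G x E interaction the linear model is
  # saturated in the binary exposure, so the derived stratified point
  # estimates must equal per-stratum least-squares fits to machine
  # precision, replicate after replicate.
  scn <- sim_scenario(n_individuals = 1500, n_replicates = 15, seed = 21)
  set.seed(scn$seed)
  for (i in seq_len(scn$n_replicates)) {
    dat <- simulate_replicate(scn)
    fit <- fit_all_models(dat, "quantitative")
    design <- study_design(fit$n, sum(dat$E))
    joint <- data.frame(
      variant_id = "v", beta = fit$joint$beta, se_beta = fit$joint$se_beta,
      delta = fit$joint$delta, se_delta = fit$joint$se_delta,
      corr_beta_delta = fit$joint$corr, n_variant = fit$n
    )
    un <- derive_unexposed(joint)
    ex <- derive_exposed(joint)

    # oracle: independent per-stratum least-squares fits
    lm0 <- lm(dat$Y[dat$E == 0] ~ dat$G[dat$E == 0])
    lm1 <- lm(dat$Y[dat$E == 1] ~ dat$G[dat$E == 1])
    expect_equal(un$beta_hat, unname(coef(lm0)[2]), tolerance = 1e-10)
    expect_equal(ex$beta_hat, unname(coef(lm1)[2]), tolerance = 1e-10)
    expect_equal(un$beta_hat, fit$stratified_unexp$beta, tolerance = 1e-12)
    expect_equal(ex$beta_hat, fit$stratified_exp$beta, tolerance = 1e-12)
    # SEs agree up to pooled-vs-stratum residual variance
    expect_equal(ex$se_hat, fit$stratified_exp$se, tolerance = 0.1)
  }
})

test_that("derived marginal effect matches a pooled no-interaction fit", {
  scn <- sim_scenario(n_individuals = 10000, n_replicates = 30, seed = 22)
  set.seed(scn$seed)
  diffs <- replicate(scn$n_replicates, {
    dat <- simulate_replicate(scn)
    fit <- fit_all_models(dat, "quantitative")
    design <- study_design(fit$n, sum(dat$E))
    joint <- data.frame(
      beta = fit$joint$beta, se_beta = fit$joint$se_beta,
      delta = fit$joint$delta, se_delta = fit$joint$se_delta,
      corr_beta_delta = fit$joint$corr
    )
    marg <- derive_marginal(joint, design)
    oracle <- unname(coef(lm(dat$Y ~ dat$G + dat$E))[2])
    abs(marg$beta_hat - oracle)
  })
  expect_lt(mean(diffs), 1e-2)
})

test_that("a joint fit recovers the generating coefficients", {
  dat <- make_individual_data(n = 10000, maf = 0.3, p_exposed = 0.4,
                              beta_g = 0.1, beta_e = 0.1, beta_ge = 0.1,
                              seed = 31)
  fit <- fit_all_models(dat, "quantitative")
  expect_lt(abs(fit$joint$beta - 0.1) / fit$joint$se_beta, 3)
  expect_lt(abs(fit$joint$delta - 0.1) / fit$joint$se_delta, 3)
  expect_equal(fit$realized_mu_e, mean(dat$E))
})

test_that("degenerate individual-level designs are rejected", {
  dat <- make_individual_data(n = 500, seed = 32)
  dat$E <- rep(0L, 500)
  expect_error(fit_all_models(dat), "empty stratum")
  dat2 <- make_individual_data(n = 500, seed = 33)
  dat2$G[dat2$E == 1] <- 0L
  expect_error(fit_all_models(dat2), "constant genotype")
})

test_that("scenario draws honour their declared ranges and the null model", {
  scn <- sim_scenario(n_individuals = 800, n_replicates = 1, seed = 41,
                      null_model = TRUE)
  set.seed(scn$seed)
  cors <- replicate(40, {
    dat <- simulate_replicate(scn)
    expect_true(all(dat$G %in% 0:2))
    expect_true(all(dat$E %in% 0:1))
    c(cor(dat$Y, dat$G), cor(dat$G, dat$E))
  })
  # under the null Y carries no genetic signal; with independent draws the
  # G-E sample correlation is centred at zero
  expect_lt(abs(mean(cors[1, ])), 0.02)
  expect_lt(abs(mean(cors[2, ])), 0.02)
})

test_that("the genotype-exposure dependence mechanism hits its target", {
  # closed-form check of the calibration itself
  cal <- joint2strat:::calibrate_ge_dependence(0.3, 0.35, 0.15)
  g <- 0:2; pg <- dbinom(g, 2, 0.3)
  pi_g <- plogis(cal$a + cal$b * g)
  expect_equal(sum(pg * pi_g), 0.35, tolerance = 1e-6)
  achieved <- (sum(pg * g * pi_g) - 0.6 * 0.35) /
    sqrt(2 * 0.3 * 0.7 * 0.35 * 0.65)
  expect_equal(achieved, 0.15, tolerance = 1e-6)

  # empirical check on a large sample
  set.seed(51)
  G <- rbinom(2e5, 2, 0.3)
  E <- rbinom(2e5, 1, plogis(cal$a + cal$b * G))
  expect_equal(cor(G, E), 0.15, tolerance = 0.02)
  expect_equal(mean(E), 0.35, tolerance = 0.01)
})

test_that("binary traits run through the same pipeline with high agreement", {
  scn <- sim_scenario(n_individuals = 4000, n_replicates = 60,
                      trait_type = "binary", seed = 61)
  rep <- run_accuracy_study(scn)
  z_icc <- rep$icc$icc[rep$icc$quantity == "z"]
  expect_true(all(z_icc > 0.99))
  # the reversed link-sign convention only flips directions; agreement holds
  scn2 <- sim_scenario(n_individuals = 4000, n_replicates = 30,
                       trait_type = "binary", binary_link_sign = "reversed",
                       seed = 62)
  rep2 <- run_accuracy_study(scn2)
  expect_true(all(rep2$icc$icc[rep2$icc$quantity == "z"] > 0.99))
})

test_that("identical scenarios give bit-identical reports", {
  scn <- sim_scenario(n_individuals = 1000, n_replicates = 25, seed = 71)
  r1 <- run_accuracy_study(scn)
  r2 <- run_accuracy_study(scn)
  expect_identical(r1$icc, r2$icc)
  scn0 <- sim_scenario(n_individuals = 1000, n_replicates = 25, seed = 72,
                       null_model = TRUE)
  expect_identical(run_null_study(scn0)$type1, run_null_study(scn0)$type1)
})

test_that("study preconditions are enforced", {
  scn <- sim_scenario(ge_corr = 0.1)
  expect_error(run_accuracy_study(scn), "no bias mechanism")
  expect_error(run_bias_study(sim_scenario(), "ge_corr"), "does not engage")
  expect_error(run_null_study(sim_scenario()), "null_model")
})

test_that("mean derived effects recover the generating effect combinations", {
  # across replicates the mean derived unexposed, exposed and marginal
  # effects should track beta_G, beta_G + beta_GE and
  # beta_G + beta_GE * mu_E within Monte-Carlo error
  scn <- sim_scenario(n_individuals = 3000, n_replicates = 150, seed = 81)
  set.seed(scn$seed)
  err <- matrix(NA_real_, scn$n_replicates, 3)
  for (i in seq_len(scn$n_replicates)) {
    dat <- simulate_replicate(scn)
    fit <- fit_all_models(dat, "quantitative")
    design <- study_design(fit$n, sum(dat$E))
    joint <- data.frame(
      beta = fit$joint$beta, se_beta = fit$joint$se_beta,
      delta = fit$joint$delta, se_delta = fit$joint$se_delta,
      corr_beta_delta = fit$joint$corr
    )
    tr <- dat$truth
    err[i, 1] <- derive_unexposed(joint)$beta_hat - tr$beta_g
    err[i, 2] <- derive_exposed(joint)$beta_hat - (tr$beta_g + tr$beta_ge)
    err[i, 3] <- derive_marginal(joint, design)$beta_hat -
      (tr$beta_g + tr$beta_ge * design$mu_e)
  }
  mc <- apply(err, 2, sd) / sqrt(nrow(err))
  expect_true(all(abs(colMeans(err)) < 4 * mc + 1e-3))
})
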