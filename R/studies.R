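#' Fit joint, stratified and marginal models to individual-level data
#'
#' The "truth" side of the validation: ordinary least-squares fits for a
#' quantitative trait (maximum-likelihood logistic fits for a binary
#' trait) of (i) the joint model `Y ~ G + E + G:E`, (ii) the
#' no-interaction model within each exposure stratum, and (iii) the
#' marginal model `Y ~ G + E` on the pooled sample. The joint fit also
#' reports the sampling correlation between the genetic and interaction
#' estimates, taken from its covariance matrix — exactly the quantity a
#' meta-analysis would carry per variant.
#'
#' @param dat A list with numeric vectors `G`, `E`, `Y` of equal length
#'   (as produced by [simulate_replicate()]).
#' @param trait_type `"quantitative"` (linear models) or `"binary"`
#'   (logistic models).
#' @return A list of class `fit_result`:
#'   `joint` (`beta`, `se_beta`, `delta`, `se_delta`, `corr`),
#'   `stratified_unexp`, `stratified_exp`, `marginal` (each `beta`, `se`,
#'   `z`, `p`, with the Wald z and two-sided normal p), `realized_mu_e`
#'   and `n`.
#' @export
fit_all_models <- function(dat, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  G <- dat$G; E <- dat$E; Y <- dat$Y
  n <- length(Y)
  stopifnot(length(G) == n, length(E) == n)
  if (!any(E == 0) || !any(E == 1)) {
    stop("empty stratum: both exposure groups must be populated",
         call. = FALSE)
  }
  if (stats::var(G[E == 0]) == 0 || stats::var(G[E == 1]) == 0) {
    stop("constant genotype in a stratum (singular design)", call. = FALSE)
  }
  df <- data.frame(Y = Y, G = G, E = E)
  fit1 <- if (trait_type == "quantitative") {
    function(formula, data) stats::lm(formula, data = data, model = FALSE)
  } else {
    function(formula, data) {
      stats::glm(formula, data = data, family = stats::binomial(),
                 model = FALSE)
    }
  }

  term_stats <- function(fit, term) {
    b <- stats::coef(fit)[[term]]
    se <- sqrt(stats::vcov(fit)[term, term])
    z <- b / se
    list(beta = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
  }

  joint_fit <- fit1(Y ~ G + E + G:E, df)
  V <- stats::vcov(joint_fit)
  co <- stats::coef(joint_fit)
  joint <- list(
    beta = co[["G"]],
    se_beta = sqrt(V["G", "G"]),
    delta = co[["G:E"]],
    se_delta = sqrt(V["G:E", "G:E"]),
    corr = V["G", "G:E"] / sqrt(V["G", "G"] * V["G:E", "G:E"])
  )

  structure(
    list(
      joint = joint,
      stratified_unexp = term_stats(fit1(Y ~ G, df[df$E == 0, ]), "G"),
      stratified_exp = term_stats(fit1(Y ~ G, df[df$E == 1, ]), "G"),
      marginal = term_stats(fit1(Y ~ G + E, df), "G"),
      realized_mu_e = mean(E),
      n = n
    ),
    class = "fit_result"
  )
}

# Internal: run the summary-level derivation on one joint fit, returning
# the same (beta, se, z, p) shape as the individual-level fits.
estimate_from_joint <- function(joint, design, n_variant) {
  jd <- data.frame(
    variant_id = "sim", beta = joint$beta, se_beta = joint$se_beta,
    delta = joint$delta, se_delta = joint$se_delta,
    corr_beta_delta = joint$corr, n_variant = n_variant
  )
  reshape <- function(d) list(beta = d$beta_hat, se = d$se_hat,
                              z = d$z, p = d$p)
  list(
    unexp = reshape(derive_unexposed(jd)),
    exp = reshape(derive_exposed(jd)),
    marg = reshape(derive_marginal(jd, design))
  )
}

analyses <- c("unexp", "exp", "marg")
quantities <- c("beta", "se", "z")

# Internal: simulate scn$n_replicates replicates, fit all models, run the
# summary-level derivation on each joint fit, and return one row per
# usable replicate with paired true/estimated statistics plus the realised
# bias magnitudes. Seeds the RNG from the scenario.
collect_replicates <- function(scn) {
  set.seed(scn$seed)
  rows <- vector("list", scn$n_replicates)
  skipped <- 0L
  for (i in seq_len(scn$n_replicates)) {
    dat <- simulate_replicate(scn)
    fit <- tryCatch(fit_all_models(dat, scn$trait_type),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- skipped + 1L
      next
    }
    design <- study_design(dat$truth$n_full, dat$truth$n_exposed_full)
    est <- estimate_from_joint(fit$joint, design, n_variant = fit$n)
    true <- list(unexp = fit$stratified_unexp, exp = fit$stratified_exp,
                 marg = fit$marginal)
    row <- list(rep = i)
    for (a in analyses) {
      for (q in c(quantities, "p")) {
        row[[paste("true", q, a, sep = "_")]] <- true[[a]][[q]]
        row[[paste("est", q, a, sep = "_")]] <- est[[a]][[q]]
      }
    }
    sd0 <- stats::sd(dat$Y[dat$E == 0])
    sd1 <- stats::sd(dat$Y[dat$E == 1])
    row$rho_ge <- stats::cor(dat$G, dat$E)
    row$rel_mu_error <- abs(dat$truth$mu_e - dat$truth$m_e) / dat$truth$mu_e
    row$sd_diff <- sd1 - sd0
    rows[[i]] <- row
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  attr(out, "n_skipped") <- skipped
  out
}

# Internal: ICC table (analysis x quantity) from a collected-replicates
# table, optionally restricted to a subset of rows.
icc_table <- function(df, idx = seq_len(nrow(df))) {
  grid <- expand.grid(analysis = analyses, quantity = quantities,
                      stringsAsFactors = FALSE)
  grid$icc <- mapply(function(a, q) {
    icc(df[[paste("true", q, a, sep = "_")]][idx],
        df[[paste("est", q, a, sep = "_")]][idx])
  }, grid$analysis, grid$quantity)
  grid[order(grid$analysis, grid$quantity), ]
}

new_agreement_report <- function(scn, df, study, extra = list()) {
  structure(
    c(list(
      study = study,
      scenario = scn,
      n_replicates_used = nrow(df),
      n_skipped = attr(df, "n_skipped")
    ), extra),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s study): %d replicates used, %d skipped\n",
              x$study, x$n_replicates_used, x$n_skipped))
  if (!is.null(x$icc)) {
    cat("\nICC (true vs summary-derived):\n")
    print(x$icc, row.names = FALSE)
  }
  if (!is.null(x$per_quintile)) {
    cat("\nPer-quintile ICC of test statistics:\n")
    wide <- stats::reshape(
      x$per_quintile[x$per_quintile$quantity == "z",
                     c("quintile", "mean_magnitude", "analysis", "icc")],
      direction = "wide", idvar = c("quintile", "mean_magnitude"),
      timevar = "analysis"
    )
    print(wide, row.names = FALSE)
  }
  if (!is.null(x$type1)) {
    cat("\nEmpirical type-I error at alpha =", x$alpha, ":\n")
    print(x$type1, row.names = FALSE)
    cat(sprintf("\nBonferroni discordance (threshold %.3g):\n",
                x$bonferroni_threshold))
    print(x$discordance, row.names = FALSE)
  }
  invisible(x)
}

#' Run the estimator-accuracy study
#'
#' The headline validation: across replicates, compares effect sizes,
#' standard errors and Wald statistics from individual-level stratified and
#' marginal regressions ("true") against the same quantities derived from
#' each replicate's joint-model summary statistics ("estimated"), and
#' reports the absolute-agreement [icc()] per analysis and quantity. With
#' independent genotype and exposure all nine ICCs are expected to be
#' essentially 1.
#'
#' @param scn A [sim_scenario()] with no bias mechanism engaged.
#' @return An `agreement_report` with element `icc`: a data frame with
#'   columns `analysis` (`unexp`, `exp`, `marg`), `quantity` (`beta`,
#'   `se`, `z`) and `icc`.
#' @export
run_accuracy_study <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (scn$ge_corr > 0 || scn$subsample_fraction < 1 ||
      scn$exposed_removal_fraction > 0 || scn$exposed_extra_noise_sd > 0) {
    stop("the accuracy study requires a scenario with no bias mechanism ",
         "engaged", call. = FALSE)
  }
  df <- collect_replicates(scn)
  if (nrow(df) < 2L) stop("fewer than 2 usable replicates", call. = FALSE)
  new_agreement_report(scn, df, "accuracy", list(icc = icc_table(df)))
}

#' Run a bias-source study, stratified by quintiles of the bias magnitude
#'
#' Re-runs the accuracy comparison under one of three bias mechanisms and
#' reports ICCs within quintiles of the realised per-replicate bias
#' magnitude: the sample genotype-exposure correlation (`"ge_corr"`), the
#' relative exposure-proportion misspecification
#' \eqn{|\mu_E - m_E| / \mu_E} (`"misspecified_mu"`), or the difference in
#' phenotypic SD between exposed and unexposed individuals
#' (`"heteroscedastic"`). Expected patterns: genotype-exposure dependence
#' leaves the stratified ICCs at ~1 and mildly degrades the marginal one;
#' exposure-proportion misspecification degrades only the marginal one;
#' heteroscedasticity leaves effect sizes unbiased but distorts the
#' stratified standard errors, increasingly so across quintiles.
#'
#' @param scn A [sim_scenario()] with the matching bias mechanism engaged.
#' @param bias_kind One of `"ge_corr"`, `"misspecified_mu"`,
#'   `"heteroscedastic"`.
#' @return An `agreement_report` with elements `icc` (overall),
#'   `per_quintile` (columns `quintile`, `mean_magnitude`, `analysis`,
#'   `quantity`, `icc`) and `se_error` (per-quintile mean absolute
#'   difference between true and derived standard errors per analysis).
#' @export
run_bias_study <- function(scn,
                           bias_kind = c("ge_corr", "misspecified_mu",
                                         "heteroscedastic")) {
  stopifnot(inherits(scn, "sim_scenario"))
  bias_kind <- match.arg(bias_kind)
  engaged <- switch(bias_kind,
    ge_corr = scn$ge_corr > 0,
    misspecified_mu = scn$subsample_fraction < 1 ||
      scn$exposed_removal_fraction > 0,
    heteroscedastic = scn$exposed_extra_noise_sd > 0
  )
  if (!engaged) {
    stop("scenario does not engage the '", bias_kind, "' mechanism",
         call. = FALSE)
  }
  df <- collect_replicates(scn)
  if (nrow(df) < 10L) stop("fewer than 10 usable replicates", call. = FALSE)

  magnitude <- switch(bias_kind,
    ge_corr = df$rho_ge,
    misspecified_mu = df$rel_mu_error,
    heteroscedastic = df$sd_diff
  )
  qs <- stats::quantile(magnitude, probs = seq(0, 1, 0.2), names = FALSE)
  quintile <- cut(magnitude, breaks = unique(qs), include.lowest = TRUE,
                  labels = FALSE)
  per_q <- lapply(sort(unique(quintile)), function(k) {
    idx <- which(quintile == k)
    tab <- icc_table(df, idx)
    tab$quintile <- k
    tab$mean_magnitude <- mean(magnitude[idx])
    se_err <- vapply(analyses, function(a) {
      mean(abs(df[[paste0("true_se_", a)]][idx] -
                 df[[paste0("est_se_", a)]][idx]))
    }, numeric(1))
    list(icc = tab,
         se_error = data.frame(quintile = k,
                               mean_magnitude = mean(magnitude[idx]),
                               analysis = analyses,
                               mean_abs_se_error = se_err,
                               row.names = NULL))
  })
  per_quintile <- do.call(rbind, lapply(per_q, `[[`, "icc"))
  per_quintile <- per_quintile[, c("quintile", "mean_magnitude", "analysis",
                                   "quantity", "icc")]
  se_error <- do.call(rbind, lapply(per_q, `[[`, "se_error"))
  new_agreement_report(scn, df, paste0("bias:", bias_kind), list(
    icc = icc_table(df),
    per_quintile = per_quintile,
    se_error = se_error,
    bias_kind = bias_kind
  ))
}

#' Run the null-model study: type-I error and significance discordance
#'
#' Simulates under the null (no genetic and no interaction effect),
#' derives stratified and marginal statistics from each replicate's joint
#' fit and reports (i) the empirical rejection rate at `alpha` for the
#' individual-level ("true") and summary-derived ("estimated") statistics
#' in each analysis, and (ii) the proportion of replicates declared
#' significant under a Bonferroni threshold (`alpha` divided by the number
#' of replicates, mirroring a per-SNP screen) by exactly one of the two
#' methods.
#'
#' @param scn A [sim_scenario()] with `null_model = TRUE` (bias mechanisms
#'   may additionally be engaged to study their effect on calibration).
#' @param alpha Nominal significance level for the rejection rates.
#' @return An `agreement_report` with elements `type1` (columns `analysis`,
#'   `rate_true`, `rate_estimated`), `discordance` (columns `analysis`,
#'   `discordant`), `alpha`, `bonferroni_threshold` and `icc`.
#' @export
run_null_study <- function(scn, alpha = 0.05) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (!scn$null_model) {
    stop("the null study requires `null_model = TRUE`", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1)
  df <- collect_replicates(scn)
  if (nrow(df) < 2L) stop("fewer than 2 usable replicates", call. = FALSE)

  thr <- alpha / nrow(df)
  type1 <- data.frame(
    analysis = analyses,
    rate_true = vapply(analyses, function(a) {
      mean(df[[paste0("true_p_", a)]] < alpha)
    }, numeric(1)),
    rate_estimated = vapply(analyses, function(a) {
      mean(df[[paste0("est_p_", a)]] < alpha)
    }, numeric(1)),
    row.names = NULL
  )
  discordance <- data.frame(
    analysis = analyses,
    discordant = vapply(analyses, function(a) {
      mean(xor(df[[paste0("true_p_", a)]] < thr,
               df[[paste0("est_p_", a)]] < thr))
    }, numeric(1)),
    row.names = NULL
  )
  new_agreement_report(scn, df, "null", list(
    icc = icc_table(df),
    type1 = type1,
    discordance = discordance,
    alpha = alpha,
    bonferroni_threshold = thr
  ))
}
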