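#' Covariance of two estimates from their correlation
#'
#' The standard-error formulas for the exposed-stratum and marginal effects
#' need the sampling covariance between the genetic main-effect estimate and
#' the interaction-effect estimate, \eqn{cov(\hat\beta, \hat\delta)}.
#' Meta-analysis output (METAL interaction dialect) reports the correlation
#' between the two estimates instead; this converts one to the other.
#'
#' @param r Correlation between the two estimates, in \[-1, 1\]. Vectorised.
#' @param s1,s2 Standard errors of the two estimates, each >= 0. Vectorised.
#' @return `r * s1 * s2`, the sampling covariance.
#' @examples
#' cov_from_corr(0.5, 0.1, 0.2)   # 0.01
#' cov_from_corr(-0.3, 0.05, 0.04)
#' @export
cov_from_corr <- function(r, s1, s2) {
  bad <- !is.na(r) & (r < -1 | r > 1)
  if (any(bad)) {
    stop(
      "correlation out of [-1, 1] at position(s) ",
      paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.na(s1) & s1 < 0) || any(!is.na(s2) & s2 < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  r * s1 * s2
}

#' Two-sided Wald test from an effect estimate and its standard error
#'
#' @param beta_hat Effect estimate(s).
#' @param se_hat Standard error(s); must be > 0 for a defined statistic.
#'   Non-positive or missing SEs yield `NA` z and p (missing-value
#'   sentinel), never an error: meta-analysed files routinely contain
#'   degenerate rows.
#' @return A `data.frame` with columns `z` (Wald statistic
#'   `beta_hat / se_hat`) and `p` (two-sided standard-normal tail
#'   probability).
#' @details p-values use the standard-normal reference rather than a t
#'   distribution: summary statistics from large meta-analyses carry no
#'   usable residual degrees of freedom.
#' @examples
#' wald_test(0.196, 0.1)   # z = 1.96, p ~ 0.05
#' @export
wald_test <- function(beta_hat, se_hat) {
  n <- max(length(beta_hat), length(se_hat))
  beta_hat <- rep_len(as.double(beta_hat), n)
  se_hat <- rep_len(as.double(se_hat), n)
  ok <- is.finite(beta_hat) & is.finite(se_hat) & se_hat > 0
  z <- rep(NA_real_, n)
  z[ok] <- beta_hat[ok] / se_hat[ok]
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(z = z, p = p)
}

# Internal: assemble a StratumStats block (beta, se, z, p) from vectors.
stratum_stats <- function(beta_hat, se_hat) {
  wt <- wald_test(beta_hat, se_hat)
  data.frame(beta_hat = beta_hat, se_hat = se_hat, z = wt$z, p = wt$p)
}

# Internal: pull the estimator covariance from a joint-statistics table,
# honouring an explicit covariance column when present (column-name driven
# dispatch) and falling back to the correlation otherwise.
joint_covariance <- function(joint) {
  if (!is.null(joint[["cov_beta_delta"]])) {
    return(as.double(joint[["cov_beta_delta"]]))
  }
  cov_from_corr(joint$corr_beta_delta, joint$se_beta, joint$se_delta)
}

#' Genetic effect in the unexposed stratum from joint-model statistics
#'
#' In a model with a full interaction between the SNP and a binary exposure,
#' the genetic main effect *is* the genetic effect among unexposed
#' individuals: \eqn{\hat\beta_{unexp} = \hat\beta},
#' \eqn{\sigma_{\hat\beta_{unexp}} = \sigma_{\hat\beta}}. For a linear trait
#' this identity is exact (the interaction model is saturated in the
#' exposure), so the returned point estimates equal a stratified
#' least-squares fit to machine precision.
#'
#' @param joint A `data.frame` of joint-model summary statistics with at
#'   least columns `beta` and `se_beta` (one row per variant; see
#'   [read_joint_file()] for the full column contract).
#' @return A `data.frame` with columns `beta_hat`, `se_hat`, `z`, `p`.
#' @export
derive_unexposed <- function(joint) {
  stratum_stats(as.double(joint$beta), as.double(joint$se_beta))
}

#' Genetic effect in the exposed stratum from joint-model statistics
#'
#' Setting the exposure indicator to 1 in the joint model gives
#' \eqn{\hat\beta_{exp} = \hat\beta + \hat\delta} with
#' \eqn{\sigma_{\hat\beta_{exp}} =
#'   \sqrt{\sigma_{\hat\beta}^2 + \sigma_{\hat\delta}^2 +
#'         2\,cov(\hat\beta,\hat\delta)}}.
#' The variance expression is a completed square, so it is non-negative for
#' any correlation in \[-1, 1\]; a negative value can only arise from
#' corrupt inputs and raises an error naming the offending variants.
#'
#' @inheritParams derive_unexposed
#' @param joint Must additionally carry `delta`, `se_delta` and either
#'   `corr_beta_delta` or `cov_beta_delta`.
#' @return A `data.frame` with columns `beta_hat`, `se_hat`, `z`, `p`.
#' @export
derive_exposed <- function(joint) {
  cv <- joint_covariance(joint)
  v <- as.double(joint$se_beta)^2 + as.double(joint$se_delta)^2 + 2 * cv
  v <- check_variance(v, joint, "exposed")
  stratum_stats(as.double(joint$beta) + as.double(joint$delta), sqrt(v))
}

#' Marginal genetic effect from joint-model statistics
#'
#' Averaging the joint model over the exposure distribution gives the SNP
#' coefficient of the no-interaction (marginal) model:
#' \eqn{\hat\beta_{marg} = \hat\beta + \hat\delta\,\mu_E} with
#' \eqn{\sigma_{\hat\beta_{marg}} =
#'   \sqrt{\sigma_{\hat\beta}^2 + \mu_E^2 \sigma_{\hat\delta}^2 +
#'         2 \mu_E\,cov(\hat\beta,\hat\delta)}},
#' where \eqn{\mu_E = N_e / N} is the exposure frequency. Requires
#' \eqn{0 < \mu_E < 1}; with an empty stratum the marginal model coincides
#' with the non-empty stratum and the design is rejected.
#'
#' @inheritParams derive_exposed
#' @param design A [study_design()] with `0 < mu_e < 1`.
#' @return A `data.frame` with columns `beta_hat`, `se_hat`, `z`, `p`.
#' @export
derive_marginal <- function(joint, design) {
  check_nondegenerate(design)
  mu <- design$mu_e
  cv <- joint_covariance(joint)
  v <- as.double(joint$se_beta)^2 + mu^2 * as.double(joint$se_delta)^2 +
    2 * mu * cv
  v <- check_variance(v, joint, "marginal")
  stratum_stats(as.double(joint$beta) + mu * as.double(joint$delta), sqrt(v))
}

# Internal: negative derived variances indicate corrupt inputs (with a
# correlation in [-1,1] the quadratic form cannot be negative beyond
# floating-point noise, which is clamped).
check_variance <- function(v, joint, label) {
  eps <- -1e-12 * pmax(1, abs(v))
  bad <- !is.na(v) & v < eps
  if (any(bad)) {
    ids <- if (!is.null(joint$variant_id)) joint$variant_id[bad] else which(bad)
    stop(
      "negative ", label, "-stratum variance for variant(s): ",
      paste(utils::head(ids, 5L), collapse = ", "),
      " (corrupt standard errors or correlation?)",
      call. = FALSE
    )
  }
  v[!is.na(v) & v < 0] <- 0
  v
}

#' Infer per-variant stratum sample sizes
#'
#' A variant's genotyped sample size \eqn{N_v} can fall short of the study
#' size \eqn{N} because of missing genotypes. Assuming missingness is
#' unrelated to exposure, the expected stratum sizes are
#' \eqn{N_v (N - N_e) / N} unexposed and \eqn{N_v N_e / N} exposed.
#' Sizes are returned as reals (expectations), not rounded, so the two
#' always sum exactly to `n_variant`.
#'
#' @param n_variant Per-variant sample size(s) \eqn{N_v}, each > 0.
#' @param design A [study_design()].
#' @return A `data.frame` with columns `n_unexposed` and `n_exposed`.
#' @examples
#' infer_stratum_sizes(1000, study_design(1000, 300))  # 700, 300
#' @export
infer_stratum_sizes <- function(n_variant, design) {
  if (!inherits(design, "study_design")) {
    stop("`design` must be a `study_design` object", call. = FALSE)
  }
  n_variant <- as.double(n_variant)
  if (any(!is.na(n_variant) & n_variant <= 0)) {
    stop("`n_variant` must be positive", call. = FALSE)
  }
  n_exp <- n_variant * design$n_exposed / design$n_total
  data.frame(n_unexposed = n_variant - n_exp, n_exposed = n_exp)
}

#' Flag variants with low relative sample size
#'
#' Variants genotyped in far fewer individuals than the rest of the screen
#' are prone to biased derivation: their realised exposure proportion can
#' drift from the study-wide \eqn{\mu_E}. The filter computes the 9th
#' decile (0.9-quantile) \eqn{Q} of the per-variant sample-size
#' distribution and flags every variant with `n_variant < Q / 1.5`.
#'
#' Rows are flagged, never deleted here; writers decide whether to drop
#' flagged rows (see [run_pipeline()]'s `keep_filtered`).
#'
#' @param n_variant Numeric vector of per-variant sample sizes; must
#'   contain at least one non-missing value.
#' @param quantile_type Quantile convention passed to [stats::quantile()].
#'   Default 7, the linear-interpolation order-statistic estimate that is
#'   the shared default of mainstream numerics stacks.
#' @return A logical vector (`TRUE` = flagged for removal) with attribute
#'   `threshold` holding \eqn{Q / 1.5}. Missing sizes are flagged.
#' @examples
#' flag <- filter_low_sample_size(c(rep(1000, 150), 500))
#' sum(flag)              # 1
#' attr(flag, "threshold")
#' @export
filter_low_sample_size <- function(n_variant, quantile_type = 7) {
  n_variant <- as.double(n_variant)
  if (length(n_variant) == 0L || all(is.na(n_variant))) {
    stop("no sample sizes to filter on (empty input)", call. = FALSE)
  }
  q9 <- stats::quantile(n_variant, probs = 0.9, na.rm = TRUE,
                        type = quantile_type, names = FALSE)
  threshold <- q9 / 1.5
  flagged <- is.na(n_variant) | n_variant < threshold
  attr(flagged, "threshold") <- threshold
  flagged
}

#' Derive the full per-variant output table
#'
#' Applies the whole conversion to a table of joint-model summary
#' statistics: stratum sample-size inference, the unexposed, exposed and
#' marginal derivations with Wald tests, and the relative sample-size
#' filter flag.
#'
#' @param joint A `data.frame` of validated joint-model statistics: columns
#'   `variant_id`, `beta`, `se_beta`, `delta`, `se_delta`,
#'   `corr_beta_delta` (or `cov_beta_delta`), `n_variant`.
#' @param design A [study_design()] with both strata populated.
#' @param apply_filter Compute the relative sample-size flag? If `FALSE`
#'   the `filtered` column is all `FALSE`.
#' @return A `data.frame` with one row per input row:
#'   `variant_id`,
#'   `n_unexp`, `beta_unexp`, `se_unexp`, `z_unexp`, `p_unexp`,
#'   `n_exp`, `beta_exp`, `se_exp`, `z_exp`, `p_exp`,
#'   `n_marg`, `beta_marg`, `se_marg`, `z_marg`, `p_marg`,
#'   `filtered`.
#' @examples
#' joint <- data.frame(
#'   variant_id = "rs1", beta = 0.1, se_beta = 0.03,
#'   delta = 0.05, se_delta = 0.04, corr_beta_delta = -0.5,
#'   n_variant = 9000
#' )
#' derive_stratified_stats(joint, study_design(10000, 3000))
#' @export
derive_stratified_stats <- function(joint, design, apply_filter = TRUE) {
  check_nondegenerate(design)
  if (nrow(joint) == 0L) stop("no records", call. = FALSE)
  sizes <- infer_stratum_sizes(joint$n_variant, design)
  unexp <- derive_unexposed(joint)
  expo <- derive_exposed(joint)
  marg <- derive_marginal(joint, design)
  filtered <- if (apply_filter) {
    as.logical(filter_low_sample_size(joint$n_variant))
  } else {
    rep(FALSE, nrow(joint))
  }
  out <- data.frame(
    variant_id = as.character(joint$variant_id),
    n_unexp = sizes$n_unexposed,
    beta_unexp = unexp$beta_hat, se_unexp = unexp$se_hat,
    z_unexp = unexp$z, p_unexp = unexp$p,
    n_exp = sizes$n_exposed,
    beta_exp = expo$beta_hat, se_exp = expo$se_hat,
    z_exp = expo$z, p_exp = expo$p,
    n_marg = as.double(joint$n_variant),
    beta_marg = marg$beta_hat, se_marg = marg$se_hat,
    z_marg = marg$z, p_marg = marg$p,
    filtered = filtered,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
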