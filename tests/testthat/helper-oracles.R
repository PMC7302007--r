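# Independent oracles and fixture builders shared across the suite.

# Brute-force type-7 (linear interpolation between order statistics)
# quantile, written from the order-statistic definition rather than
# stats::quantile, to cross-check the filter's quantile convention.
oracle_quantile_type7 <- function(x, prob) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force two-way ANOVA ICC(A,1) via stats::aov mean squares — an
# independent route to the same agreement coefficient.
oracle_icc_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(
    value = c(x, y),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# A small deterministic table of joint-model summary statistics.
make_joint_table <- function(n = 5, seed = 42) {
  set.seed(seed)
  data.frame(
    variant_id = sprintf("rs%04d", seq_len(n)),
    beta = round(stats::rnorm(n, 0, 0.1), 4),
    se_beta = round(stats::runif(n, 0.01, 0.05), 4),
    delta = round(stats::rnorm(n, 0, 0.1), 4),
    se_delta = round(stats::runif(n, 0.01, 0.08), 4),
    corr_beta_delta = round(stats::runif(n, -0.9, 0.9), 4),
    n_variant = sample(5000:10000, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Write a joint table to a METAL-style tab-delimited file (optionally
# gzipped) using the package's default header names.
write_joint_fixture <- function(joint, path, gzip = FALSE) {
  out <- data.frame(
    MarkerName = joint$variant_id,
    Effect = joint$beta,
    StdErr = joint$se_beta,
    IntEffect = joint$delta,
    IntStdErr = joint$se_delta,
    IntCor = joint$corr_beta_delta,
    Weight = joint$n_variant,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     compress = if (gzip) "gzip" else "none")
  path
}

# Simulate one small individual-level dataset with known coefficients.
make_individual_data <- function(n = 2000, maf = 0.3, p_exposed = 0.4,
                                 beta_g = 0.1, beta_e = 0.1, beta_ge = 0.1,
                                 sd = 1, seed = 1) {
  set.seed(seed)
  G <- stats::rbinom(n, 2, maf)
  E <- stats::rbinom(n, 1, p_exposed)
  Y <- beta_g * G + beta_e * E + beta_ge * G * E + stats::rnorm(n, 0, sd)
  list(G = G, E = E, Y = Y)
}
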