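#' Intraclass correlation coefficient (two-way, absolute agreement)
#'
#' Agreement between two paired series of measurements of the same
#' quantities — here, statistics computed from individual-level data and
#' the same statistics reconstructed from joint-model summaries. This is
#' the single-measurement, two-way random-effects, *absolute agreement*
#' ICC (often written ICC(A,1)): unlike a Pearson or consistency-type
#' coefficient it penalises systematic shifts between the two series, which
#' is the property that makes it an agreement measure.
#'
#' With \eqn{n} paired subjects and \eqn{k = 2} raters,
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the rows (subjects),
#' columns (raters) and residual mean squares of the two-way ANOVA
#' decomposition.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with finite entries.
#' @return A single number in \[-1, 1\]; exactly 1 when `x == y`
#'   elementwise with positive variance; `NA` when the total variance is
#'   zero (agreement undefined).
#' @examples
#' icc(1:3, 1:3)            # 1
#' icc(1:10, 1:10 + 100)    # far below 1: absolute agreement penalises bias
#' @export
icc <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("need at least 2 paired observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  n <- length(x)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- m - matrix(row_m, n, k) -
    matrix(col_m, n, k, byrow = TRUE) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (!is.finite(denom) || denom <= .Machine$double.eps * max(1, msr)) {
    return(NA_real_)
  }
  (msr - mse) / denom
}
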