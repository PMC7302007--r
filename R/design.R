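#' Describe the study design of a gene-environment interaction screen
#'
#' Bundles the total sample size \eqn{N}, the number of exposed individuals
#' \eqn{N_e} and the implied exposure frequency \eqn{\mu_E = N_e / N}.
#' These two scalars are the only study-level inputs the derivation needs:
#' they drive the per-variant stratum sample-size split and the marginal
#' effect reconstruction.
#'
#' @param n_total Total sample size \eqn{N} of the study (positive integer).
#' @param n_exposed Number of exposed individuals \eqn{N_e}, between 0 and
#'   `n_total`.
#' @return An object of class `study_design`: a list with elements
#'   `n_total`, `n_exposed` and `mu_e`.
#' @examples
#' design <- study_design(n_total = 10000, n_exposed = 3000)
#' design$mu_e  # 0.3
#' @export
study_design <- function(n_total, n_exposed) {
  if (length(n_total) != 1L || !is.finite(n_total) || n_total <= 0 ||
      n_total != trunc(n_total)) {
    stop("`n_total` must be a single positive integer", call. = FALSE)
  }
  if (length(n_exposed) != 1L || !is.finite(n_exposed) || n_exposed < 0 ||
      n_exposed > n_total || n_exposed != trunc(n_exposed)) {
    stop("`n_exposed` must be a single integer in [0, n_total]", call. = FALSE)
  }
  structure(
    list(
      n_total = as.double(n_total),
      n_exposed = as.double(n_exposed),
      mu_e = n_exposed / n_total
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: N = %d, N_e = %d (exposure frequency mu_e = %.4g)\n",
    as.integer(x$n_total), as.integer(x$n_exposed), x$mu_e
  ))
  invisible(x)
}

# Internal: require a non-degenerate design (both strata populated), as
# needed by the exposed/marginal derivations.
check_nondegenerate <- function(design) {
  if (!inherits(design, "study_design")) {
    stop("`design` must be a `study_design` object", call. = FALSE)
  }
  if (design$mu_e <= 0 || design$mu_e >= 1) {
    stop(
      "degenerate study design: exposure frequency mu_e must lie strictly ",
      "between 0 and 1 (one stratum is empty; the marginal model equals ",
      "the non-empty stratum)",
      call. = FALSE
    )
  }
  invisible(design)
}
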