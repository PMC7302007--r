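#' Default column mapping for METAL-style interaction output
#'
#' Maps the roles the derivation needs onto the header names used by the
#' METAL interaction-analysis output lineage. Consortium files vary in
#' naming, so every entry can be overridden (see [read_joint_file()]).
#' The `cov_beta_delta` role is optional: when its column is present it is
#' used directly as the sampling covariance between the two estimates;
#' otherwise the covariance is reconstructed from `corr_beta_delta` via
#' [cov_from_corr()].
#'
#' @return A named character vector mapping roles (`variant_id`, `beta`,
#'   `se_beta`, `delta`, `se_delta`, `corr_beta_delta`, `cov_beta_delta`,
#'   `n_variant`) to header names.
#' @export
default_column_map <- function() {
  c(
    variant_id = "MarkerName",
    beta = "Effect",
    se_beta = "StdErr",
    delta = "IntEffect",
    se_delta = "IntStdErr",
    corr_beta_delta = "IntCor",
    cov_beta_delta = "IntCov",
    n_variant = "Weight"
  )
}

# Gzip magic bytes 1f 8b at the start of the file.
is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Roles that must resolve to a column; one of corr/cov suffices.
required_roles <- c("variant_id", "beta", "se_beta", "delta", "se_delta",
                    "n_variant")

#' Read a file of joint-model summary statistics
#'
#' Reads a tab-delimited (optionally gzipped) file of per-variant summary
#' statistics from a joint SNP + SNP-by-exposure model — the METAL
#' meta-analysis interaction dialect — and validates each row. Rows that
#' violate the numeric invariants (missing or non-finite estimates,
#' negative standard errors, correlation outside \[-1, 1\], non-positive
#' sample size) are kept with `valid = FALSE` and a reason, never silently
#' dropped; downstream derivation emits missing-value sentinels for them.
#'
#' @param path Path to the input file. Compression is handled
#'   transparently.
#' @param column_map Named character vector mapping roles to header names;
#'   entries override [default_column_map()]. Either the correlation or the
#'   covariance column must be present in the header.
#' @return A `data.table` with the standardised columns `variant_id`,
#'   `beta`, `se_beta`, `delta`, `se_delta`, `corr_beta_delta` (and/or
#'   `cov_beta_delta`), `n_variant`, `valid`, `invalid_reason`, followed by
#'   any unmapped input columns carried through unmodified.
#' @export
read_joint_file <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  map <- default_column_map()
  if (length(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown)) {
      stop("unknown column-map role(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  read_path <- path
  if (is_gzip(path)) {
    # decompress through a base connection; fread then sees plain text
    read_path <- tempfile(fileext = ".tsv")
    on.exit(unlink(read_path), add = TRUE)
    inc <- gzfile(path, "rb")
    outc <- file(read_path, "wb")
    while (length(chunk <- readBin(inc, "raw", n = 1048576L)) > 0) {
      writeBin(chunk, outc)
    }
    close(inc)
    close(outc)
  }
  dt <- data.table::fread(read_path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "", "."), showProgress = FALSE)
  if (nrow(dt) == 0L) stop("no records in ", path, call. = FALSE)

  hdr <- names(dt)
  missing_req <- map[required_roles][!(map[required_roles] %in% hdr)]
  has_corr <- map[["corr_beta_delta"]] %in% hdr
  has_cov <- map[["cov_beta_delta"]] %in% hdr
  if (length(missing_req) || !(has_corr || has_cov)) {
    need <- c(map[required_roles],
              paste0(map[["corr_beta_delta"]], " or ", map[["cov_beta_delta"]]))
    stop(
      "required column(s) not found.\n  expected: ",
      paste(need, collapse = ", "),
      "\n  found:    ", paste(hdr, collapse = ", "),
      call. = FALSE
    )
  }

  roles <- c(required_roles,
             if (has_corr) "corr_beta_delta",
             if (has_cov) "cov_beta_delta")
  out <- dt[, map[roles], with = FALSE]
  data.table::setnames(out, roles)
  passthrough <- setdiff(hdr, map[roles])
  if (length(passthrough)) out <- cbind(out, dt[, passthrough, with = FALSE])

  out[, variant_id := as.character(variant_id)]
  num_cols <- setdiff(roles, "variant_id")
  for (cc in num_cols) data.table::set(out, j = cc, value = as.double(out[[cc]]))

  reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reason[cond & is.na(reason)] <<- why
    cond
  }
  core <- c("beta", "se_beta", "delta", "se_delta",
            if (has_corr) "corr_beta_delta" else "cov_beta_delta")
  miss <- Reduce(`|`, lapply(core, function(cc) !is.finite(out[[cc]])))
  flag(miss, "missing or non-finite estimate")
  flag(out$se_beta < 0 | out$se_delta < 0, "negative standard error")
  if (has_corr) {
    flag(out$corr_beta_delta < -1 | out$corr_beta_delta > 1,
         "correlation outside [-1, 1]")
  }
  flag(!is.finite(out$n_variant) | out$n_variant <= 0,
       "non-positive or missing sample size")

  out[, valid := is.na(reason)]
  out[, invalid_reason := reason]
  out[]
}

#' Run the full derivation pipeline on a summary-statistics file
#'
#' Reads joint-model summary statistics, applies the relative sample-size
#' filter, derives unexposed / exposed / marginal statistics for every
#' variant and writes a single tab-delimited output file. Invalid rows are
#' written with `NA` sentinels in the derived columns and counted; by
#' default rows flagged by the filter are excluded from the output.
#'
#' @param input,output Paths to the input and output files.
#' @param n_total,n_exposed Study-level sample sizes \eqn{N} and
#'   \eqn{N_e}; both strata must be non-empty.
#' @param column_map Passed to [read_joint_file()].
#' @param keep_filtered Keep rows flagged by the sample-size filter in the
#'   output (their `filtered` column records the flag)? Default drops them.
#' @param apply_filter Apply the 9th-decile/1.5 sample-size filter at all?
#' @param max_row_warnings Cap on per-row invalidity messages; the rest are
#'   summarised (genome-wide files have millions of rows).
#' @param quiet Suppress progress messages (row warnings are still capped).
#' @return Invisibly, a list of counts: `read`, `invalid`,
#'   `flagged_by_filter`, `dropped_by_filter`, `written`. Always
#'   `read == written + dropped_by_filter`.
#' @export
run_pipeline <- function(input, output, n_total, n_exposed,
                         column_map = default_column_map(),
                         keep_filtered = FALSE, apply_filter = TRUE,
                         max_row_warnings = 10L, quiet = FALSE) {
  design <- study_design(n_total, n_exposed)
  check_nondegenerate(design)

  joint <- read_joint_file(input, column_map)
  n_read <- nrow(joint)
  n_invalid <- sum(!joint$valid)

  if (n_invalid > 0) {
    bad <- which(!joint$valid)
    for (i in utils::head(bad, max_row_warnings)) {
      message(sprintf("row %d (%s): %s; derived statistics set to NA",
                      i, joint$variant_id[i], joint$invalid_reason[i]))
    }
    if (n_invalid > max_row_warnings) {
      message(sprintf("... and %d further invalid rows",
                      n_invalid - max_row_warnings))
    }
  }

  # Mask invalid fields so derivation propagates NA instead of erroring on
  # out-of-range values.
  masked <- data.table::as.data.table(joint)
  bad <- !masked$valid
  if (any(bad)) {
    for (cc in intersect(
      c("beta", "se_beta", "delta", "se_delta", "corr_beta_delta",
        "cov_beta_delta"),
      names(masked)
    )) {
      fld <- masked[[cc]]
      fld[bad & (!is.finite(fld) | (cc == "corr_beta_delta" & abs(fld) > 1) |
                   (cc %in% c("se_beta", "se_delta") & fld < 0))] <- NA_real_
      data.table::set(masked, j = cc, value = fld)
    }
    nv <- masked$n_variant
    nv[bad & (!is.finite(nv) | nv <= 0)] <- NA_real_
    data.table::set(masked, j = "n_variant", value = nv)
  }

  flagged <- if (apply_filter) {
    filter_low_sample_size(masked$n_variant)
  } else {
    rep(FALSE, n_read)
  }
  n_flagged <- sum(flagged)

  keep <- if (keep_filtered) rep(TRUE, n_read) else !flagged
  derived <- derive_stratified_stats(masked[keep, ], design,
                                     apply_filter = FALSE)
  derived$filtered <- flagged[keep]

  # an invalid row is emitted, but every derived statistic is a sentinel
  inv_kept <- !masked$valid[keep]
  if (any(inv_kept)) {
    stat_cols <- grep("^(beta|se|z|p)_", names(derived))
    derived[inv_kept, stat_cols] <- NA_real_
  }

  num <- vapply(derived, is.double, logical(1))
  derived[num] <- lapply(derived[num], signif, digits = 6)
  data.table::fwrite(derived, output, sep = "\t", na = "NA", quote = FALSE)

  counts <- list(
    read = n_read,
    invalid = n_invalid,
    flagged_by_filter = n_flagged,
    dropped_by_filter = if (keep_filtered) 0L else n_flagged,
    written = nrow(derived)
  )
  if (!quiet) {
    message(sprintf(
      "read %d rows (%d invalid); filter flagged %d, dropped %d; wrote %d rows to %s",
      counts$read, counts$invalid, counts$flagged_by_filter,
      counts$dropped_by_filter, counts$written, output
    ))
  }
  invisible(counts)
}
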