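#' Column system-suitability test
#'
#' Compares measured CHI(IAM) values of the suitability compounds against
#' their reference values.  A compound fails when |measured - reference|
#' exceeds the tolerance (default 5 CHI units, strict inequality); the
#' column passes overall only if every compared compound passes.  Reference
#' compounds without a measurement are reported as missing, not failed.
#'
#' Two reference generations exist: the old-column values and the updated
#' values established for the new silica support (basic compounds retain
#' less strongly on the better-endcapped new phase, so their reference CHI
#' values were lowered).
#'
#' @param measured Named numeric vector of measured CHI values (names are
#'   compound names), or a data frame with `name` and `chi` columns.
#' @param reference Reference table, default the packaged suitability set
#'   (`load_fixture("table3")`).
#' @param use_new_values Use the updated (new-column) reference CHI values
#'   (default `TRUE`); otherwise the old-column values.
#' @param tolerance Pass tolerance in CHI units (> 0), default 5.
#' @return An object of class `"suitability_report"`: a list with the
#'   per-compound table (`$results`), `$overall_pass`, `$missing` and the
#'   parameters used.
#' @examples
#' ref <- load_fixture("table3")
#' ok <- setNames(ref$chi_new_reference, ref$name)
#' run_system_suitability(ok)$overall_pass  # TRUE
#' @export
run_system_suitability <- function(measured,
                                   reference = load_fixture("table3"),
                                   use_new_values = TRUE,
                                   tolerance = 5) {
  if (is.data.frame(measured))
    measured <- stats::setNames(measured$chi, measured$name)
  if (is.null(names(measured)))
    stop("measured CHI values must be named by compound", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  ref_chi <- if (use_new_values) reference$chi_new_reference
             else reference$chi_reference
  key <- compound_key(reference$name)
  mkey <- compound_key(names(measured))
  idx <- match(key, mkey)
  compared <- !is.na(idx)
  if (!any(compared))
    stop("no measured compound matches the reference set", call. = FALSE)
  res <- data.frame(name = reference$name[compared],
                    acid_base_class = reference$acid_base_class[compared],
                    chi_reference = ref_chi[compared],
                    chi_measured = as.numeric(measured[idx[compared]]))
  res$deviation <- res$chi_measured - res$chi_reference
  res$pass <- abs(res$deviation) <= tolerance
  structure(list(results = res,
                 missing = reference$name[!compared],
                 overall_pass = all(res$pass),
                 tolerance = tolerance,
                 reference_era = if (use_new_values) "new" else "old"),
            class = "suitability_report")
}

#' @export
print.suitability_report <- function(x, ...) {
  cat(sprintf("System suitability (%s reference values, tolerance %g CHI units)\n",
              x$reference_era, x$tolerance))
  df <- x$results
  df$verdict <- ifelse(df$pass, "pass", "FAIL")
  print(df[c("name", "chi_reference", "chi_measured", "deviation",
             "verdict")], digits = 3, row.names = FALSE)
  if (length(x$missing))
    cat("  not measured:", paste(x$missing, collapse = ", "), "\n")
  cat(sprintf("Overall: %s\n", if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Paired-column CHI comparison
#'
#' Ordinary least squares of one column's CHI values on another's, with the
#' outlier rule used for cross-batch comparisons: after a single full-data
#' fit (no iterative refitting), compounds whose absolute residual exceeds
#' twice the standard error of the estimate (SEE, n - 2 denominator) are
#' flagged.  Pearson r and r^2 are both reported (printed "correlation
#' coefficients" in the field are r; squared values are r^2).
#'
#' The regression direction is new-on-reference by default (`chi_b` on
#' `chi_a`); swap the arguments for the other convention.
#'
#' @param name Compound names.
#' @param chi_a CHI values on the reference (x) column.
#' @param chi_b CHI values on the compared (y) column.
#' @param exclude Optional compound names to leave out before fitting (an
#'   explicit input, so published exclusion lists are reproducible).
#' @return A `"column_comparison"` object with `n`, `pearson_r`,
#'   `r_squared`, `slope`, `intercept`, `see`, `outliers`, `max_abs_diff`
#'   (over the raw included pairs), `excluded` and the per-compound table.
#' @examples
#' tab <- load_fixture("table4")
#' cmp <- compare_columns(tab$name, tab$chi_iam_ref, tab$chi_iam_r20511)
#' cmp$slope
#' @export
compare_columns <- function(name, chi_a, chi_b, exclude = NULL) {
  stopifnot(length(name) == length(chi_a), length(chi_a) == length(chi_b))
  key <- compound_key(name)
  inc <- !(key %in% compound_key(exclude))
  d <- data.frame(name = name[inc], chi_a = chi_a[inc], chi_b = chi_b[inc])
  if (nrow(d) < 3)
    stop("need >= 3 pairs after exclusion", call. = FALSE)
  if (stats::var(d$chi_a) == 0)
    stop("singular fit: zero variance in chi_a", call. = FALSE)
  fit <- stats::lm(chi_b ~ chi_a, data = d)
  res <- stats::resid(fit)
  see <- sqrt(sum(res^2) / (nrow(d) - 2))
  r <- stats::cor(d$chi_a, d$chi_b)
  d$residual <- res
  # the floor keeps numerically-perfect fits from flagging rounding noise
  d$outlier <- abs(res) > pmax(2 * see, 1e-8 * max(1, diff(range(d$chi_b))))
  structure(list(n = nrow(d), pearson_r = r, r_squared = r^2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 see = see,
                 outliers = d$name[d$outlier],
                 max_abs_diff = max(abs(d$chi_b - d$chi_a)),
                 excluded = if (is.null(exclude)) character(0)
                            else as.character(exclude),
                 pairs = d),
            class = "column_comparison")
}

#' @export
print.column_comparison <- function(x, ...) {
  cat(sprintf("Paired-column CHI comparison (n = %d)\n", x$n))
  cat(sprintf("  chi_b = %.3f + %.3f * chi_a;  r = %.3f (r^2 = %.3f)\n",
              x$intercept, x$slope, x$pearson_r, x$r_squared))
  cat(sprintf("  SEE = %.2f CHI units (2xSEE outlier threshold %.2f); max |diff| = %.2f\n",
              x$see, 2 * x$see, x$max_abs_diff))
  cat("  outliers:", if (length(x$outliers))
    paste(x$outliers, collapse = ", ") else "none", "\n")
  if (length(x$excluded))
    cat("  excluded before fitting:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.column_comparison <- function(x, ...) {
  d <- x$pairs
  graphics::plot(d$chi_a, d$chi_b, pch = 19,
                 col = ifelse(d$outlier, "red3", "grey30"),
                 xlab = "CHI(IAM), reference column",
                 ylab = "CHI(IAM), compared column", ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  graphics::abline(0, 1, col = "forestgreen", lty = 2)
  invisible(x)
}

#' Batch-to-batch reproducibility
#'
#' Exact per-compound CHI differences between two column batches, sorted by
#' decreasing absolute difference.
#'
#' @param name Compound names.
#' @param chi_batch1,chi_batch2 CHI values on the two batches.
#' @return A list with `max_abs_diff` and the sorted `differences` table.
#' @export
batch_reproducibility <- function(name, chi_batch1, chi_batch2) {
  stopifnot(length(name) >= 1,
            length(chi_batch1) == length(name),
            length(chi_batch2) == length(name))
  d <- data.frame(name = name, chi_batch1 = chi_batch1,
                  chi_batch2 = chi_batch2,
                  diff = chi_batch2 - chi_batch1)
  d <- d[order(-abs(d$diff)), ]
  list(max_abs_diff = max(abs(d$diff)), differences = d)
}
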