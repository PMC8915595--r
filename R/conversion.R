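#' Fit the CHI(IAM) to log K(IAM) conversion
#'
#' Reconstructs the mapping from the CHI(IAM) scale (acetonitrile %) to the
#' octanol/water-comparable log K(IAM) lipophilicity scale from paired
#' calibration values.  The paired values printed for the standard mixture
#' are visibly convex, so the default parametric form is an exponential with
#' offset, log K = a * exp(b * CHI) + c, fitted by Levenberg-Marquardt
#' nonlinear least squares.  A shape-preserving monotone (Hyman-filtered
#' cubic) interpolant is available as an alternative form and as the
#' automatic fallback when the nonlinear fit fails to converge.
#'
#' Beyond 10 CHI units outside the calibration range the fitted curve is
#' continued linearly with its end slope, so that the exponential arm does
#' not explode for strongly retained compounds (observed CHI values run up
#' to ~62 while the calibration set stops at 49.4).
#'
#' @param pairs Data frame with columns `chi_ref` and `logk_iam_ref`
#'   (>= 4 rows, distinct CHI, jointly monotone), e.g.
#'   `load_fixture("table1")`.
#' @param form `"exponential"` (default) or `"monotone"` interpolant.
#' @param fallback If `TRUE` (default) fall back to the monotone interpolant
#'   when the nonlinear fit does not converge; if `FALSE`, raise an error.
#' @return Object of class `"chi_logk_conversion"` with elements `form`,
#'   `parameters` (a, b, c for the exponential form), `calibration_pairs`,
#'   `range` (calibration CHI range) and `max_fit_error`.
#' @examples
#' conv <- chi_logk_conversion(load_fixture("table1"))
#' predict(conv, newdata = c(2.9, 32, 49.4))
#' @export
chi_logk_conversion <- function(pairs, form = c("exponential", "monotone"),
                                fallback = TRUE) {
  form <- match.arg(form)
  pairs <- as.data.frame(pairs)
  if (!all(c("chi_ref", "logk_iam_ref") %in% names(pairs)))
    stop("pairs must have columns chi_ref and logk_iam_ref", call. = FALSE)
  pairs <- pairs[order(pairs$chi_ref), , drop = FALSE]
  chi <- pairs$chi_ref
  logk <- pairs$logk_iam_ref
  if (length(chi) < 4) stop("need >= 4 calibration pairs", call. = FALSE)
  if (anyDuplicated(chi)) stop("CHI values must be distinct", call. = FALSE)
  if (any(diff(logk) <= 0))
    stop("calibration pairs are not strictly monotone in CHI", call. = FALSE)

  if (form == "exponential") {
    fit <- tryCatch(fit_exponential_offset(chi, logk),
                    error = function(e) NULL)
    if (is.null(fit) || fit$parameters[["b"]] <= 0) {
      if (!fallback)
        stop("nonlinear conversion fit failed to converge", call. = FALSE)
      form <- "monotone"
    } else {
      params <- fit$parameters
    }
  }
  if (form == "monotone") {
    params <- NULL
  }
  obj <- structure(list(form = form,
                        parameters = if (form == "exponential") params,
                        calibration_pairs = pairs,
                        range = range(chi),
                        max_fit_error = NA_real_),
                   class = "chi_logk_conversion")
  obj$max_fit_error <- max(abs(eval_conversion(obj, chi) - logk))
  obj
}

# log-linearized start (regress log(logk - min + eps) on chi), then
# Levenberg-Marquardt refinement
fit_exponential_offset <- function(chi, logk) {
  c0 <- min(logk) - 0.25 * diff(range(logk))
  sl <- stats::coef(stats::lm(log(logk - c0) ~ chi))
  start <- list(a = exp(unname(sl[1])), b = unname(sl[2]), c = c0)
  fit <- minpack.lm::nlsLM(logk ~ a * exp(b * chi) + c,
                           data = data.frame(chi = chi, logk = logk),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  list(parameters = as.list(stats::coef(fit)))
}

# core evaluator; linear continuation of the end slope beyond +-10 CHI units
# outside the calibration range
eval_conversion <- function(object, chi) {
  lo <- object$range[1] - 10
  hi <- object$range[2] + 10
  if (object$form == "exponential") {
    p <- object$parameters
    f <- function(x) p$a * exp(p$b * x) + p$c
    df <- function(x) p$a * p$b * exp(p$b * x)
  } else {
    cp <- object$calibration_pairs
    sf <- stats::splinefun(cp$chi_ref, cp$logk_iam_ref, method = "hyman")
    f <- function(x) sf(pmin(pmax(x, object$range[1]), object$range[2])) +
      ifelse(x > object$range[2], (x - object$range[2]) *
               sf(object$range[2], deriv = 1), 0) +
      ifelse(x < object$range[1], (x - object$range[1]) *
               sf(object$range[1], deriv = 1), 0)
    df <- function(x) sf(pmin(pmax(x, object$range[1]), object$range[2]),
                         deriv = 1)
  }
  out <- numeric(length(chi))
  mid <- chi >= lo & chi <= hi
  out[mid] <- f(chi[mid])
  out[chi > hi] <- f(hi) + df(hi) * (chi[chi > hi] - hi)
  out[chi < lo] <- f(lo) + df(lo) * (chi[chi < lo] - lo)
  out
}

#' Convert CHI(IAM) values to log K(IAM)
#'
#' Evaluates a fitted [chi_logk_conversion()].  Values outside the
#' calibration CHI range are permitted (the observed drug set extends from
#' about -15 to 62 CHI) but are flagged: the result carries an
#' `"extrapolated"` attribute and a warning is issued.
#'
#' @param object A `"chi_logk_conversion"` object.
#' @param newdata Numeric CHI values (or data frame with a `chi` column).
#' @param quiet Suppress the extrapolation warning.
#' @param ... Ignored.
#' @return Numeric log K(IAM) values with logical attribute `extrapolated`.
#' @export
predict.chi_logk_conversion <- function(object, newdata, quiet = FALSE, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$chi
  extra <- newdata < object$range[1] | newdata > object$range[2]
  if (any(extra) && !quiet)
    warning(sprintf("%d CHI value(s) outside the calibration range [%g, %g]; extrapolated",
                    sum(extra), object$range[1], object$range[2]),
            call. = FALSE)
  structure(eval_conversion(object, newdata), extrapolated = extra)
}

#' @export
print.chi_logk_conversion <- function(x, ...) {
  cat("CHI(IAM) -> log K(IAM) conversion\n")
  if (x$form == "exponential") {
    p <- x$parameters
    cat(sprintf("  form: log K = %.4f * exp(%.5f * CHI) + %.4f\n",
                p$a, p$b, p$c))
  } else {
    cat("  form: monotone (Hyman) interpolant through the calibration pairs\n")
  }
  cat(sprintf("  calibration range: [%g, %g] CHI; max fit error %.4f log units\n",
              x$range[1], x$range[2], x$max_fit_error))
  invisible(x)
}

#' @rdname chi_logk_conversion
#' @param object A fitted conversion.
#' @param path JSON file path.
#' @param id Registry identifier stored in the document.
#' @export
write_conversion <- function(object, path, id = "chi_to_logk_iam/table1_default") {
  stopifnot(inherits(object, "chi_logk_conversion"))
  doc <- list(id = id, form = object$form, parameters = object$parameters,
              calibration_pairs = object$calibration_pairs[
                c("chi_ref", "logk_iam_ref")],
              max_fit_error = object$max_fit_error)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname chi_logk_conversion
#' @export
read_conversion <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- as.data.frame(doc$calibration_pairs)
  obj <- structure(list(form = doc$form,
                        parameters = if (doc$form == "exponential")
                          as.list(doc$parameters),
                        calibration_pairs = pairs[order(pairs$chi_ref), ],
                        range = range(pairs$chi_ref),
                        max_fit_error = doc$max_fit_error),
                   class = "chi_logk_conversion")
  obj
}

# cached package default: exponential conversion fitted to the shipped
# calibration-standard pairs
.iamdist_cache <- new.env(parent = emptyenv())

#' Package default CHI -> log K(IAM) conversion
#'
#' The exponential-offset conversion fitted to the shipped calibration
#' standards (computed once per session and cached).
#' @return A `"chi_logk_conversion"` object.
#' @export
default_conversion <- function() {
  if (is.null(.iamdist_cache$conv))
    .iamdist_cache$conv <- chi_logk_conversion(load_fixture("table1"))
  .iamdist_cache$conv
}
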