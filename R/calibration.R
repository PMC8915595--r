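#' Isocratic retention factor
#'
#' Computes the dimensionless retention factor k = (tR - t0) / t0 from a
#' retention time and the column dead time.  A compound eluting at exactly
#' twice the dead time has k = 1 (log k = 0), i.e. it is equally distributed
#' between the mobile and the stationary phase.
#'
#' @param retention_time Retention time tR in minutes.
#' @param dead_time Column dead time t0 in minutes; must be positive and no
#'   larger than `retention_time`.  There is no default: the dead time is a
#'   property of the column/instrument and must be supplied per run.
#' @return Numeric retention factor(s), >= 0.
#' @examples
#' retention_factor(4, 1)   # 3
#' retention_factor(2, 1)   # 1, i.e. log k = 0
#' @export
retention_factor <- function(retention_time, dead_time) {
  if (!is.numeric(retention_time) || !is.numeric(dead_time))
    stop("retention_time and dead_time must be numeric", call. = FALSE)
  if (any(dead_time <= 0))
    stop("dead_time must be positive", call. = FALSE)
  if (any(retention_time < dead_time))
    stop("retention_time < dead_time: dead time is mis-assigned", call. = FALSE)
  (retention_time - dead_time) / dead_time
}

#' CHI from an isocratic log k series
#'
#' Fits the linear relation log k = log k0 + b * phi between the logarithmic
#' retention factor and the acetonitrile volume percentage phi, and returns
#' the CHI value: the acetonitrile percentage at which log k = 0 (retention
#' time equal to twice the dead time).  The extrapolated intercept log k0 is
#' the aqueous (0 % acetonitrile) retention.
#'
#' @param fraction Acetonitrile volume percentages (0-100), at least two
#'   distinct values.
#' @param logk Logarithmic retention factors at those percentages.
#' @return An object of class `"iam_isocratic"`: a list with elements
#'   `chi` (= -log k0 / slope), `logk0`, `slope` and `n`.
#' @examples
#' isocratic_chi(c(10, 30, 50), c(0.8, 0.4, 0.0))$chi  # 50
#' @export
isocratic_chi <- function(fraction, logk) {
  if (length(fraction) != length(logk))
    stop("fraction and logk must have equal length", call. = FALSE)
  if (length(unique(fraction)) < 2)
    stop("need >= 2 distinct acetonitrile fractions", call. = FALSE)
  if (any(fraction < 0 | fraction > 100))
    stop("acetonitrile fractions must lie within [0, 100]", call. = FALSE)
  fit <- stats::lm(logk ~ fraction)
  b <- unname(stats::coef(fit)[2])
  logk0 <- unname(stats::coef(fit)[1])
  if (!is.finite(b) || b >= 0)
    stop("degenerate series: log k must decrease with organic modifier",
         call. = FALSE)
  structure(list(chi = -logk0 / b, logk0 = logk0, slope = b,
                 n = length(fraction)),
            class = "iam_isocratic")
}

#' @export
print.iam_isocratic <- function(x, ...) {
  cat(sprintf("Isocratic CHI: %.2f  (log k0 = %.3f, slope = %.4f, n = %d)\n",
              x$chi, x$logk0, x$slope, x$n))
  invisible(x)
}

#' Gradient retention-time to CHI calibration
#'
#' Fits the linear calibration used to convert gradient retention times into
#' CHI(IAM) values.  The reference CHI values of a standard mixture (nine
#' alkylphenones plus acetanilide and paracetamol in the canonical set) are
#' regressed on their measured gradient retention times by ordinary least
#' squares; the slope and intercept of that line then map any retention time
#' measured in the same run onto the CHI scale.
#'
#' CHI is the response: the calibration curve is used to predict CHI for new
#' compounds.  Standards are unweighted.  Negative predicted CHI values are
#' legal (very polar compounds extrapolate below zero) and are not truncated.
#'
#' @param standards A data frame with columns `name`, `retention_time_min`
#'   and `chi_ref` (see [load_fixture()] for the canonical set), or any data
#'   frame with those columns.
#' @return An object of class `"chi_calibration"` with components `slope`
#'   (CHI units per minute), `intercept` (CHI units), `n_points`,
#'   `r_squared`, `see` (residual standard deviation, n - 2 denominator;
#'   0 when n = 2) and `standards` (the input, with fitted values and
#'   residuals appended).
#' @seealso [predict.chi_calibration()], [write_calibration()]
#' @examples
#' cal <- chi_calibration(load_fixture("table1"))
#' predict(cal, newdata = 1.58)  # paracetamol
#' @export
chi_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  req <- c("name", "retention_time_min", "chi_ref")
  if (!all(req %in% names(standards)))
    stop("standards must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(standards$name))
    stop("standard names must be unique", call. = FALSE)
  n <- nrow(standards)
  if (n < 2)
    stop("need at least 2 calibration standards", call. = FALSE)
  tr <- standards$retention_time_min
  chi <- standards$chi_ref
  if (stats::var(tr) == 0 && stats::var(chi) > 0)
    stop("singular fit: duplicate retention times span different CHI values",
         call. = FALSE)
  fit <- stats::lm(chi ~ tr)
  res <- stats::resid(fit)
  see <- if (n > 2) sqrt(sum(res^2) / (n - 2)) else 0
  r2 <- if (stats::var(chi) > 0) summary(fit)$r.squared else 1
  standards$chi_fitted <- stats::fitted(fit)
  standards$residual <- res
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = n, r_squared = r2, see = see,
                 standards = standards),
            class = "chi_calibration")
}

#' Predict CHI from gradient retention times
#'
#' Applies a fitted calibration line: CHI = intercept + slope * tR.  No
#' clamping is applied; negative CHI values are valid outputs.
#'
#' @param object A [chi_calibration()] fit.
#' @param newdata Numeric vector of retention times (minutes), or a data
#'   frame with a `retention_time_min` column.  Defaults to the standards'
#'   own retention times.
#' @param ... Ignored.
#' @return Numeric CHI values.
#' @export
predict.chi_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- object$standards$retention_time_min
  if (is.data.frame(newdata))
    newdata <- newdata$retention_time_min
  if (!is.numeric(newdata))
    stop("newdata must be numeric retention times", call. = FALSE)
  object$intercept + object$slope * newdata
}

#' @export
coef.chi_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.chi_calibration <- function(object, ...) {
  stats::setNames(object$standards$residual, object$standards$name)
}

#' @export
print.chi_calibration <- function(x, ...) {
  cat("Gradient retention time -> CHI(IAM) calibration\n")
  cat(sprintf("  CHI = %.3f + %.3f * tR   (n = %d)\n",
              x$intercept, x$slope, x$n_points))
  cat(sprintf("  r^2 = %.4f, SEE = %.3f CHI units, max |resid| = %.2f\n",
              x$r_squared, x$see, max(abs(x$standards$residual))))
  invisible(x)
}

#' @export
summary.chi_calibration <- function(object, ...) {
  print(object)
  cat("\nStandards:\n")
  print(object$standards, digits = 4, row.names = FALSE)
  invisible(object)
}

#' @export
plot.chi_calibration <- function(x, ...) {
  s <- x$standards
  graphics::plot(s$retention_time_min, s$chi_ref,
                 xlab = "gradient retention time (min)",
                 ylab = "reference CHI(IAM)", pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Serialize / restore a calibration fit as JSON
#'
#' The JSON document records slope, intercept, n, r2, see, a timestamp and a
#' content hash of the standards table, so a restored fit reproduces
#' predictions exactly and carries its provenance.
#'
#' @param fit A `"chi_calibration"` object.
#' @param path File path for the JSON document.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a `"chi_calibration"` object.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "chi_calibration"))
  doc <- list(slope = fit$slope, intercept = fit$intercept,
              n = fit$n_points, r2 = fit$r_squared, see = fit$see,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              standards_hash = fixture_hash(fit$standards[
                c("name", "retention_time_min", "chi_ref")]),
              standards = fit$standards[
                c("name", "retention_time_min", "chi_ref")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @param path File path of a JSON document written by [write_calibration()].
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (fixture_hash(as.data.frame(doc$standards)) != doc$standards_hash)
    stop("standards hash mismatch: calibration document corrupted",
         call. = FALSE)
  chi_calibration(as.data.frame(doc$standards))
}

# content fingerprint of a data frame for provenance checks
fixture_hash <- function(df) {
  txt <- paste(utils::capture.output(
    utils::write.csv(df, row.names = FALSE)), collapse = "\n")
  content_hash(txt)
}
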