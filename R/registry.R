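#' JSON coefficient registry
#'
#' Coefficient sets live in a registry file: a JSON array of documents
#' `{model_id, terms, intercept, link, fit_stats, provenance, column_era}`.
#' Multiple sets may coexist per column era ("old-column" vs "new-column"
#' coefficients), mirroring the central QC finding that absolute estimates
#' differ between column generations while rank order is preserved.
#'
#' @param sets A list of [model_coefficients()] objects (or a single one).
#' @param path Registry file path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns a named list of `"model_coefficients"` objects;
#'   `registry_get()` returns one set or errors on an unknown id.
#' @examples
#' mc <- model_coefficients("demo", c(logk_iam = 0.5), -0.1)
#' f <- tempfile(fileext = ".json")
#' write_registry(list(mc), f)
#' registry_get(read_registry(f), "demo")
#' @export
write_registry <- function(sets, path) {
  if (inherits(sets, "model_coefficients")) sets <- list(sets)
  docs <- lapply(sets, function(s) {
    stopifnot(inherits(s, "model_coefficients"))
    list(model_id = s$model_id, terms = as.list(s$terms),
         intercept = s$intercept, link = s$link,
         fit_stats = s$fit_stats, provenance = s$provenance,
         column_era = s$column_era)
  })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  docs <- jsonlite::read_json(path, simplifyVector = FALSE)
  sets <- lapply(docs, function(d) {
    model_coefficients(d$model_id, unlist(d$terms), d$intercept,
                       link = d$link,
                       fit_stats = d$fit_stats,
                       provenance = d$provenance,
                       column_era = if (is.null(d$column_era)) NA_character_
                                    else d$column_era)
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "model_id"))
}

#' @rdname write_registry
#' @param registry A named list from [read_registry()].
#' @param model_id Identifier to look up.
#' @export
registry_get <- function(registry, model_id) {
  if (!model_id %in% names(registry))
    stop("configuration error: unknown registry id '", model_id, "'",
         call. = FALSE)
  registry[[model_id]]
}
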