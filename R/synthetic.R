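#' Configuration for the synthetic compound-set generator
#'
#' Defines the statistical structure the analysis assumes, so that every
#' pipeline stage (calibration, conversion, model fitting, column QC) can
#' be exercised and validated without external data.  Per acid/base class,
#' CHI(IAM) and log K(HSA) are drawn from normal distributions; clinical
#' log Vdss is generated from a known coefficient set applied to the
#' converted binding values plus noise; the "new column" reproduces the
#' old-column CHI except for a systematic negative shift applied to basic
#' compounds (the endcapping effect on positively charged solutes) plus
#' batch noise; and gradient retention times invert a known calibration
#' line plus timing noise.
#'
#' Defaults mirror the study conditions: 72 compounds, a class mix and
#' per-class moments rounded from the marketed-drug set (illustrative
#' summaries, not study facts), the calibration line of the standard set,
#' an 8 CHI-unit basic shift, 0.1 log-unit clinical noise, 0.02 min timing
#' noise and 0.5 CHI-unit batch noise.
#'
#' @param n_compounds Number of compounds.
#' @param class_mix Named proportions over the six acid/base classes,
#'   summing to 1.
#' @param chi_mean,chi_sd Named per-class CHI moments (CHI units).
#' @param hsa_mean,hsa_sd Named per-class log K(HSA) moments.
#' @param true_model [model_coefficients()] generating clinical log Vdss
#'   from `logk_iam` and `logk_hsa`.
#' @param vdss_noise_sd Clinical noise, log10 units.
#' @param calibration_line `c(slope, intercept)` of the retention-time ->
#'   CHI line (CHI units per minute; CHI units).
#' @param retention_noise_sd Retention-time noise, minutes.
#' @param basic_shift Systematic CHI reduction for basic compounds on the
#'   new column, CHI units.
#' @param batch_noise_sd Column batch noise, CHI units.
#' @param conversion CHI -> log K(IAM) conversion used when generating
#'   clinical values; default the packaged one.
#' @param seed Integer seed; fully determines the output.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(
    n_compounds = 72,
    class_mix = c(acidic = 0.25, amphoteric = 0.03, basic = 0.18,
                  neutral = 0.32, `weak acid` = 0.08, `weak base` = 0.14),
    chi_mean = c(acidic = 20, amphoteric = 39, basic = 40, neutral = 25,
                 `weak acid` = 14, `weak base` = 23),
    chi_sd = c(acidic = 10, amphoteric = 7, basic = 15, neutral = 14,
               `weak acid` = 13, `weak base` = 18),
    hsa_mean = c(acidic = 4.7, amphoteric = 1.8, basic = 1.8, neutral = 1.9,
                 `weak acid` = 1.4, `weak base` = 1.8),
    hsa_sd = c(acidic = 1.9, amphoteric = 0.5, basic = 1.5, neutral = 1.3,
               `weak acid` = 0.8, `weak base` = 1.4),
    true_model = model_coefficients("synthetic/truth",
                                    c(logk_iam = 0.44, logk_hsa = -0.22),
                                    -0.66),
    vdss_noise_sd = 0.1,
    calibration_line = c(slope = 16.2, intercept = -21.8),
    retention_noise_sd = 0.02,
    basic_shift = 8,
    batch_noise_sd = 0.5,
    conversion = NULL,
    seed = 1) {
  classes <- names(class_mix)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  if (any(class_mix < 0)) stop("class_mix must be non-negative", call. = FALSE)
  for (v in list(chi_sd, hsa_sd))
    if (any(v < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  for (v in list(chi_mean, chi_sd, hsa_mean, hsa_sd))
    if (!all(classes %in% names(v)))
      stop("per-class parameters must cover every class in class_mix",
           call. = FALSE)
  if (vdss_noise_sd < 0 || retention_noise_sd < 0 || batch_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  stopifnot(inherits(true_model, "model_coefficients"))
  structure(list(n_compounds = as.integer(n_compounds),
                 class_mix = class_mix, chi_mean = chi_mean, chi_sd = chi_sd,
                 hsa_mean = hsa_mean, hsa_sd = hsa_sd,
                 true_model = true_model, vdss_noise_sd = vdss_noise_sd,
                 calibration_line = calibration_line,
                 retention_noise_sd = retention_noise_sd,
                 basic_shift = basic_shift, batch_noise_sd = batch_noise_sd,
                 conversion = conversion, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic compound set
#'
#' Draws a compound table with the schema the real pipeline consumes:
#' acid/base class, old- and new-column CHI(IAM), gradient retention times
#' on both columns, log K(HSA) and a clinical log Vdss generated by the
#' configured true model.  Identical configurations (including the seed)
#' produce byte-identical tables.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `name`, `acid_base_class`, `chi_old`,
#'   `chi_new`, `retention_time_old`, `retention_time_new`, `logk_iam`,
#'   `logk_hsa`, `log_vdss_clinical`.
#' @examples
#' d <- generate_compound_set(simulation_config(n_compounds = 20, seed = 7))
#' head(d)
#' @export
generate_compound_set <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_compounds
  conv <- if (is.null(config$conversion)) default_conversion()
          else config$conversion
  withr_seed(config$seed, {
    cls <- sample(names(config$class_mix), n, replace = TRUE,
                  prob = config$class_mix)
    chi_old <- stats::rnorm(n, config$chi_mean[cls], config$chi_sd[cls])
    shift <- ifelse(cls == "basic", config$basic_shift, 0)
    chi_new <- chi_old - shift + stats::rnorm(n, 0, config$batch_noise_sd)
    logk_hsa <- stats::rnorm(n, config$hsa_mean[cls], config$hsa_sd[cls])
    sl <- config$calibration_line[["slope"]]
    ic <- config$calibration_line[["intercept"]]
    rt_old <- (chi_old - ic) / sl + stats::rnorm(n, 0, config$retention_noise_sd)
    rt_new <- (chi_new - ic) / sl + stats::rnorm(n, 0, config$retention_noise_sd)
    logk_iam <- as.numeric(predict(conv, chi_old, quiet = TRUE))
    truth <- linear_score(config$true_model,
                          data.frame(logk_iam = logk_iam,
                                     logk_hsa = logk_hsa))
    vdss <- truth + stats::rnorm(n, 0, config$vdss_noise_sd)
    data.frame(name = sprintf("cpd%03d", seq_len(n)),
               acid_base_class = cls,
               chi_old = chi_old, chi_new = chi_new,
               retention_time_old = rt_old, retention_time_new = rt_new,
               logk_iam = logk_iam, logk_hsa = logk_hsa,
               log_vdss_clinical = vdss)
  })
}

#' Generate a synthetic calibration run
#'
#' Emits the nine canonical standards with their reference CHI values and
#' gradient retention times computed by inverting the configured
#' calibration line, plus timing noise.
#'
#' @param config A [simulation_config()]; uses `calibration_line`,
#'   `retention_noise_sd` and `seed`.
#' @return Data frame with columns `name`, `chi_ref`, `retention_time_min`.
#' @export
generate_calibration_run <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  std <- load_fixture("table1")
  sl <- config$calibration_line[["slope"]]
  ic <- config$calibration_line[["intercept"]]
  withr_seed(config$seed, {
    data.frame(name = std$name,
               chi_ref = std$chi_ref,
               retention_time_min = (std$chi_ref - ic) / sl +
                 stats::rnorm(nrow(std), 0, config$retention_noise_sd))
  })
}

# evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
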