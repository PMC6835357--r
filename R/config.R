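#' Pipeline configuration
#'
#' Thresholds and tuning constants used across the pipeline.  Defaults
#' follow the published workflow: detection in at least 75% of study
#' samples, QC coefficient of variation below 30%, fold-change cut-off
#' 1.3, alpha 0.05, FDR threshold 0.05, nutrient correlation cut-off
#' |r| > 0.30 with hits in at least 2 categories, at least 2 of 3
#' statistical models, 1000 permutations, one orthogonal component and
#' 7-fold cross-validation for OPLS-DA.
#'
#' @param detection_fraction_min minimum detection fraction over non-QC
#'   samples, in (0, 1].
#' @param qc_cv_max maximum QC coefficient of variation (SD/mean), strict.
#' @param glog_lambda generalized-log offset in response units, or
#'   `"auto"` (smallest positive nonmissing response in the table).
#' @param fc_min volcano fold-change cut-off (> 1).
#' @param alpha per-test significance level.
#' @param q_threshold FDR threshold for the univariate (volcano) call.
#' @param r_min partial-correlation magnitude cut-off.
#' @param n_nutrient_min minimum number of correlated nutrient categories
#'   for a robust call.
#' @param n_models_min minimum number of passing statistical models for a
#'   robust call.
#' @param n_permutations OPLS-DA permutation count.
#' @param n_orth_components orthogonal components in OPLS-DA.
#' @param cv_folds cross-validation folds for Q2.
#' @param meba_prior_df prior degrees of freedom (shrinkage weight) for the
#'   moderated Hotelling T2 statistic; 0 recovers the classical statistic.
#' @param rng_seed integer seed for stochastic stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection_fraction_min = 0.75,
                            qc_cv_max = 0.30,
                            glog_lambda = "auto",
                            fc_min = 1.3,
                            alpha = 0.05,
                            q_threshold = 0.05,
                            r_min = 0.30,
                            n_nutrient_min = 2,
                            n_models_min = 2,
                            n_permutations = 1000,
                            n_orth_components = 1,
                            cv_folds = 7,
                            meba_prior_df = 3,
                            rng_seed = 1L) {
  cfg <- list(
    detection_fraction_min = detection_fraction_min,
    qc_cv_max = qc_cv_max,
    glog_lambda = glog_lambda,
    fc_min = fc_min,
    alpha = alpha,
    q_threshold = q_threshold,
    r_min = r_min,
    n_nutrient_min = as.integer(n_nutrient_min),
    n_models_min = as.integer(n_models_min),
    n_permutations = as.integer(n_permutations),
    n_orth_components = as.integer(n_orth_components),
    cv_folds = as.integer(cv_folds),
    meba_prior_df = meba_prior_df,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(is.numeric(cfg$detection_fraction_min) &&
        cfg$detection_fraction_min > 0 && cfg$detection_fraction_min <= 1,
      "detection_fraction_min must be in (0, 1]")
  chk(is.numeric(cfg$qc_cv_max) && cfg$qc_cv_max > 0,
      "qc_cv_max must be positive")
  chk(identical(cfg$glog_lambda, "auto") ||
        (is.numeric(cfg$glog_lambda) && cfg$glog_lambda >= 0),
      "glog_lambda must be 'auto' or a nonnegative number")
  chk(is.numeric(cfg$fc_min) && cfg$fc_min > 1, "fc_min must exceed 1")
  for (p in c("alpha", "q_threshold")) {
    chk(is.numeric(cfg[[p]]) && cfg[[p]] > 0 && cfg[[p]] < 1,
        paste(p, "must be in (0, 1)"))
  }
  chk(is.numeric(cfg$r_min) && cfg$r_min >= 0 && cfg$r_min < 1,
      "r_min must be in [0, 1)")
  for (p in c("n_nutrient_min", "n_models_min", "n_permutations",
              "cv_folds")) {
    chk(is.numeric(cfg[[p]]) && cfg[[p]] >= 1 && cfg[[p]] == round(cfg[[p]]),
        paste(p, "must be a positive integer"))
  }
  chk(is.numeric(cfg$n_orth_components) && cfg$n_orth_components >= 0,
      "n_orth_components must be >= 0")
  chk(is.numeric(cfg$meba_prior_df) && cfg$meba_prior_df >= 0,
      "meba_prior_df must be nonnegative")
  invisible(cfg)
}

#' Load a configuration file
#'
#' YAML key-value file; unspecified keys take the package defaults of
#' [pipeline_config()].  Out-of-domain values raise a validation error.
#'
#' @param path YAML file; an empty or absent-key file yields all defaults.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}
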