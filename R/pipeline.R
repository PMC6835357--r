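log_stage <- function(stage, ...) {
  message(sprintf("[dietmet] %s: %s", stage, sprintf(...)))
}

# per-stage substreams from one global seed, so adding a stage never
# perturbs the draws of earlier stages
stage_seed <- function(seed, stage_index) {
  (as.integer(seed) * 101L + 7919L * as.integer(stage_index)) %% 2147483L
}

#' Run the full pipeline
#'
#' Orchestrates generate (optional) -> preprocess -> diet score -> stats
#' -> biomarker calling, writing every intermediate as CSV plus a JSON
#' run manifest.  Deterministic for a fixed (config, spec) pair.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory (created if needed).
#' @param input_dir directory with `plasma.csv`, `plasma_samples.csv`,
#'   `plasma_features.csv`, the urine equivalents and `nutrients.csv`;
#'   ignored when `synthetic` is given.
#' @param synthetic a [simulation_spec()] to generate inputs from, or
#'   `TRUE` for the default spec (seeded from the config seed).
#' @return the run manifest, invisibly; all outputs are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         input_dir = NULL, synthetic = NULL) {
  if (is.character(config)) config <- load_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$rng_seed, stages = list(),
                   version = as.character(utils::packageVersion("dietmet")))
  t_all <- proc.time()["elapsed"]
  tick <- function() proc.time()["elapsed"]

  # --- inputs ---------------------------------------------------------
  t0 <- tick()
  truth <- NULL
  if (!is.null(synthetic)) {
    spec <- if (isTRUE(synthetic))
      simulation_spec(seed = stage_seed(config$rng_seed, 1L))
    else synthetic
    study <- generate_study(spec)
    plasma_raw <- study$plasma; urine_raw <- study$urine
    nutrients <- study$nutrients; truth <- study$truth
    raw_dir <- file.path(out_dir, "raw")
    dir.create(raw_dir, showWarnings = FALSE)
    write_feature_table(plasma_raw, file.path(raw_dir, "plasma.csv"),
                        file.path(raw_dir, "plasma_samples.csv"),
                        file.path(raw_dir, "plasma_features.csv"))
    write_feature_table(urine_raw, file.path(raw_dir, "urine.csv"),
                        file.path(raw_dir, "urine_samples.csv"),
                        file.path(raw_dir, "urine_features.csv"))
    write_nutrient_records(nutrients, file.path(raw_dir, "nutrients.csv"))
    jsonlite::write_json(
      list(planted = truth$planted, nonadherent = truth$nonadherent,
           cross_fluid = truth$cross_fluid),
      file.path(raw_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
    log_stage("simulate", "%d plasma x %d urine features, %d participants",
              nrow(plasma_raw$responses), nrow(urine_raw$responses),
              nrow(truth$participants))
  } else {
    if (is.null(input_dir)) stop("need input_dir or synthetic", call. = FALSE)
    plasma_raw <- read_feature_table(
      file.path(input_dir, "plasma.csv"),
      file.path(input_dir, "plasma_samples.csv"),
      file.path(input_dir, "plasma_features.csv"))
    urine_raw <- read_feature_table(
      file.path(input_dir, "urine.csv"),
      file.path(input_dir, "urine_samples.csv"),
      file.path(input_dir, "urine_features.csv"))
    nutrients <- read_nutrient_records(file.path(input_dir, "nutrients.csv"))
  }
  manifest$stages$input <- list(
    plasma_features = nrow(plasma_raw$responses),
    urine_features = nrow(urine_raw$responses),
    seconds = round(tick() - t0, 2))

  # --- preprocessing --------------------------------------------------
  res <- list()
  for (m in c("plasma", "urine")) {
    t0 <- tick()
    raw <- if (m == "plasma") plasma_raw else urine_raw
    pp <- preprocess_matrix(raw, config, matrix_name = m)
    res[[m]] <- pp
    utils::write.csv(pp$qc$detection,
                     file.path(out_dir, paste0(m, "_qc_detection.csv")),
                     row.names = FALSE)
    utils::write.csv(pp$qc$cv,
                     file.path(out_dir, paste0(m, "_qc_cv.csv")),
                     row.names = FALSE)
    write_feature_table(pp$table,
                        file.path(out_dir, paste0(m, "_processed.csv")),
                        file.path(out_dir, paste0(m, "_processed_samples.csv")))
    n_before <- nrow(raw$responses)
    n_after <- nrow(pp$table$responses)
    manifest$stages[[paste0("preprocess_", m)]] <- list(
      features_before = n_before,
      features_after_detection = sum(pp$qc$detection$retained),
      features_after_cv = n_after,
      seconds = round(tick() - t0, 2))
    log_stage("preprocess", "%s: %d -> %d features", m, n_before, n_after)
  }

  # --- diet records ---------------------------------------------------
  t0 <- tick()
  arms <- stats::setNames(plasma_raw$samples$arm, plasma_raw$samples$participant_id)
  arms <- arms[!is.na(names(arms)) & !duplicated(names(arms))]
  scores <- rbind(score_diet_records(nutrients, "baseline"),
                  score_diet_records(nutrients, "intervention"))
  utils::write.csv(scores, file.path(out_dir, "diet_scores.csv"),
                   row.names = FALSE)
  deltas <- nutrient_deltas(nutrients, arms)
  utils::write.csv(deltas, file.path(out_dir, "nutrient_deltas.csv"),
                   row.names = FALSE)
  manifest$stages$diet_records <- list(
    participants = length(unique(scores$participant_id)),
    categories = nrow(deltas), seconds = round(tick() - t0, 2))

  # --- statistics + calling -------------------------------------------
  nd <- nutrient_delta_matrix(nutrients)
  calls <- list()
  for (m in c("plasma", "urine")) {
    t0 <- tick()
    pp <- res[[m]]
    vol <- volcano(pp$ratios, config$fc_min, config$alpha, config$glog_lambda)
    meba <- meba_t2(pp$glog, config$meba_prior_df)
    anv <- mixed_anova_interaction(pp$glog)
    rs <- pp$ratios_scaled
    opls <- oplsda_fit(t(rs$responses), rs$samples$arm,
                       n_orth = config$n_orth_components,
                       cv_folds = config$cv_folds,
                       n_perm = config$n_permutations,
                       seed = stage_seed(config$rng_seed, 3L))
    # post-intervention responses against nutrient intake changes,
    # adjusted for age, sex and post-intervention BMI
    smg <- pp$glog$samples
    wk <- which(!qc_mask(pp$glog) & smg$timepoint == "week2")
    gl_wk2 <- pp$glog$responses[, wk, drop = FALSE]
    colnames(gl_wk2) <- smg$participant_id[wk]
    covs <- smg[wk, c("age", "sex", "bmi")]
    covs$sex <- as.numeric(factor(covs$sex)) - 1
    rownames(covs) <- smg$participant_id[wk]
    pcorr <- partial_correlation_table(gl_wk2, nd, covs)
    cl <- call_robust(meba, anv, vol, pcorr, config)
    traj <- summarize_trajectories(pp$table,
                                   cl$feature_id[cl$robust])
    for (obj in c("vol", "meba", "anv", "pcorr", "cl", "traj")) {
      utils::write.csv(get(obj),
                       file.path(out_dir, paste0(m, "_", switch(obj,
                         vol = "volcano", meba = "meba", anv = "anova",
                         pcorr = "partial_correlation", cl = "calls",
                         traj = "trajectories"), ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(r2y = opls$r2y, q2 = opls$q2, perm_p = opls$perm_p,
           n_orth = opls$n_orth),
      file.path(out_dir, paste0(m, "_oplsda.json")), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(opls$splot,
                     file.path(out_dir, paste0(m, "_oplsda_splot.csv")),
                     row.names = FALSE)
    calls[[m]] <- cl
    manifest$stages[[paste0("stats_", m)]] <- list(
      features = nrow(cl), robust_calls = sum(cl$robust),
      oplsda_r2y = opls$r2y, oplsda_q2 = opls$q2,
      oplsda_perm_p = opls$perm_p,
      seconds = round(tick() - t0, 2))
    log_stage("stats", "%s: %d robust biomarker call(s)", m, sum(cl$robust))
  }

  # cross-fluid correlations for the generator's coupled pairs (when the
  # run is synthetic and both features survived filtering)
  if (!is.null(truth) && nrow(truth$cross_fluid) > 0) {
    pairs <- truth$cross_fluid
    ok <- pairs$plasma_id %in% res$plasma$table$features$feature_id &
      pairs$urine_id %in% res$urine$table$features$feature_id
    if (any(ok)) {
      cfc <- cross_fluid_correlation(res$plasma$table, res$urine$table,
                                     pairs[ok, , drop = FALSE])
      utils::write.csv(cfc, file.path(out_dir, "cross_fluid.csv"),
                       row.names = FALSE)
    }
  }

  manifest$total_seconds <- round(tick() - t_all, 2)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
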