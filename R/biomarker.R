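#' Robust dietary biomarker calls
#'
#' A feature is a robust dietary biomarker when it passes at least
#' `n_models_min` of the three statistical models — the moderated
#' Hotelling T2 timecourse ranking, the mixed diet-by-time ANOVA, and
#' the univariate volcano (judged on its FDR q-value) — and correlates
#' with at least `n_nutrient_min` nutrient categories at `|r| > r_min`
#' and `p < alpha`.
#'
#' @param meba data.frame from [meba_t2()].
#' @param anova data.frame from [mixed_anova_interaction()].
#' @param volcano data.frame from [volcano()].
#' @param partial_corr data.frame from [partial_correlation_table()].
#' @param config a [pipeline_config()] supplying `alpha`, `q_threshold`,
#'   `r_min`, `n_nutrient_min`, `n_models_min`.
#' @return data.frame, one row per feature: model flags,
#'   `n_models_passed`, `n_nutrient_hits`, `robust`, and the top five
#'   nutrient correlations by |r| (`top5_nutrients`, `top5_r`, `top5_p`
#'   as semicolon-joined strings).
#' @export
call_robust <- function(meba, anova, volcano, partial_corr,
                        config = pipeline_config()) {
  ids <- meba$feature_id
  for (nm in list(anova = anova, volcano = volcano)) {
    missing_f <- setdiff(ids, nm$feature_id)
    extra <- setdiff(nm$feature_id, ids)
    if (length(missing_f) > 0 || length(extra) > 0)
      stop("model result sets cover different features (e.g. ",
           paste(utils::head(c(missing_f, extra), 3), collapse = ", "), ")",
           call. = FALSE)
  }
  am <- anova[match(ids, anova$feature_id), ]
  vm <- volcano[match(ids, volcano$feature_id), ]
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    pm <- meba$p[i] < config$alpha
    pa <- am$p[i] < config$alpha
    pu <- vm$q[i] < config$q_threshold
    nmod <- sum(pm, pa, pu)
    pc <- partial_corr[partial_corr$feature_id == id &
                         !is.na(partial_corr$r), , drop = FALSE]
    hits <- pc[abs(pc$r) > config$r_min & pc$p < config$alpha, , drop = FALSE]
    top5 <- pc[order(-abs(pc$r)), , drop = FALSE]
    top5 <- utils::head(top5, 5)
    data.frame(
      feature_id = id,
      passed_meba = pm, passed_anova = pa, passed_univariate = pu,
      n_models_passed = nmod,
      n_nutrient_hits = nrow(hits),
      robust = nmod >= config$n_models_min &&
        nrow(hits) >= config$n_nutrient_min,
      top5_nutrients = paste(top5$nutrient, collapse = ";"),
      top5_r = paste(sprintf("%.3f", top5$r), collapse = ";"),
      top5_p = paste(sprintf("%.3g", top5$p), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-fluid correlation of matched biomarkers
#'
#' Pearson correlation of a plasma feature with a urine feature over all
#' matched (participant, timepoint) samples, both timepoints pooled.
#' Responses are log-transformed by default, appropriate for log-normal
#' concentration data; urine responses should be creatinine-normalized
#' beforehand.
#'
#' @param plasma,urine `feature_table`s sharing participants and
#'   timepoints.
#' @param pairs data.frame with columns `plasma_id`, `urine_id`.
#' @param log correlate log responses (default) or raw.
#' @return data.frame: `plasma_id`, `urine_id`, `r`, `p`, `n`.
#' @export
cross_fluid_correlation <- function(plasma, urine, pairs, log = TRUE) {
  key <- function(ft) {
    qc <- qc_mask(ft)
    paste(ft$samples$participant_id, ft$samples$timepoint)[!qc]
  }
  kp <- key(plasma); ku <- key(urine)
  common <- intersect(kp, ku)
  if (length(common) == 0)
    stop("no matched (participant, timepoint) samples", call. = FALSE)
  pi <- which(!qc_mask(plasma))[match(common, kp)]
  ui <- which(!qc_mask(urine))[match(common, ku)]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    fp <- match(pairs$plasma_id[k], plasma$features$feature_id)
    fu <- match(pairs$urine_id[k], urine$features$feature_id)
    if (is.na(fp) || is.na(fu))
      stop("pair feature not found: ", pairs$plasma_id[k], " / ",
           pairs$urine_id[k], call. = FALSE)
    x <- plasma$responses[fp, pi]
    y <- urine$responses[fu, ui]
    if (log) { x <- base::log(x); y <- base::log(y) }
    ok <- is.finite(x) & is.finite(y)
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(plasma_id = pairs$plasma_id[k], urine_id = pairs$urine_id[k],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trajectory summaries for called biomarkers
#'
#' Per feature and arm: baseline and week-2 mean and SD of the raw
#' responses and the mean fold change (geometric mean of the paired
#' ratios); plus a between-arm baseline t-test (flagging baseline
#' imbalance) and outlier participants whose standardized log-ratio
#' residual within their arm exceeds 3 in absolute value.
#'
#' @param table imputed, untransformed `feature_table`.
#' @param feature_ids features to summarize (default: all).
#' @return data.frame, one row per feature, with per-arm summaries,
#'   `baseline_p`, and `outliers` (semicolon-joined participant ids).
#' @export
summarize_trajectories <- function(table, feature_ids = table$features$feature_id) {
  ratios <- paired_ratios(table)
  sm <- table$samples
  qc <- qc_mask(table)
  rows <- lapply(feature_ids, function(id) {
    f <- match(id, table$features$feature_id)
    fr <- match(id, ratios$features$feature_id)
    arm_r <- ratios$samples$arm
    lr <- log(ratios$responses[fr, ])
    outliers <- character(0)
    for (a in c("W-P", "P-W")) {
      v <- lr[arm_r == a]
      z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
      outliers <- c(outliers,
                    ratios$samples$participant_id[arm_r == a][!is.na(z) & abs(z) > 3])
    }
    one_arm <- function(a) {
      bsel <- !qc & sm$arm == a & sm$timepoint == "baseline"
      wsel <- !qc & sm$arm == a & sm$timepoint == "week2"
      b <- table$responses[f, bsel]; w <- table$responses[f, wsel]
      c(b_mean = mean(b, na.rm = TRUE), b_sd = stats::sd(b, na.rm = TRUE),
        w_mean = mean(w, na.rm = TRUE), w_sd = stats::sd(w, na.rm = TRUE),
        fc = exp(mean(lr[arm_r == a], na.rm = TRUE)))
    }
    s1 <- one_arm("W-P"); s2 <- one_arm("P-W")
    b1 <- table$responses[f, !qc & sm$arm == "W-P" & sm$timepoint == "baseline"]
    b2 <- table$responses[f, !qc & sm$arm == "P-W" & sm$timepoint == "baseline"]
    bt <- summary_ttest(mean(b1, na.rm = TRUE), stats::sd(b1, na.rm = TRUE),
                        sum(!is.na(b1)),
                        mean(b2, na.rm = TRUE), stats::sd(b2, na.rm = TRUE),
                        sum(!is.na(b2)))
    data.frame(feature_id = id,
               wp_baseline_mean = s1["b_mean"], wp_baseline_sd = s1["b_sd"],
               wp_week2_mean = s1["w_mean"], wp_week2_sd = s1["w_sd"],
               wp_fold_change = s1["fc"],
               pw_baseline_mean = s2["b_mean"], pw_baseline_sd = s2["b_sd"],
               pw_week2_mean = s2["w_mean"], pw_week2_sd = s2["w_sd"],
               pw_fold_change = s2["fc"],
               baseline_p = bt$p,
               outliers = paste(outliers, collapse = ";"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
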