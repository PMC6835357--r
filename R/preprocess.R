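#' Normalize responses to an internal standard
#'
#' Divides every response by the sample's internal-standard response,
#' removing sample-to-sample instrument variation.  The internal-standard
#' feature is dropped from the returned table (it carries no biological
#' information downstream).
#'
#' @param ft a `feature_table`.
#' @param is_feature feature id of the internal standard.
#' @return normalized `feature_table` without the IS row.
#' @export
normalize_internal_standard <- function(ft, is_feature) {
  idx <- match(is_feature, ft$features$feature_id)
  if (is.na(idx))
    stop("internal standard feature '", is_feature, "' not found",
         call. = FALSE)
  is_resp <- ft$responses[idx, ]
  bad <- is.na(is_resp) | is_resp <= 0
  if (any(bad))
    stop("internal standard missing or nonpositive in sample(s): ",
         paste(ft$samples$sample_id[bad], collapse = ", "), call. = FALSE)
  resp <- sweep(ft$responses, 2, is_resp, "/")
  ft <- set_responses(ft, resp)
  drop_features(ft, is_feature)
}

#' Normalize urinary responses to creatinine
#'
#' Divides every response by the sample's creatinine response to correct
#' for hydration-driven dilution differences between single-spot urine
#' samples.  Units become response per creatinine response.  The
#' creatinine feature is dropped from the returned table.
#'
#' @param ft a urine `feature_table`.
#' @param creatinine_feature feature id of creatinine.
#' @return normalized `feature_table`.
#' @export
normalize_creatinine <- function(ft, creatinine_feature = "creatinine") {
  normalize_internal_standard(ft, creatinine_feature)
}

#' Per-feature detection and QC precision summary
#'
#' @param ft a `feature_table`.
#' @return data.frame with `feature_id`, `detection_fraction` (nonmissing
#'   over non-QC samples), `qc_cv` (SD/mean over QC samples, `NA` when
#'   fewer than two QC observations), `retained`, `reason`.
#' @keywords internal
qc_summary <- function(ft) {
  qc <- qc_mask(ft)
  study <- ft$responses[, !qc, drop = FALSE]
  qcs <- ft$responses[, qc, drop = FALSE]
  det <- rowMeans(!is.na(study))
  cv <- apply(qcs, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / mean(v)
  })
  data.frame(feature_id = ft$features$feature_id,
             detection_fraction = det, qc_cv = cv,
             retained = TRUE, reason = "ok", stringsAsFactors = FALSE)
}

#' Filter features by detection fraction
#'
#' Features measured (nonmissing) in fewer than `min_fraction` of the
#' non-QC study samples are removed.  The comparison is `>=`, so the
#' published "in more than 75% of samples" rule corresponds to
#' `detection_fraction >= 0.75`.
#'
#' @param ft a `feature_table`.
#' @param min_fraction threshold in (0, 1].
#' @return list with `table` (filtered) and `summary` (QC summary with
#'   reason codes).
#' @export
filter_detection <- function(ft, min_fraction = 0.75) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  qs <- qc_summary(ft)
  drop <- qs$detection_fraction < min_fraction
  qs$retained[drop] <- FALSE
  qs$reason[drop] <- "low-detection"
  list(table = ft[!drop, ], summary = qs)
}

#' Filter features by QC coefficient of variation
#'
#' Features whose CV (SD/mean) over QC injections is `>= max_cv` are
#' removed (strict `< max_cv` retains).  Features with fewer than two QC
#' observations cannot be assessed: they are retained, flagged
#' `cv-undefined`, and a warning is issued.
#'
#' @param ft a `feature_table` with QC samples.
#' @param max_cv threshold (default 0.30).
#' @return list with `table` and `summary`.
#' @export
filter_qc_cv <- function(ft, max_cv = 0.30) {
  if (sum(qc_mask(ft)) < 2)
    stop("at least two QC samples are required", call. = FALSE)
  qs <- qc_summary(ft)
  undef <- is.na(qs$qc_cv)
  if (any(undef)) {
    warning(sum(undef), " feature(s) with < 2 QC observations retained ",
            "with undefined CV", call. = FALSE)
    qs$reason[undef] <- "cv-undefined"
  }
  drop <- !undef & qs$qc_cv >= max_cv
  qs$retained[drop] <- FALSE
  qs$reason[drop] <- "high-cv"
  list(table = ft[!drop, ], summary = qs)
}

#' Half-minimum imputation of missing responses
#'
#' Every missing value of a feature is replaced by half the smallest
#' nonmissing response of that feature over all samples; no other cell
#' changes.
#'
#' @param ft a `feature_table`.
#' @return imputed `feature_table`.
#' @export
impute_half_min <- function(ft) {
  resp <- ft$responses
  for (f in seq_len(nrow(resp))) {
    miss <- is.na(resp[f, ])
    if (!any(miss)) next
    obs <- resp[f, !miss]
    obs <- obs[obs > 0]
    if (length(obs) == 0)
      stop("feature '", ft$features$feature_id[f],
           "' has no positive observed response to impute from",
           call. = FALSE)
    resp[f, miss] <- min(obs) / 2
  }
  set_responses(ft, resp)
}

#' Generalized log transformation
#'
#' `x -> log2((x + sqrt(x^2 + lambda^2)) / 2)`, a variance-stabilizing
#' transform that behaves like `log2` for large responses and is defined
#' at zero.  `lambda = "auto"` uses the smallest positive nonmissing
#' response in the table.
#'
#' @param ft a `feature_table` with nonnegative responses.
#' @param lambda nonnegative offset in response units, or `"auto"`.
#' @return transformed `feature_table` (values may be negative).
#' @export
glog_transform <- function(ft, lambda = "auto") {
  if (identical(lambda, "auto")) {
    pos <- ft$responses[!is.na(ft$responses) & ft$responses > 0]
    if (length(pos) == 0)
      stop("no positive responses to derive lambda from", call. = FALSE)
    lambda <- min(pos)
  }
  if (!is.numeric(lambda) || lambda < 0)
    stop("lambda must be nonnegative", call. = FALSE)
  x <- ft$responses
  g <- log2((x + sqrt(x^2 + lambda^2)) / 2)
  ft <- set_glog_flag(set_responses_any(ft, g))
  attr(ft, "glog_lambda") <- lambda
  ft
}

# like set_responses but without the nonnegativity expectation downstream
set_responses_any <- function(ft, responses) {
  ft$responses <- responses
  rownames(ft$responses) <- ft$features$feature_id
  colnames(ft$responses) <- ft$samples$sample_id
  ft
}

set_glog_flag <- function(ft) { attr(ft, "transformed") <- TRUE; ft }

#' Autoscale (unit-variance scale) each feature
#'
#' Per feature: subtract the mean and divide by the sample SD (ddof 1)
#' over nonmissing values.  Zero-variance features cannot be scaled; they
#' are dropped and reported.
#'
#' @param ft a `feature_table` (typically glog-transformed).
#' @return autoscaled `feature_table`; dropped constant features, if any,
#'   are recorded in the `"excluded_constant"` attribute.
#' @export
autoscale <- function(ft) {
  x <- ft$responses
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(sdv) & sdv == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s) before scaling",
            call. = FALSE)
  }
  x <- (x - mu) / sdv
  ft2 <- set_responses_any(ft, x)[!const, ]
  attr(ft2, "excluded_constant") <- ft$features$feature_id[const]
  ft2
}

#' Paired week-2 / baseline response ratios
#'
#' Collapses the table to one column per participant holding the ratio of
#' the week-2 response to the baseline response for each feature.
#' Participants missing either timepoint are dropped with a warning.
#'
#' @param ft a `feature_table` of imputed, untransformed responses.
#' @return a `feature_table` whose samples are participants (arm and
#'   covariates carried over), with `timepoint = "ratio"`.
#' @export
paired_ratios <- function(ft) {
  sm <- ft$samples
  qc <- qc_mask(ft)
  study <- which(!qc)
  base <- study[sm$timepoint[study] == "baseline"]
  wk2 <- study[sm$timepoint[study] == "week2"]
  common <- intersect(sm$participant_id[base], sm$participant_id[wk2])
  dropped <- setdiff(unique(sm$participant_id[study]), common)
  if (length(dropped) > 0)
    warning("dropping participant(s) missing a timepoint: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  bi <- base[match(common, sm$participant_id[base])]
  wi <- wk2[match(common, sm$participant_id[wk2])]
  b <- ft$responses[, bi, drop = FALSE]
  w <- ft$responses[, wi, drop = FALSE]
  zero <- which(!is.na(b) & b == 0, arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop("zero baseline response (cannot form ratio) for feature '",
         ft$features$feature_id[zero[1, 1]], "', participant '",
         common[zero[1, 2]], "'", call. = FALSE)
  ratios <- w / b
  samples <- sm[bi, , drop = FALSE]
  samples$sample_id <- common
  samples$timepoint <- "ratio"
  samples$run_id <- NA_character_
  samples$injection_position <- NA_integer_
  rownames(samples) <- NULL
  feature_table(ratios, ft$features, samples)
}

#' Standard preprocessing chain for one matrix
#'
#' Applies, in order: internal-standard normalization, creatinine
#' normalization (urine only), detection filter, QC-CV filter,
#' half-minimum imputation and, for urine, QC-anchored batch correction.
#' The returned list carries the processed table plus the paired-ratio,
#' glog and autoscaled views used by the downstream statistics.
#'
#' @param ft raw `feature_table`.
#' @param config a [pipeline_config()].
#' @param matrix_name `"plasma"` or `"urine"`; default taken from the
#'   sample metadata.
#' @param is_feature internal-standard feature id, or `NULL` to skip.
#' @param creatinine_feature creatinine feature id (urine), or `NULL`.
#' @param batch_correct apply QC-anchored batch correction; defaults to
#'   urine only, where drift correction has the most to gain.
#' @return list with `table` (imputed responses), `ratios`, `glog`
#'   (glog-transformed table), `scaled` (glog + autoscale), `ratios_scaled`
#'   (glog + autoscale of the paired ratios), `qc` (filter summaries) and
#'   `batch_model`.
#' @export
preprocess_matrix <- function(ft, config = pipeline_config(),
                              matrix_name = NULL,
                              is_feature = "IS_ClTyr",
                              creatinine_feature = if (identical(matrix_name, "urine")) "creatinine" else NULL,
                              batch_correct = identical(matrix_name, "urine")) {
  if (is.null(matrix_name)) {
    mats <- unique(stats::na.omit(ft$samples$matrix))
    matrix_name <- if (length(mats) == 1) mats else "plasma"
  }
  if (!is.null(is_feature) && is_feature %in% ft$features$feature_id)
    ft <- normalize_internal_standard(ft, is_feature)
  if (!is.null(creatinine_feature) &&
      creatinine_feature %in% ft$features$feature_id)
    ft <- normalize_creatinine(ft, creatinine_feature)
  fd <- filter_detection(ft, config$detection_fraction_min)
  fc <- filter_qc_cv(fd$table, config$qc_cv_max)
  ft <- impute_half_min(fc$table)
  bm <- NULL
  if (isTRUE(batch_correct)) {
    bc <- batch_correct(ft, anchoring = "qc")
    ft <- bc$table
    bm <- bc$model
  }
  ratios <- paired_ratios(ft)
  gl <- glog_transform(ft, config$glog_lambda)
  list(table = ft,
       ratios = ratios,
       glog = gl,
       scaled = autoscale(gl),
       ratios_scaled = autoscale(glog_transform(ratios, config$glog_lambda)),
       qc = list(detection = fd$summary, cv = fc$summary),
       batch_model = bm)
}
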