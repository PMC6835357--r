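#' Mixed diet-by-time ANOVA via the within-subject contrast
#'
#' With exactly two timepoints, the diet-by-time interaction of a
#' two-level repeated-measures model equals the between-arm effect on the
#' within-subject difference score.  Per feature, the week2 minus
#' baseline glog difference is regressed on arm plus covariates; the
#' interaction F is the partial F for the arm term (df1 = 1).  Without
#' covariates and with any arm sizes this equals the square of the
#' two-sample t on the differences.
#'
#' @param glog_table glog-transformed `feature_table`, both timepoints
#'   per participant.
#' @param covariates character vector of sample-metadata columns to
#'   adjust for (default age, sex, BMI; sex is coded 0/1).
#' @return data.frame: `feature_id`, `f`, `p`, `df1`, `df2`.
#' @export
mixed_anova_interaction <- function(glog_table,
                                    covariates = c("age", "sex", "bmi")) {
  sm <- glog_table$samples
  qc <- qc_mask(glog_table)
  study <- which(!qc)
  base <- study[sm$timepoint[study] == "baseline"]
  wk2 <- study[sm$timepoint[study] == "week2"]
  common <- intersect(sm$participant_id[base], sm$participant_id[wk2])
  bi <- base[match(common, sm$participant_id[base])]
  wi <- wk2[match(common, sm$participant_id[wk2])]
  arm <- factor(sm$arm[bi], levels = c("P-W", "W-P"))
  covs <- NULL
  if (length(covariates) > 0) {
    covs <- sm[bi, covariates, drop = FALSE]
    if ("sex" %in% names(covs)) covs$sex <- as.numeric(factor(covs$sex)) - 1
    covs <- as.matrix(covs)
    storage.mode(covs) <- "double"
  }
  arm_num <- as.numeric(arm) - 1
  design <- cbind(intercept = 1, arm = arm_num, covs)
  if (qr(design)$rank < ncol(design)) {
    # identify the offending column(s) by incremental rank
    r <- 1
    bad <- character(0)
    for (j in 2:ncol(design)) {
      rj <- qr(design[, 1:j, drop = FALSE])$rank
      if (rj == r) bad <- c(bad, colnames(design)[j]) else r <- rj
    }
    stop("collinear design column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  D <- glog_table$responses[, wi, drop = FALSE] -
    glog_table$responses[, bi, drop = FALSE]
  qr_d <- qr(design)
  df2 <- length(common) - ncol(design)
  rows <- lapply(seq_len(nrow(D)), function(f) {
    d <- D[f, ]
    fit <- stats::lm.fit(design, d)
    res <- fit$residuals
    sigma2 <- sum(res^2) / df2
    # partial F for the arm column = squared t of its coefficient
    xtx_inv <- chol2inv(qr.R(qr_d))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    tval <- fit$coefficients["arm"] / se
    data.frame(feature_id = glog_table$features$feature_id[f],
               f = tval^2, p = 2 * stats::pt(-abs(tval), df2),
               df1 = 1, df2 = df2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Covariate-adjusted partial Pearson correlation
#'
#' Rows with any missing entry are removed (listwise deletion); `x` and
#' `y` are residualized on the covariates (with intercept) by least
#' squares, and the Pearson correlation of the residuals is returned
#' with the t-based p-value on `n - 2 - k` degrees of freedom (`k`
#' covariates).  Zero-variance residuals yield an undefined (`NA`)
#' result with `defined = FALSE` rather than a silent zero.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame (or `NULL` for plain
#'   Pearson).
#' @return list: `r`, `p`, `n_used`, `df`, `defined`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
  }
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & !apply(is.na(covariates), 1, any)
  x <- x[keep]; y <- y[keep]
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(x)
  if (n < k + 3)
    stop("need at least k + 3 complete observations", call. = FALSE)
  if (k > 0) {
    Z <- cbind(1, covariates[keep, , drop = FALSE])
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  near_zero <- function(res, orig)
    stats::sd(res) <= 1e-10 * max(stats::sd(orig), .Machine$double.eps)
  if (near_zero(rx, x) || near_zero(ry, y))
    return(list(r = NA_real_, p = NA_real_, n_used = n, df = n - 2 - k,
                defined = FALSE))
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, n_used = n, df = df, defined = TRUE)
}

#' Feature-by-nutrient partial correlation table
#'
#' Applies [partial_correlation()] to every (feature, nutrient) pair:
#' feature values are per-participant responses (typically glog paired
#' ratios), nutrient values are per-participant intake deltas.
#'
#' @param feature_values numeric matrix, features x participants.
#' @param nutrient_deltas numeric matrix, participants x nutrients (see
#'   [nutrient_delta_matrix()]).
#' @param covariates data.frame/matrix of per-participant covariates.
#' @return data.frame: `feature_id`, `nutrient`, `r`, `p`, `n_used`.
#' @export
partial_correlation_table <- function(feature_values, nutrient_deltas,
                                      covariates = NULL) {
  common <- intersect(colnames(feature_values), rownames(nutrient_deltas))
  if (length(common) == 0)
    stop("no participants shared between features and nutrients",
         call. = FALSE)
  fv <- feature_values[, common, drop = FALSE]
  nd <- nutrient_deltas[common, , drop = FALSE]
  cv <- if (!is.null(covariates)) as.matrix(covariates[common, , drop = FALSE])
        else NULL
  rows <- list()
  for (f in seq_len(nrow(fv))) {
    for (j in seq_len(ncol(nd))) {
      pc <- partial_correlation(fv[f, ], nd[, j], cv)
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = rownames(fv)[f], nutrient = colnames(nd)[j],
        r = pc$r, p = pc$p, n_used = pc$n_used, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' ROC analysis of a single or ratiometric marker
#'
#' AUC by the Mann-Whitney identity (ties counted one half), its p-value
#' from the normal-approximation Mann-Whitney test, and sensitivity and
#' specificity at the Youden-optimal threshold.  The AUC is oriented by
#' `positive_class`, so swapping the class labels maps the AUC to one
#' minus itself.
#'
#' @param values numeric marker vector (a feature's responses, or a
#'   ratio of two features).
#' @param labels two-level class labels.
#' @param positive_class label treated as positive; defaults to the
#'   second sorted level.
#' @return list: `auc`, `p`, `sensitivity`, `specificity`, `threshold`,
#'   `positive_class`.
#' @export
roc_auc <- function(values, labels, positive_class = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("labels must have two classes", call. = FALSE)
  if (is.null(positive_class)) positive_class <- cls[2]
  pos <- values[labels == positive_class]
  neg <- values[labels != positive_class]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be nonempty", call. = FALSE)
  ok_p <- !is.na(pos); ok_n <- !is.na(neg)
  pos <- pos[ok_p]; neg <- neg[ok_n]
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc_raw <- u / (n1 * n2)
  p <- suppressWarnings(stats::wilcox.test(pos, neg, exact = FALSE,
                                           correct = TRUE)$p.value)
  # Youden-optimal threshold on the oriented marker
  sign_dir <- if (auc_raw >= 0.5) 1 else -1
  vv <- sign_dir * c(pos, neg)
  lab <- c(rep(TRUE, n1), rep(FALSE, n2))
  cuts <- sort(unique(vv))
  cuts <- c(-Inf, (cuts[-1] + cuts[-length(cuts)]) / 2, Inf)
  best <- c(youden = -Inf, sens = NA, spec = NA, thr = NA)
  for (cth in cuts) {
    sens <- mean(vv[lab] > cth)
    spec <- mean(vv[!lab] <= cth)
    yj <- sens + spec - 1
    if (yj > best["youden"])
      best <- c(youden = yj, sens = sens, spec = spec, thr = cth)
  }
  list(auc = auc_raw, p = p,
       sensitivity = unname(best["sens"]), specificity = unname(best["spec"]),
       threshold = sign_dir * unname(best["thr"]),
       positive_class = positive_class)
}
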