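#' Empirical-Bayes batch correction anchored on QC injections
#'
#' Removes per-batch (per-run) location shifts on the log scale.  For
#' each feature, batch locations are estimated from the anchor samples
#' (QC injections in `"qc"` mode, all samples in `"grand-mean"` mode) and
#' shrunk toward the cross-batch prior mean by precision weighting:
#'
#' \deqn{\hat\gamma_b^{post} = \frac{(n_b/\sigma^2)\,\hat\gamma_b}
#'   {n_b/\sigma^2 + 1/\tau^2}}
#'
#' where \eqn{\hat\gamma_b} is the batch-mean deviation from the
#' feature's grand anchor mean, \eqn{\sigma^2} the technical
#' (within-batch) variance, and \eqn{\tau^2} the between-batch effect
#' variance; both are method-of-moments estimates across batches.  With a
#' single QC per batch \eqn{\sigma^2} is estimated from the mean squared
#' successive difference of QC values along run order, which is robust to
#' smooth drift.  `shrink = FALSE` sets \eqn{\tau^2 = \infty}
#' (raw batch-mean removal); with one batch the transform is the
#' identity.
#'
#' @param ft a `feature_table` with `run_id` and QC samples populated;
#'   responses positive (impute first).
#' @param anchoring `"qc"` or `"grand-mean"`.
#' @param shrink apply empirical-Bayes shrinkage (default `TRUE`).
#' @param scale also correct per-batch scale; only available when every
#'   batch has at least 3 anchor samples.
#' @return list with `table` (corrected) and `model` (class
#'   `batch_model`: per-batch-per-feature shifts on the log scale,
#'   hyperparameters, anchoring mode).
#' @export
batch_correct <- function(ft, anchoring = c("qc", "grand-mean"),
                          shrink = TRUE, scale = FALSE) {
  anchoring <- match.arg(anchoring)
  sm <- ft$samples
  if (!("run_id" %in% names(sm)) || any(is.na(sm$run_id)))
    stop("run_id must be set for every sample", call. = FALSE)
  batches <- unique(sm$run_id)
  qc <- qc_mask(ft)
  anchor <- if (anchoring == "qc") qc else rep(TRUE, nrow(sm))
  if (anchoring == "qc") {
    no_qc <- setdiff(batches, unique(sm$run_id[qc]))
    if (length(no_qc) > 0)
      stop("run(s) without a QC sample in qc anchoring mode: ",
           paste(no_qc, collapse = ", "), call. = FALSE)
  }
  resp <- ft$responses
  if (any(!is.na(resp) & resp <= 0))
    stop("batch correction requires positive responses (impute first)",
         call. = FALSE)
  lg <- log(resp)
  nb <- length(batches)
  nf <- nrow(lg)
  shifts <- matrix(0, nf, nb, dimnames = list(ft$features$feature_id, batches))
  scales <- matrix(1, nf, nb, dimnames = list(ft$features$feature_id, batches))
  hyper <- data.frame(feature_id = ft$features$feature_id,
                      prior_mean = NA_real_, sigma2 = NA_real_,
                      tau2 = NA_real_, stringsAsFactors = FALSE)
  # order batches by their first injection for the successive-difference
  # technical-variance estimate
  first_pos <- vapply(batches, function(b)
    min(sm$injection_position[sm$run_id == b], na.rm = TRUE), numeric(1))
  bord <- order(first_pos)
  can_scale <- scale &&
    all(vapply(batches, function(b) sum(anchor & sm$run_id == b), 0L) >= 3)
  for (f in seq_len(nf)) {
    m <- rep(NA_real_, nb)
    nsz <- integer(nb)
    wvar <- c()
    for (bi in seq_len(nb)) {
      v <- lg[f, anchor & sm$run_id == batches[bi]]
      v <- v[!is.na(v)]
      nsz[bi] <- length(v)
      if (length(v) > 0) m[bi] <- mean(v)
      if (length(v) > 1) wvar <- c(wvar, stats::var(v))
    }
    if (all(is.na(m))) next
    prior <- mean(m, na.rm = TRUE)
    gamma_hat <- m - prior
    B <- if (nb > 1) stats::var(m[!is.na(m)]) else 0
    if (length(wvar) > 0) {
      sigma2 <- mean(wvar)
    } else {
      # one anchor per batch: mean squared successive difference / 2,
      # computed along run order so smooth drift contributes little
      vo <- m[bord]
      vo <- vo[!is.na(vo)]
      sigma2 <- if (length(vo) > 1) mean(diff(vo)^2) / 2 else 0
    }
    nbar <- max(mean(nsz[nsz > 0]), 1)
    tau2 <- max(B - sigma2 / nbar, 0)
    hyper$prior_mean[f] <- prior
    hyper$sigma2[f] <- sigma2
    hyper$tau2[f] <- tau2
    if (nb == 1) next
    if (!shrink) {
      post <- gamma_hat
    } else if (tau2 == 0) {
      post <- rep(0, nb)
    } else {
      w <- (nsz / max(sigma2, 1e-12)) /
        (nsz / max(sigma2, 1e-12) + 1 / tau2)
      post <- w * gamma_hat
    }
    post[is.na(post)] <- 0
    shifts[f, ] <- post
    if (can_scale) {
      for (bi in seq_len(nb)) {
        v <- lg[f, anchor & sm$run_id == batches[bi]]
        v <- v[!is.na(v)]
        if (length(v) >= 3 && stats::sd(v) > 0) scales[f, bi] <- stats::sd(v)
      }
      scales[f, ] <- scales[f, ] / exp(mean(log(scales[f, ])))
    }
  }
  # apply: per sample, subtract its batch's shift (and rescale) on log scale
  bidx <- match(sm$run_id, batches)
  corrected <- lg
  for (j in seq_len(ncol(lg))) {
    corrected[, j] <- hyper$prior_mean +
      (lg[, j] - hyper$prior_mean - shifts[, bidx[j]]) / scales[, bidx[j]]
  }
  # features where no prior could be formed stay untouched
  untouched <- is.na(hyper$prior_mean)
  corrected[untouched, ] <- lg[untouched, ]
  model <- structure(list(shifts = shifts, scales = scales, hyper = hyper,
                          anchoring = anchoring, shrink = shrink,
                          batches = batches),
                     class = "batch_model")
  list(table = set_responses(ft, exp(corrected)), model = model)
}

#' Invert a fitted batch model
#'
#' Applies the inverse transform, recovering the uncorrected table to
#' numerical precision; used to verify that the model is a bijection.
#'
#' @param ft a corrected `feature_table`.
#' @param model the `batch_model` returned by [batch_correct()].
#' @return the uncorrected `feature_table`.
#' @export
batch_uncorrect <- function(ft, model) {
  sm <- ft$samples
  bidx <- match(sm$run_id, model$batches)
  lg <- log(ft$responses)
  out <- lg
  for (j in seq_len(ncol(lg))) {
    out[, j] <- model$hyper$prior_mean +
      (lg[, j] - model$hyper$prior_mean) * model$scales[, bidx[j]] +
      model$shifts[, bidx[j]]
  }
  untouched <- is.na(model$hyper$prior_mean)
  out[untouched, ] <- lg[untouched, ]
  set_responses(ft, exp(out))
}
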