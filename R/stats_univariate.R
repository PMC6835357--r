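#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}.
#'
#' @param p vector of p-values in [0, 1] (`NA` passed through).
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- p
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Volcano analysis of paired response ratios
#'
#' Per feature: the between-arm mean fold change is the ratio of the
#' geometric mean paired ratio in arm W-P to that in arm P-W; the
#' p-value is a two-sample pooled-variance t-test on glog-transformed
#' ratios; q-values are BH-adjusted within the table.  A feature is
#' flagged significant when the fold change clears `fc_min` in either
#' direction and `p < alpha`.
#'
#' @param ratios a `feature_table` of paired ratios (samples are
#'   participants with `arm` set), as from [paired_ratios()].
#' @param fc_min fold-change cut-off (> 1).
#' @param alpha significance level for the flag.
#' @param glog_lambda lambda for the glog transform of the ratios.
#' @return data.frame: `feature_id`, `fc`, `log2fc`, `p`, `q`,
#'   `significant`.
#' @export
volcano <- function(ratios, fc_min = 1.3, alpha = 0.05,
                    glog_lambda = "auto") {
  arm <- ratios$samples$arm
  i1 <- which(arm == "W-P"); i2 <- which(arm == "P-W")
  if (length(i1) < 2 || length(i2) < 2)
    stop("at least two participants per arm are required", call. = FALSE)
  gl <- glog_transform(ratios, glog_lambda)$responses
  r <- ratios$responses
  rows <- lapply(seq_len(nrow(r)), function(f) {
    g1 <- r[f, i1]; g2 <- r[f, i2]
    fc <- exp(mean(log(g1), na.rm = TRUE) - mean(log(g2), na.rm = TRUE))
    x1 <- gl[f, i1]; x2 <- gl[f, i2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    tt <- summary_ttest(mean(x1), stats::sd(x1), length(x1),
                        mean(x2), stats::sd(x2), length(x2))
    data.frame(feature_id = ratios$features$feature_id[f],
               fc = fc, log2fc = log2(fc), p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- (out$fc >= fc_min | out$fc <= 1 / fc_min) &
    out$p < alpha
  out
}
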