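#' Orthogonal PLS discriminant analysis of a two-class matrix
#'
#' Orthogonal-signal-correction PLS with a single predictive component:
#' variation orthogonal to the class vector is iteratively removed
#' (`n_orth` components), then one predictive component is fit on the
#' filtered matrix.  With `n_orth = 0` the model reduces to
#' single-component PLS-DA.  Model quality is summarized by R2Y (fitted
#' class variance explained), Q2 (stratified k-fold cross-validated), and
#' a label-permutation p-value for Q2.  The S-plot reports, per feature,
#' the covariance and correlation of the (autoscaled) feature with the
#' predictive scores.
#'
#' @param X numeric matrix, samples x features, typically autoscaled glog
#'   ratios; no missing values.
#' @param y two-level class labels (factor or character), length
#'   `nrow(X)`.
#' @param n_orth number of orthogonal components (>= 0, < rank of X).
#' @param cv_folds folds for Q2 (capped at the smaller class size).
#' @param n_perm permutations for the Q2 null; 0 skips the test.
#' @param seed integer seed for fold assignment and permutations.
#' @return list of class `oplsda_model`: `scores` (predictive t),
#'   `orth_scores`, `loadings`, `weights`, `r2y`, `q2`, `perm_p`,
#'   `perm_q2` (null draws), `splot` (data.frame of cov/corr per
#'   feature), `classes`, `y_num`.
#' @export
oplsda_fit <- function(X, y, n_orth = 1, cv_folds = 7, n_perm = 1000,
                       seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  cls <- sort(unique(as.character(y)))
  if (length(cls) != 2) stop("y must have exactly two classes", call. = FALSE)
  if (min(table(y)) < 2)
    stop("at least two samples per class are required", call. = FALSE)
  if (n_orth >= qr(scale(X, scale = FALSE))$rank)
    stop("n_orth must be smaller than the rank of X", call. = FALSE)
  y_num <- ifelse(as.character(y) == cls[2], 1, -1)
  yc <- y_num - mean(y_num)

  core <- .opls_core(X, yc, n_orth)
  fitted <- core$t * core$q
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)

  set.seed(seed)
  folds <- .stratified_folds(y_num, cv_folds)
  q2 <- .opls_q2(X, yc, y_num, n_orth, folds)

  perm_q2 <- numeric(0)
  perm_p <- NA_real_
  if (n_perm > 0) {
    perm_q2 <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(y_num)
      fp <- .stratified_folds(yp, cv_folds)
      .opls_q2(X, yp - mean(yp), yp, n_orth, fp)
    }, numeric(1))
    perm_p <- (1 + sum(perm_q2 >= q2)) / (n_perm + 1)
  }

  t <- core$t
  splot <- data.frame(
    feature = colnames(X) %||% paste0("V", seq_len(ncol(X))),
    covariance = apply(X, 2, function(x) stats::cov(x, t)),
    correlation = apply(X, 2, function(x) {
      s <- stats::sd(x)
      if (s == 0) NA_real_ else stats::cor(x, t)
    }),
    stringsAsFactors = FALSE)

  structure(list(scores = core$t, orth_scores = core$t_orth,
                 loadings = core$p, weights = core$w,
                 orth_loadings = core$p_orth, orth_weights = core$w_orth,
                 q = core$q, r2y = r2y, q2 = q2, perm_p = perm_p,
                 perm_q2 = perm_q2, splot = splot, classes = cls,
                 y_num = y_num, n_orth = n_orth),
            class = "oplsda_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# orthogonal filtering + one predictive component; y must be centered
.opls_core <- function(X, yc, n_orth) {
  Xf <- X
  w_orth <- p_orth <- NULL
  t_orth <- NULL
  for (k in seq_len(n_orth)) {
    w <- drop(crossprod(Xf, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no orthogonal variation left to extract (component ", k, ")",
           call. = FALSE)
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
    t_orth <- cbind(t_orth, to)
  }
  w <- drop(crossprod(Xf, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xf %*% w)
  p <- drop(crossprod(Xf, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(w = w, t = t, p = p, q = q,
       w_orth = w_orth, p_orth = p_orth, t_orth = t_orth)
}

# project new samples through a fitted core
.opls_predict <- function(core, Xnew) {
  Xf <- Xnew
  n_orth <- if (is.null(core$w_orth)) 0 else ncol(core$w_orth)
  for (k in seq_len(n_orth)) {
    to <- drop(Xf %*% core$w_orth[, k])
    Xf <- Xf - tcrossprod(to, core$p_orth[, k])
  }
  drop(Xf %*% core$w) * core$q
}

.stratified_folds <- function(y_num, k) {
  n <- length(y_num)
  fold <- integer(n)
  for (cl in unique(y_num)) {
    idx <- sample(which(y_num == cl))
    fold[idx] <- rep_len(seq_len(min(k, length(idx))), length(idx))
  }
  fold
}

.opls_q2 <- function(X, yc, y_num, n_orth, folds) {
  press <- 0
  for (k in unique(folds)) {
    test <- folds == k
    if (all(test) || !any(test)) next
    ytr <- yc[!test]
    core <- .opls_core(X[!test, , drop = FALSE], ytr - mean(ytr), n_orth)
    pred <- .opls_predict(core, X[test, , drop = FALSE]) + mean(ytr)
    press <- press + sum((yc[test] - pred)^2)
  }
  1 - press / sum(yc^2)
}
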