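# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (enumeration / longhand linear algebra)
# and never call the implementation they check.

# Benjamini-Hochberg by direct step-up enumeration
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, ps * m / seq_len(m))
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- q
  out
}

# classical two-sample Hotelling T2, longhand
hotelling_oracle <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  d <- colMeans(X1) - colMeans(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S) %*% d)
}

# partial correlation from the inverse correlation matrix
pcor_oracle <- function(x, y, Z) {
  R <- stats::cor(cbind(x, y, Z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# AUC by exhaustive pairwise comparison (ties one half)
auc_oracle <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# one-component PLS1 by plain NIPALS iteration (independent of the
# closed-form route used in the package)
nipals_pls1 <- function(X, y, tol = 1e-12, maxit = 500) {
  u <- y
  w <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in seq_len(maxit)) {
    w_new <- drop(crossprod(X, u))
    w_new <- w_new / sqrt(sum(w_new^2))
    t <- drop(X %*% w_new)
    q <- sum(y * t) / sum(t^2)
    u_new <- y * q
    if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
    w <- w_new; u <- u_new
  }
  t <- drop(X %*% w)
  list(w = w, t = t, p = drop(crossprod(X, t)) / sum(t^2),
       q = sum(y * t) / sum(t^2))
}

# minimal feature table: resp matrix + auto metadata
make_ft <- function(resp, is_qc = rep(FALSE, ncol(resp)),
                    participant_id = NULL, arm = NULL, timepoint = NULL,
                    matrix_name = "plasma", run_id = NULL,
                    injection_position = seq_len(ncol(resp))) {
  nf <- nrow(resp); ns <- ncol(resp)
  fid <- sprintf("F%02d", seq_len(nf))
  sid <- sprintf("S%02d", seq_len(ns))
  if (is.null(participant_id))
    participant_id <- ifelse(is_qc, NA_character_, sprintf("P%02d", seq_len(ns)))
  if (is.null(arm)) arm <- ifelse(is_qc, NA_character_, "W-P")
  if (is.null(timepoint)) timepoint <- ifelse(is_qc, NA_character_, "baseline")
  if (is.null(run_id)) run_id <- "R01"
  feature_table(
    resp,
    data.frame(feature_id = fid, stringsAsFactors = FALSE),
    data.frame(sample_id = sid, participant_id = participant_id, arm = arm,
               timepoint = timepoint, matrix = matrix_name,
               age = 40, sex = "F", bmi = 25, run_id = run_id,
               injection_position = injection_position, is_qc = is_qc,
               stringsAsFactors = FALSE))
}

# paired two-arm table: one row per feature, columns = participants x
# (baseline, week2); values supplied as two matrices
make_paired_ft <- function(baseline, week2, arms,
                           age = NULL, sex = NULL, bmi = NULL) {
  n <- ncol(baseline)
  pid <- sprintf("P%02d", seq_len(n))
  resp <- cbind(baseline, week2)
  if (is.null(age)) age <- rep(40, n)
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  if (is.null(bmi)) bmi <- rep(25, n)
  feature_table(
    resp,
    data.frame(feature_id = sprintf("F%02d", seq_len(nrow(resp))),
               stringsAsFactors = FALSE),
    data.frame(sample_id = c(paste0(pid, "_T0"), paste0(pid, "_T2")),
               participant_id = rep(pid, 2), arm = rep(arms, 2),
               timepoint = rep(c("baseline", "week2"), each = n),
               matrix = "plasma", age = rep(age, 2), sex = rep(sex, 2),
               bmi = rep(bmi, 2), run_id = "R01",
               injection_position = seq_len(2 * n),
               is_qc = FALSE, stringsAsFactors = FALSE))
}

# noise-free simulation spec for exactness checks
noise_free_spec <- function(...) {
  simulation_spec(technical_cv = 0, biological_cv_plasma = 0,
                  biological_cv_urine = 0, drift_per_injection = 0,
                  lod_quantile = 0, nonadherent_fraction = 0,
                  dilution_cv = 0, nutrient_effect_r = 0,
                  cross_fluid_pairs = NULL, ...)
}
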