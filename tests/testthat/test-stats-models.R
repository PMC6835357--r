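test_that("BH adjustment equals the exhaustive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-15)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("volcano computes between-arm geometric fold change with BH q", {
  # identical arms: fc 1, p near 1
  r <- matrix(rep(c(1.2, 0.8, 1.0, 1.1), each = 3), 3, 4, byrow = FALSE)
  set.seed(9)
  r <- matrix(stats::rlnorm(3 * 8, 0, 0.2), 3, 8)
  r[, 5:8] <- r[, 1:4]
  ft <- feature_table(
    r, data.frame(feature_id = sprintf("F%02d", 1:3)),
    data.frame(sample_id = sprintf("P%02d", 1:8),
               participant_id = sprintf("P%02d", 1:8),
               arm = rep(c("W-P", "P-W"), each = 4),
               timepoint = "ratio", is_qc = FALSE))
  v <- volcano(ft)
  expect_equal(v$fc, rep(1, 3), tolerance = 1e-12)
  expect_true(all(v$p > 0.99))
  expect_false(any(v$significant))
  # planted fold change 2 in W-P only, noise-free
  r2 <- matrix(1, 2, 8)
  r2[1, 1:4] <- 2
  ft2 <- feature_table(r2, ft$features[1:2, , drop = FALSE], ft$samples)
  v2 <- volcano(ft2)
  expect_equal(v2$fc[1], 2, tolerance = 1e-12)
  expect_error(volcano(ft[, 1:5]), "two participants")
})

test_that("mixed ANOVA interaction equals t-squared without covariates", {
  set.seed(10)
  n <- 12
  b <- matrix(stats::rlnorm(3 * n, 5, 0.4), 3, n)
  w <- b * matrix(stats::rlnorm(3 * n, 0.2, 0.3), 3, n)
  arms <- rep(c("W-P", "P-W"), each = n / 2)
  ft <- make_paired_ft(b, w, arms)
  gl <- glog_transform(ft, 0)
  out <- mixed_anova_interaction(gl, covariates = character(0))
  for (f in 1:3) {
    d <- log2(w[f, ]) - log2(b[f, ])
    tt <- stats::t.test(d[arms == "W-P"], d[arms == "P-W"], var.equal = TRUE)
    expect_equal(out$f[f], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(out$p[f], tt$p.value, tolerance = 1e-8)
  }
  # covariate adjustment matches lm partial F
  age <- stats::runif(n, 20, 60)
  sex <- rep(c("F", "M"), n / 2)
  bmi <- stats::runif(n, 20, 35)
  ft2 <- make_paired_ft(b, w, arms, age = age, sex = sex, bmi = bmi)
  gl2 <- glog_transform(ft2, 0)
  out2 <- mixed_anova_interaction(gl2)
  d <- log2(w[1, ]) - log2(b[1, ])
  sex_num <- as.numeric(factor(sex)) - 1
  fit <- stats::lm(d ~ factor(arms, levels = c("P-W", "W-P")) + age +
                     sex_num + bmi)
  tv <- summary(fit)$coefficients[2, "t value"]
  expect_equal(out2$f[1], unname(tv)^2, tolerance = 1e-8)
  # a covariate collinear with arm is reported
  ft3 <- make_paired_ft(b, w, arms, age = (arms == "W-P") * 10)
  expect_error(mixed_anova_interaction(glog_transform(ft3, 0),
                                       covariates = "age"),
               "collinear")
})

test_that("partial correlation matches the inverse-correlation oracle", {
  # plain Pearson without covariates
  pc <- partial_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pc$r, 1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    Z <- matrix(stats::rnorm(n * 2), n, 2)
    x <- stats::rnorm(n) + Z %*% c(1, -0.5)
    y <- stats::rnorm(n) + Z %*% c(0.3, 0.8)
    pc <- partial_correlation(drop(x), drop(y), Z)
    expect_equal(pc$r, pcor_oracle(drop(x), drop(y), Z), tolerance = 1e-10)
    expect_equal(pc$df, n - 4)
  }
  # residualizing y on itself yields an undefined flag, not zero
  z <- stats::rnorm(20)
  pc2 <- partial_correlation(stats::rnorm(20), z, cbind(z))
  expect_false(pc2$defined)
  expect_true(is.na(pc2$r))
  # listwise deletion
  x <- c(1:9, NA); y <- c(NA, 2:10)
  pc3 <- partial_correlation(x, y)
  expect_equal(pc3$n_used, 8)
})

test_that("partial correlation recovers a known generating coefficient", {
  set.seed(12)
  rho <- 0.5
  n <- 2000
  z <- stats::rnorm(n)
  e <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(rbind(c(1, rho), c(rho, 1)))
  x <- 2 * z + e[, 1]
  y <- -z + e[, 2]
  pc <- partial_correlation(x, y, cbind(z))
  expect_lt(abs(pc$r - rho), 0.05)
})

test_that("ROC AUC equals exhaustive pair enumeration", {
  r <- roc_auc(c(1, 2, 3, 4, 5, 6),
               rep(c("a", "b"), each = 3), positive_class = "b")
  expect_equal(r$auc, 1)
  r2 <- roc_auc(c(1, 3, 2, 4), c("b", "b", "a", "a"), positive_class = "b")
  expect_equal(r2$auc, 1 / 4)
  set.seed(13)
  for (n1 in 2:6) for (n2 in 2:6) {
    pos <- sample(1:8, n1, replace = TRUE)
    neg <- sample(1:8, n2, replace = TRUE)
    got <- roc_auc(c(pos, neg), rep(c("pos", "neg"), c(n1, n2)),
                   positive_class = "pos")
    expect_equal(got$auc, auc_oracle(pos, neg), tolerance = 1e-12)
    # label inversion flips the AUC
    inv <- roc_auc(c(pos, neg), rep(c("pos", "neg"), c(n1, n2)),
                   positive_class = "neg")
    expect_equal(inv$auc, 1 - got$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c("a", "a", "a")), "two classes")
})

test_that("ROC AUC agrees with an established implementation", {
  set.seed(99)
  v <- stats::rnorm(40)
  lab <- rep(c("a", "b"), 20)
  v[lab == "b"] <- v[lab == "b"] + 1
  got <- roc_auc(v, lab, positive_class = "b")$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = v, levels = c("a", "b"),
    direction = "<"))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("ROC sensitivity/specificity at Youden match a perfect marker", {
  r <- roc_auc(c(10:14, 1:5), rep(c("p", "n"), each = 5),
               positive_class = "p")
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_lt(r$p, 0.05)
})
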