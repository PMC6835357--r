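test_that("internal-standard and creatinine normalization are exact ratios", {
  resp <- rbind(c(4, 6, 8), c(2, 2, 2), c(1, 2, 4))
  ft <- make_ft(resp)
  norm <- normalize_internal_standard(ft, "F02")
  expect_equal(unname(norm$responses[1, ]), c(2, 3, 4))
  expect_false("F02" %in% norm$features$feature_id)
  # IS column identical to a feature column -> all ones
  expect_equal(unname(norm$responses["F03", ] /
                        (resp[3, ] / resp[2, ])), rep(1, 3))
  resp2 <- resp; resp2[2, 2] <- NA
  expect_error(normalize_internal_standard(make_ft(resp2), "F02"), "S02")
  # dilution invariance: doubling a sample's dilution leaves normalized
  # values unchanged when creatinine scales with it
  resp3 <- rbind(c(10, 20), c(5, 10))
  ft3 <- make_ft(resp3)
  norm3 <- normalize_internal_standard(ft3, "F02")
  expect_equal(unname(norm3$responses[1, 1]), unname(norm3$responses[1, 2]))
})

test_that("creatinine normalization shrinks urinary biological variance", {
  st <- generate_study(simulation_spec(seed = 41))
  raw <- st$urine
  norm <- normalize_creatinine(raw, "creatinine")
  bsel <- !qc_mask(raw) & raw$samples$timepoint == "baseline"
  cv <- function(tab, sel) {
    anal <- tab$features$role == "analyte"
    stats::median(apply(tab$responses[anal, sel], 1, function(v)
      stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)), na.rm = TRUE)
  }
  expect_lt(cv(norm, bsel), cv(raw, bsel))
})

test_that("detection filter applies the >= threshold on non-QC samples", {
  set.seed(3)
  resp <- matrix(stats::rlnorm(3 * 44, 5, 0.3), 3, 44)
  is_qc <- c(rep(FALSE, 42), TRUE, TRUE)
  resp[1, 1:11] <- NA   # 31/42 = 73.8% -> removed
  resp[2, 1:10] <- NA   # 32/42 = 76.2% -> retained
  ft <- make_ft(resp, is_qc = is_qc,
                participant_id = c(sprintf("P%02d", 1:42), NA, NA),
                arm = c(rep("W-P", 42), NA, NA),
                timepoint = c(rep("baseline", 42), NA, NA))
  fd <- filter_detection(ft, 0.75)
  expect_identical(fd$table$features$feature_id, c("F02", "F03"))
  expect_equal(fd$summary$reason, c("low-detection", "ok", "ok"))
  expect_equal(fd$summary$detection_fraction[1:2], c(31, 32) / 42)
  all_pass <- filter_detection(ft, 0.5)
  expect_equal(nrow(all_pass$table$responses), 3)
})

test_that("QC-CV filter computes SD/mean over QC injections", {
  resp <- rbind(c(rep(50, 4), 10, 10, 10),
                c(rep(50, 4), 8, 10, 12),
                c(rep(50, 4), 5, 10, 15))
  is_qc <- c(rep(FALSE, 4), TRUE, TRUE, TRUE)
  ft <- make_ft(resp, is_qc = is_qc,
                participant_id = c(sprintf("P%02d", 1:4), NA, NA, NA),
                arm = c(rep("W-P", 4), NA, NA, NA),
                timepoint = c(rep("baseline", 4), NA, NA, NA))
  fc <- filter_qc_cv(ft, 0.30)
  expect_equal(fc$summary$qc_cv, c(0, 2 / 10, stats::sd(c(5, 10, 15)) / 10),
               tolerance = 1e-12)
  expect_identical(fc$table$features$feature_id, c("F01", "F02"))
  expect_equal(fc$summary$reason, c("ok", "ok", "high-cv"))
})

test_that("filters commute as a set intersection", {
  set.seed(4)
  st <- generate_study(simulation_spec(seed = 4, lod_quantile = 0.2,
                                       drift_per_injection = 0.005))
  ft <- normalize_internal_standard(st$plasma, "IS_ClTyr")
  a <- filter_qc_cv(filter_detection(ft, 0.75)$table, 0.3)$table
  b <- filter_detection(filter_qc_cv(ft, 0.3)$table, 0.75)$table
  expect_identical(sort(a$features$feature_id), sort(b$features$feature_id))
})

test_that("half-minimum imputation follows the published rule exactly", {
  resp <- rbind(c(4, NA, 8), c(1, 2, 3), c(0.5, NA, NA))
  ft <- make_ft(resp)
  imp <- impute_half_min(ft)
  expect_equal(unname(imp$responses[1, ]), c(4, 2, 8))
  expect_equal(unname(imp$responses[2, ]), c(1, 2, 3))  # untouched
  expect_equal(unname(imp$responses[3, ]), c(0.5, 0.25, 0.25))
  expect_identical(impute_half_min(imp)$responses, imp$responses)
  allna <- make_ft(rbind(c(NA, NA, NA)))
  expect_error(impute_half_min(allna), "no positive observed response")
})

test_that("glog reduces to log2 at lambda 0 and is strictly monotone", {
  ft <- make_ft(rbind(c(8, 1, 2)))
  g0 <- glog_transform(ft, 0)
  expect_equal(unname(g0$responses[1, ]), log2(c(8, 1, 2)))
  g2 <- glog_transform(make_ft(rbind(c(0, 2, 10))), 2)
  expect_equal(unname(g2$responses[1, 1]), 0)  # log2((0+2)/2)
  xs <- sort(stats::runif(50, 0, 100))
  for (lam in c(0.1, 1, 17)) {
    g <- log2((xs + sqrt(xs^2 + lam^2)) / 2)
    expect_true(all(diff(g) > 0))
  }
  expect_error(glog_transform(ft, -1), "nonnegative")
  # auto lambda = smallest positive response
  ga <- glog_transform(make_ft(rbind(c(0.25, 4, 16))), "auto")
  expect_equal(attr(ga, "glog_lambda"), 0.25)
})

test_that("autoscaling yields mean 0 and unit SD, dropping constants", {
  ft <- make_ft(rbind(c(1, 2, 3), c(7, 7, 7)))
  expect_warning(sc <- autoscale(ft), "constant")
  expect_equal(unname(sc$responses[1, ]), c(-1, 0, 1))
  expect_equal(nrow(sc$responses), 1)
  expect_identical(attr(sc, "excluded_constant"), "F02")
  set.seed(5)
  big <- make_ft(matrix(stats::rlnorm(200), 10, 20))
  sb <- autoscale(big)
  expect_equal(unname(rowMeans(sb$responses)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(sb$responses, 1, stats::sd)), rep(1, 10),
               tolerance = 1e-12)
})

test_that("paired ratios divide week2 by baseline per participant", {
  b <- rbind(c(2, 4, 8, 2), c(1, 1, 1, 1))
  w <- rbind(c(4, 4, 16, 1), c(1, 1, 1, 1))
  ft <- make_paired_ft(b, w, arms = c("W-P", "W-P", "P-W", "P-W"))
  r <- paired_ratios(ft)
  expect_equal(unname(r$responses[1, ]), c(2, 1, 2, 0.5))
  expect_equal(unname(r$responses[2, ]), rep(1, 4))
  expect_identical(r$samples$sample_id, sprintf("P%02d", 1:4))
  # participant missing week2 is dropped with a warning
  ft2 <- ft[, -6]
  expect_warning(r2 <- paired_ratios(ft2), "P02")
  expect_equal(ncol(r2$responses), 3)
  # zero baseline cannot form a ratio
  b3 <- b; b3[1, 1] <- 0
  expect_error(paired_ratios(make_paired_ft(b3, w,
                                            arms = rep("W-P", 4))),
               "cannot form ratio")
})

test_that("noise-free pipeline reproduces planted fold changes end to end", {
  spec <- noise_free_spec(
    planted_features = data.frame(feature = 1, matrix = "plasma",
                                  direction = "prudent-up", fold_change = 2,
                                  nutrient = "total_fiber"),
    seed = 9)
  st <- generate_study(spec)
  # constant null features cannot be autoscaled in the noise-free limit
  suppressWarnings(pp <- preprocess_matrix(st$plasma, pipeline_config(),
                                           "plasma"))
  arm <- pp$ratios$samples$arm
  expect_equal(unname(pp$ratios$responses[1, arm == "W-P"]),
               rep(2, sum(arm == "W-P")), tolerance = 1e-9)
  expect_equal(unname(pp$ratios$responses[1, arm == "P-W"]),
               rep(1, sum(arm == "P-W")), tolerance = 1e-9)
})
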