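test_that("generation is deterministic and structurally sound", {
  st1 <- generate_study(simulation_spec(seed = 11))
  st2 <- generate_study(simulation_spec(seed = 11))
  expect_identical(st1$plasma$responses, st2$plasma$responses)
  expect_identical(st1$nutrients, st2$nutrients)
  st3 <- generate_study(simulation_spec(seed = 12))
  expect_false(identical(st1$plasma$responses, st3$plasma$responses))
  # structure: 42 participants x 2 timepoints + one QC per run of 6
  expect_equal(sum(!qc_mask(st1$plasma)), 84)
  expect_equal(sum(qc_mask(st1$plasma)), 14)
  expect_equal(nrow(st1$plasma$responses), 81)  # 80 analytes + IS
  expect_equal(nrow(st1$urine$responses), 86)   # 84 + creatinine + IS
  # every run has exactly one QC
  sm <- st1$plasma$samples
  qc_per_run <- tapply(qc_mask(st1$plasma), sm$run_id, sum)
  expect_true(all(qc_per_run == 1))
  expect_false(any(duplicated(sm$injection_position)))
  validate_feature_table(st1$plasma)
  validate_feature_table(st1$urine)
})

test_that("noise-free generation reproduces planted fold changes exactly", {
  spec <- noise_free_spec(
    planted_features = data.frame(feature = 3, matrix = "plasma",
                                  direction = "prudent-up", fold_change = 2,
                                  nutrient = "total_fiber"),
    seed = 5)
  st <- generate_study(spec)
  sm <- st$plasma$samples
  arm <- st$truth$participants$arm_effective
  for (i in seq_len(nrow(st$truth$participants))) {
    pid <- st$truth$participants$participant_id[i]
    b <- st$plasma$responses[, sm$participant_id %in% pid &
                               sm$timepoint == "baseline"]
    w <- st$plasma$responses[, sm$participant_id %in% pid &
                               sm$timepoint == "week2"]
    ratio <- w / b
    if (arm[i] == "W-P") expect_equal(unname(ratio[3]), 2, tolerance = 1e-12)
    else expect_equal(unname(ratio[3]), 1, tolerance = 1e-12)
    expect_equal(unname(ratio[-3]), rep(1, 80), tolerance = 1e-12)
  }
})

test_that("QC and biological CVs land in the emulated bands over seeds", {
  qc_med <- bio_med <- numeric(0)
  for (seed in 1:8) {
    st <- generate_study(simulation_spec(seed = seed))
    qc <- qc_mask(st$plasma)
    analyte <- st$plasma$features$role == "analyte"
    qcv <- apply(st$plasma$responses[analyte, qc], 1, function(v)
      stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
    qc_med <- c(qc_med, stats::median(qcv, na.rm = TRUE))
    # biological CV of urine analytes at baseline (before any normalization
    # the dilution contributes too, so compute on creatinine-normalized)
    ur <- normalize_creatinine(st$urine, "creatinine")
    bsel <- !qc_mask(ur) & ur$samples$timepoint == "baseline"
    anal_u <- ur$features$role == "analyte"
    bcv <- apply(ur$responses[anal_u, bsel], 1, function(v)
      stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
    bio_med <- c(bio_med, stats::median(bcv, na.rm = TRUE))
  }
  expect_gte(stats::median(qc_med), 0.04)
  expect_lte(stats::median(qc_med), 0.12)
  expect_gte(stats::median(bio_med), 0.55)
  expect_lte(stats::median(bio_med), 0.90)
})

test_that("planted effect sizes are recoverable from the default generator", {
  st <- generate_study(simulation_spec(seed = 21))
  ratios <- paired_ratios(impute_half_min(st$plasma))
  planted <- st$truth$planted[st$truth$planted$matrix == "plasma", ]
  arm <- ratios$samples$arm
  for (k in seq_len(nrow(planted))) {
    f <- match(planted$feature_id[k], ratios$features$feature_id)
    on_arm <- if (planted$direction[k] == "prudent-up") "W-P" else "P-W"
    lr <- log(ratios$responses[f, arm == on_arm])
    se <- stats::sd(lr) / sqrt(length(lr))
    expect_lt(abs(mean(lr) - log(planted$fold_change[k])), 3 * se + 0.05)
  }
})

test_that("nutrient blocks are strongly co-linear with opposite signs", {
  st <- generate_study(simulation_spec(seed = 31))
  nd <- nutrient_delta_matrix(st$nutrients)
  cats <- nutrient_categories()
  prud <- intersect(colnames(nd), cats$category[cats$block == "prudent"])
  west <- intersect(colnames(nd), cats$category[cats$block == "western"])
  # within-block pairs positively correlated, cross-block negatively
  r_within <- stats::cor(nd[, "insoluble_fiber"], nd[, "magnesium"])
  r_cross <- stats::cor(nd[, "insoluble_fiber"], nd[, "sat_fat_pct"])
  expect_gt(r_within, 0.7)
  expect_lt(r_cross, -0.7)
})

test_that("drift applies the closed-form factor and censoring the exact count", {
  resp <- matrix(100, 2, 10)
  ft <- make_ft(resp, injection_position = 1:10)
  d0 <- apply_drift(ft, 0)
  expect_equal(d0$table$responses, ft$responses)
  d1 <- apply_drift(ft, 0.01)
  expect_equal(unname(d1$table$responses[1, 10]), 100 * 1.01^10,
               tolerance = 1e-12)
  expect_equal(unname(d1$drift$factors[1, 10]), 1.01^10, tolerance = 1e-12)
  dn <- apply_drift(ft, -0.005)
  expect_true(all(diff(dn$table$responses[1, ]) < 0))
  # censoring: quantile 0.2 on 10 distinct samples -> exactly 2 missing
  set.seed(2)
  ft2 <- make_ft(matrix(stats::runif(20, 1, 100), 2, 10))
  cl <- censor_lod(ft2, 0.2)
  expect_equal(unname(rowSums(is.na(cl$table$responses))), c(2, 2))
  cl0 <- censor_lod(ft2, 0)
  expect_identical(cl0$table$responses, ft2$responses)
})

test_that("planted index out of range is rejected", {
  expect_error(simulation_spec(planted_features = data.frame(
    feature = 99, matrix = "plasma", direction = "prudent-up",
    fold_change = 2)), "out of range")
})
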