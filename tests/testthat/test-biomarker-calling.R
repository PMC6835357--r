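fixture_models <- function() {
  ids <- c("F01", "F02", "F03")
  meba <- data.frame(feature_id = ids, t2 = c(20, 15, 10),
                     p = c(0.01, 0.01, 0.20), rank = 1:3)
  anova <- data.frame(feature_id = ids, f = c(8, 1, 9),
                      p = c(0.02, 0.30, 0.01), df1 = 1, df2 = 37)
  vol <- data.frame(feature_id = ids, fc = c(2, 1.1, 1.5),
                    p = c(0.001, 0.4, 0.01), q = c(0.20, 0.6, 0.03),
                    significant = c(TRUE, FALSE, TRUE))
  pc <- rbind(
    data.frame(feature_id = "F01", nutrient = paste0("N", 1:3),
               r = c(0.35, 0.41, 0.10), p = c(0.03, 0.01, 0.5), n_used = 42),
    data.frame(feature_id = "F02", nutrient = paste0("N", 1:3),
               r = c(0.45, 0.21, 0.05), p = c(0.01, 0.2, 0.9), n_used = 42),
    data.frame(feature_id = "F03", nutrient = paste0("N", 1:3),
               r = c(0.35, -0.1, 0.02), p = c(0.03, 0.5, 0.9), n_used = 42))
  list(meba = meba, anova = anova, vol = vol, pc = pc)
}

test_that("robust calls follow the two-models + two-nutrients rule exactly", {
  fx <- fixture_models()
  out <- call_robust(fx$meba, fx$anova, fx$vol, fx$pc, pipeline_config())
  # F01: MEBA + ANOVA pass, volcano q = 0.2 fails; two nutrient hits -> robust
  expect_equal(out$n_models_passed[1], 2)
  expect_equal(out$n_nutrient_hits[1], 2)
  expect_true(out$robust[1])
  # F02: only MEBA passes -> not robust despite a nutrient hit
  expect_equal(out$n_models_passed[2], 1)
  expect_false(out$robust[2])
  # F03: ANOVA + volcano pass but a single nutrient hit -> not robust
  expect_equal(out$n_models_passed[3], 2)
  expect_equal(out$n_nutrient_hits[3], 1)
  expect_false(out$robust[3])
  # top-5 nutrients sorted by |r| with sign preserved
  expect_match(out$top5_r[1], "^0.410;0.350")
})

test_that("a feature with three models but one nutrient hit stays uncalled", {
  fx <- fixture_models()
  fx$vol$q[3] <- 0.01
  fx$meba$p[3] <- 0.01
  out <- call_robust(fx$meba, fx$anova, fx$vol, fx$pc, pipeline_config())
  expect_equal(out$n_models_passed[3], 3)
  expect_false(out$robust[3])
})

test_that("robust calling is monotone in p and |r|", {
  fx <- fixture_models()
  cfg <- pipeline_config()
  base <- call_robust(fx$meba, fx$anova, fx$vol, fx$pc, cfg)
  # lowering a p-value can only keep or create calls
  fx2 <- fx; fx2$vol$q <- fx$vol$q / 10
  out2 <- call_robust(fx2$meba, fx2$anova, fx2$vol, fx2$pc, cfg)
  expect_true(all(out2$robust >= base$robust))
  # raising |r| of nutrient correlations likewise
  fx3 <- fx; fx3$pc$r <- sign(fx3$pc$r) * pmin(abs(fx3$pc$r) * 1.5, 0.99)
  out3 <- call_robust(fx3$meba, fx3$anova, fx3$vol, fx3$pc, cfg)
  expect_true(all(out3$robust >= base$robust))
  # feature reordering does not change the decisions
  fx4 <- lapply(fx[c("meba", "anova", "vol")], function(d) d[c(3, 1, 2), ])
  out4 <- call_robust(fx4$meba, fx4$anova, fx4$vol, fx$pc, cfg)
  expect_equal(out4$robust[match(base$feature_id, out4$feature_id)],
               base$robust)
  # missing feature in one model set is an error
  expect_error(call_robust(fx$meba[1:2, ], fx$anova, fx$vol, fx$pc, cfg),
               "different features")
})

test_that("the section 2.7 rule variant is reachable via configuration", {
  fx <- fixture_models()
  strict <- pipeline_config(n_nutrient_min = 3)
  out <- call_robust(fx$meba, fx$anova, fx$vol, fx$pc, strict)
  expect_false(any(out$robust))
})

test_that("cross-fluid correlation is exact for proportional features", {
  st <- generate_study(simulation_spec(seed = 61, lod_quantile = 0))
  pl <- impute_half_min(st$plasma)
  ur <- normalize_creatinine(impute_half_min(st$urine), "creatinine")
  # urine feature forced to be twice the plasma feature on matched samples
  key_p <- paste(pl$samples$participant_id, pl$samples$timepoint)
  key_u <- paste(ur$samples$participant_id, ur$samples$timepoint)
  idx <- match(key_p[!qc_mask(pl)], key_u)
  ur$responses[1, idx] <- 2 * pl$responses[1, which(!qc_mask(pl))]
  out <- cross_fluid_correlation(pl, ur, data.frame(
    plasma_id = "PL001", urine_id = "UR001"))
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n, 84)
  # independent features stay near zero
  out0 <- cross_fluid_correlation(pl, ur, data.frame(
    plasma_id = "PL010", urine_id = "UR010"))
  expect_lt(abs(out0$r), 0.35)
  expect_error(cross_fluid_correlation(pl, ur, data.frame(
    plasma_id = "nope", urine_id = "UR001")), "not found")
})

test_that("trajectory summaries report fold changes, baseline p and outliers", {
  spec <- noise_free_spec(
    planted_features = data.frame(feature = 1, matrix = "plasma",
                                  direction = "prudent-up", fold_change = 2,
                                  nutrient = "total_fiber"),
    seed = 62)
  st <- generate_study(spec)
  ts <- summarize_trajectories(impute_half_min(st$plasma), "PL001")
  expect_equal(ts$wp_fold_change, 2, tolerance = 1e-9)
  expect_equal(ts$pw_fold_change, 1, tolerance = 1e-9)
  expect_equal(ts$outliers, "")
  # an injected reversed-effect participant becomes an outlier
  st2 <- generate_study(simulation_spec(seed = 63, nonadherent_fraction = 0))
  tab <- impute_half_min(st2$plasma)
  sm <- tab$samples
  planted <- "PL001"  # fold change 5 by default
  wp_ids <- unique(sm$participant_id[!qc_mask(tab) & sm$arm == "W-P"])
  victim <- wp_ids[1]
  wsel <- sm$participant_id %in% victim & sm$timepoint == "week2"
  f <- match(planted, tab$features$feature_id)
  tab$responses[f, wsel] <- tab$responses[f, wsel] / 25
  ts2 <- summarize_trajectories(tab, planted)
  expect_true(grepl(victim, ts2$outliers))
})
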