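#' Reference table of nutrient categories
#'
#' The 20 micro- and macronutrient categories tracked by the diet records,
#' with units, block membership (whether intake rises under a Prudent or a
#' Western eating pattern), typical baseline intake, and the default
#' intervention deltas (mean and SD per arm) used by the synthetic-study
#' generator.  Delta units are per 2000 kcal except the energy-% and
#' ratio categories.
#'
#' @return data.frame with one row per category.
#' @export
nutrient_categories <- function() {
  # columns: category, unit, block, base mean/sd, W-P delta mean/sd, P-W delta mean/sd
  x <- rbind(
    c("insoluble_fiber",     "g/2000 kcal",        "prudent",  11,   4,    14.0,  5.3,   -5.0,  3.5),
    c("magnesium",           "mg/2000 kcal",       "prudent", 320,  80,   189,   89,   -134,  70),
    c("fruits_veg_servings", "servings/2000 kcal", "prudent",  3.5, 1.5,    3.6,  1.4,   -1.8,  1.3),
    c("total_fiber",         "g/2000 kcal",        "prudent",  18,   6,    16.6,  8.4,  -13.4,  8.1),
    c("sat_fat_pct",         "% energy",           "western",  12,   3,    -5.4,  3.2,    4.6,  2.4),
    c("potassium",           "mg/2000 kcal",       "prudent", 2800, 700, 1338,  617,   -854, 667),
    c("vegetable_cup_eq",    "cup eq./2000 kcal",  "prudent",  1.5, 0.6,    1.8,  0.80,  -0.91, 0.92),
    c("vitamin_e",           "mg/2000 kcal",       "prudent",  10,   4,     7.7,  5.3,   -7.0,  4.0),
    c("poly_sat_ratio",      "ratio",              "prudent",  0.55, 0.15,  0.47, 0.21,  -0.14, 0.18),
    c("vitamin_c",           "mg/2000 kcal",       "prudent",  80,  40,   149,   69,    -40,  54),
    c("soluble_fiber",       "g/2000 kcal",        "prudent",   5,   2,     3.9,  2.1,   -1.5,  1.5),
    c("fruit_cup_eq",        "cup eq./2000 kcal",  "prudent",  1.0, 0.5,    1.79, 0.93,  -0.92, 0.99),
    c("fat_pct",             "% energy",           "western",  33,   5,    -7.5,  5.6,    5.6,  5.6),
    c("sodium",              "mg/2000 kcal",       "western", 3400, 800,  -694,  590,    754, 658),
    c("vitamin_a",           "ug/2000 kcal",       "prudent", 800,  400, 12973, 56344, -7847, 14060),
    c("sugar_pct",           "% energy",           "prudent",  18,   5,     8.9,  5.4,   -1.5,  5.8),
    c("protein_pct",         "% energy",           "prudent",  16,   3,     1.9,  3.6,   -3.2,  2.7),
    c("carb_pct",            "% energy",           "prudent",  48,   7,     8.5,  7.8,   -0.35, 5.7),
    c("cholesterol",         "mg/2000 kcal",       "western", 300, 100,  -101,  140,     54, 110),
    c("trans_fat_pct",       "% energy",           "western",  1.2, 0.5,   -0.26, 0.55,   0.27, 0.23)
  )
  out <- data.frame(
    category = x[, 1], unit = x[, 2], block = x[, 3],
    stringsAsFactors = FALSE
  )
  num <- apply(x[, 4:9], 2, as.numeric)
  colnames(num) <- c("base_mean", "base_sd", "wp_delta_mean", "wp_delta_sd",
                     "pw_delta_mean", "pw_delta_sd")
  cbind(out, num)
}

#' Default planted-biomarker layout
#'
#' Six diet-responsive features per matrix (12 in total) spanning fold
#' changes 1.5 to 5 in both directions, each matched to a nutrient
#' category of the corresponding block for correlation coupling.
#'
#' @return data.frame with columns `feature`, `matrix`, `direction`,
#'   `fold_change`, `nutrient`.
#' @export
default_planted_features <- function() {
  prud <- c("insoluble_fiber", "fruits_veg_servings", "potassium",
            "magnesium", "vitamin_c", "total_fiber")
  west <- c("sat_fat_pct", "fat_pct", "sodium", "trans_fat_pct",
            "cholesterol")
  lay <- function(mat) {
    dir <- c("prudent-up", "prudent-up", "western-up", "western-up",
             "prudent-up", "western-up")
    fc <- c(5, 4, 3, 2.5, 2, 1.5)
    nut <- ifelse(dir == "prudent-up",
                  prud[cumsum(dir == "prudent-up")],
                  west[cumsum(dir == "western-up")])
    data.frame(feature = 1:6, matrix = mat, direction = dir,
               fold_change = fc, nutrient = nut, stringsAsFactors = FALSE)
  }
  rbind(lay("plasma"), lay("urine"))
}

#' Specification of a synthetic two-arm dietary intervention study
#'
#' Defaults emulate the cohort the pipeline was designed for: 24
#' participants assigned the Prudent diet after a Western baseline (arm
#' W-P), 18 assigned the Western diet (arm P-W), 80 plasma and 84 urinary
#' features, QC technical CV around 10%, biological CV 45% (plasma) and
#' 70% (urine), multiplicative signal drift along the injection sequence,
#' below-LOD censoring, one non-adherent participant, and nutrient
#' coupling of planted biomarkers at a nominal r of 0.5.
#'
#' @param n_wp,n_pw participants per arm.
#' @param n_features_plasma,n_features_urine analyte features per matrix
#'   (an internal standard row, and for urine a creatinine row, are added
#'   on top).
#' @param n_nutrients number of nutrient categories (at most 20).
#' @param planted_features data.frame as [default_planted_features()];
#'   `NULL` plants nothing.
#' @param technical_cv QC/technical coefficient of variation.
#' @param biological_cv_plasma,biological_cv_urine between+within subject
#'   biological CV per matrix.
#' @param drift_per_injection mean multiplicative drift per injection.
#' @param lod_quantile per-feature quantile censored as below-LOD.
#' @param nonadherent_fraction fraction of participants who eat (and
#'   report) the opposite arm's diet.
#' @param nutrient_effect_r nominal correlation between a planted
#'   feature's response change and its matched nutrient delta.
#' @param cross_fluid_pairs data.frame(`plasma_feature`, `urine_feature`,
#'   `r`) of feature index pairs whose biological levels are coupled
#'   across matrices.
#' @param dilution_cv CV of per-sample urinary dilution (hydration).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_wp = 24, n_pw = 18,
                            n_features_plasma = 80, n_features_urine = 84,
                            n_nutrients = 20,
                            planted_features = default_planted_features(),
                            technical_cv = 0.10,
                            biological_cv_plasma = 0.45,
                            biological_cv_urine = 0.70,
                            drift_per_injection = 0.001,
                            lod_quantile = 0.05,
                            nonadherent_fraction = 1 / 42,
                            nutrient_effect_r = 0.5,
                            cross_fluid_pairs = data.frame(
                              plasma_feature = 40, urine_feature = 40,
                              r = 0.6),
                            dilution_cv = 0.4,
                            seed = 1L) {
  spec <- list(n_wp = n_wp, n_pw = n_pw,
               n_features_plasma = n_features_plasma,
               n_features_urine = n_features_urine,
               n_nutrients = n_nutrients,
               planted_features = planted_features,
               technical_cv = technical_cv,
               biological_cv_plasma = biological_cv_plasma,
               biological_cv_urine = biological_cv_urine,
               drift_per_injection = drift_per_injection,
               lod_quantile = lod_quantile,
               nonadherent_fraction = nonadherent_fraction,
               nutrient_effect_r = nutrient_effect_r,
               cross_fluid_pairs = cross_fluid_pairs,
               dilution_cv = dilution_cv,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  chk <- function(ok, msg) if (!ok) stop("simulation_spec: ", msg, call. = FALSE)
  for (p in c("n_wp", "n_pw", "n_features_plasma", "n_features_urine",
              "n_nutrients"))
    chk(spec[[p]] >= 1 && spec[[p]] == round(spec[[p]]),
        paste(p, "must be a positive integer"))
  chk(spec$n_nutrients <= nrow(nutrient_categories()),
      "n_nutrients exceeds the number of known categories")
  for (p in c("technical_cv", "biological_cv_plasma", "biological_cv_urine",
              "lod_quantile", "nonadherent_fraction", "dilution_cv"))
    chk(spec[[p]] >= 0 && spec[[p]] < 1, paste(p, "must be in [0, 1)"))
  chk(abs(spec$nutrient_effect_r) < 1, "nutrient_effect_r must be in (-1, 1)")
  pf <- spec$planted_features
  if (!is.null(pf) && nrow(pf) > 0) {
    chk(all(pf$matrix %in% c("plasma", "urine")),
        "planted matrix must be 'plasma' or 'urine'")
    chk(all(pf$direction %in% c("prudent-up", "western-up")),
        "planted direction must be 'prudent-up' or 'western-up'")
    chk(all(pf$fold_change > 1), "planted fold_change must exceed 1")
    nmax <- ifelse(pf$matrix == "plasma", spec$n_features_plasma,
                   spec$n_features_urine)
    if (any(pf$feature < 1 | pf$feature > nmax))
      stop("simulation_spec: planted feature index out of range",
           call. = FALSE)
  }
  cp <- spec$cross_fluid_pairs
  if (!is.null(cp) && nrow(cp) > 0) {
    chk(all(cp$plasma_feature >= 1 & cp$plasma_feature <= spec$n_features_plasma),
        "cross_fluid plasma feature index out of range")
    chk(all(cp$urine_feature >= 1 & cp$urine_feature <= spec$n_features_urine),
        "cross_fluid urine feature index out of range")
    chk(all(abs(cp$r) < 1), "cross_fluid r must be in (-1, 1)")
  }
  invisible(spec)
}

# variance of log response implied by a CV under the log-normal model
.lncv2 <- function(cv) log(1 + cv^2)

# share of biological log-variance that is between-subject (the rest is
# visit-to-visit); metabolite two-week reliability is typically ~0.6
.ICC <- 0.6

#' Generate a complete synthetic study
#'
#' Produces paired baseline/week-2 plasma and urine feature tables with
#' pooled-QC injections (one QC per run of six study samples), nutrient
#' records for both periods, and a ground-truth object recording every
#' planted effect, applied drift factor, censoring threshold, dilution
#' factor and non-adherent participant.
#'
#' Model: responses are log-normal around a per-feature abundance;
#' biological variance splits into a stable between-subject component and
#' a visit component; planted features are multiplied by their fold
#' change at week 2 in the arm whose assigned diet matches the planted
#' direction (non-adherent participants receive the opposite arm's
#' effect); urine samples carry a per-sample multiplicative dilution
#' factor shared by all urinary features including creatinine; the
#' internal-standard feature carries technical noise only.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `plasma`, `urine` (feature tables),
#'   `nutrients` (data.frame), and `truth`.
#' @export
generate_study <- function(spec = simulation_spec()) {
  validate_simulation_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_wp + spec$n_pw
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    arm = c(rep("W-P", spec$n_wp), rep("P-W", spec$n_pw)),
    age = round(stats::runif(n, 21, 60)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    bmi = round(stats::rnorm(n, 26, 3.5), 1),
    stringsAsFactors = FALSE
  )
  n_nonadh <- round(spec$nonadherent_fraction * n)
  nonadherent <- if (n_nonadh > 0) sample(participants$participant_id, n_nonadh)
                 else character(0)
  participants$arm_effective <- ifelse(
    participants$participant_id %in% nonadherent,
    ifelse(participants$arm == "W-P", "P-W", "W-P"),
    participants$arm)
  z <- stats::rnorm(n)  # adherence-intensity latent, shared across layers

  nutrients <- .gen_nutrients(spec, participants, z)

  # shared biological deviations for cross-fluid coupled pairs, one draw
  # per (participant, timepoint); the urine side mixes in an independent
  # component to hit the nominal log-scale correlation after accounting
  # for technical and creatinine-normalization noise
  cp <- spec$cross_fluid_pairs
  g_shared <- if (!is.null(cp) && nrow(cp) > 0)
    matrix(stats::rnorm(n * 2), n, 2) else NULL

  pl <- .gen_matrix("plasma", spec, participants, z, nutrients, g_shared)
  ur <- .gen_matrix("urine", spec, participants, z, nutrients, g_shared)

  truth <- list(
    planted = .planted_ids(spec),
    nonadherent = nonadherent,
    participants = participants,
    cross_fluid = .cross_fluid_ids(spec),
    drift = list(plasma = pl$drift, urine = ur$drift),
    lod = list(plasma = pl$lod, urine = ur$lod),
    dilution = ur$dilution,
    is_feature = "IS_ClTyr",
    creatinine_feature = "creatinine"
  )
  list(plasma = pl$table, urine = ur$table, nutrients = nutrients,
       truth = truth)
}

.planted_ids <- function(spec) {
  pf <- spec$planted_features
  if (is.null(pf) || nrow(pf) == 0)
    return(data.frame(feature_id = character(0), matrix = character(0),
                      direction = character(0), fold_change = numeric(0),
                      nutrient = character(0), stringsAsFactors = FALSE))
  data.frame(
    feature_id = ifelse(pf$matrix == "plasma",
                        sprintf("PL%03d", pf$feature),
                        sprintf("UR%03d", pf$feature)),
    matrix = pf$matrix, direction = pf$direction,
    fold_change = pf$fold_change,
    nutrient = if ("nutrient" %in% names(pf)) pf$nutrient else NA_character_,
    stringsAsFactors = FALSE)
}

.cross_fluid_ids <- function(spec) {
  cp <- spec$cross_fluid_pairs
  if (is.null(cp) || nrow(cp) == 0)
    return(data.frame(plasma_id = character(0), urine_id = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  data.frame(plasma_id = sprintf("PL%03d", cp$plasma_feature),
             urine_id = sprintf("UR%03d", cp$urine_feature),
             r = cp$r, stringsAsFactors = FALSE)
}

.gen_nutrients <- function(spec, participants, z) {
  cats <- nutrient_categories()[seq_len(spec$n_nutrients), , drop = FALSE]
  n <- nrow(participants)
  lam <- sqrt(abs(spec$nutrient_effect_r))
  a <- ifelse(participants$arm_effective == "W-P", 1, -1)
  base <- matrix(NA_real_, n, nrow(cats))
  intv <- matrix(NA_real_, n, nrow(cats))
  for (j in seq_len(nrow(cats))) {
    cj <- cats[j, ]
    sgn <- if (cj$block == "prudent") 1 else -1
    b <- stats::rnorm(n, cj$base_mean, cj$base_sd)
    mu <- ifelse(participants$arm_effective == "W-P",
                 cj$wp_delta_mean, cj$pw_delta_mean)
    sd <- ifelse(participants$arm_effective == "W-P",
                 cj$wp_delta_sd, cj$pw_delta_sd)
    d <- mu + sd * (lam * sgn * a * z +
                      sqrt(1 - lam^2) * stats::rnorm(n))
    v <- b + d
    if (grepl("pct", cj$category)) {
      b <- pmin(pmax(b, 0), 100); v <- pmin(pmax(v, 0), 100)
    } else {
      b <- pmax(b, 0); v <- pmax(v, 0)
    }
    base[, j] <- b
    intv[, j] <- v
  }
  colnames(base) <- colnames(intv) <- cats$category
  # absolute daily-unit fields for the diet quality score
  energy <- stats::rnorm(n, 1.15, 0.12)  # kcal / 2000
  mk <- function(period, m) {
    out <- data.frame(participant_id = participants$participant_id,
                      period = period, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(m))
    if ("total_fiber" %in% colnames(m))
      out$total_fiber_g_day <- m[, "total_fiber"] * energy
    if ("fruits_veg_servings" %in% colnames(m))
      out$fruits_veg_servings_day <- m[, "fruits_veg_servings"] * energy
    if ("potassium" %in% colnames(m))
      out$potassium_mg_day <- m[, "potassium"] * energy
    out
  }
  rbind(mk("baseline", base), mk("intervention", intv))
}

.gen_matrix <- function(matrix_name, spec, participants, z, nutrients,
                        g_shared) {
  n <- nrow(participants)
  nf <- if (matrix_name == "plasma") spec$n_features_plasma
        else spec$n_features_urine
  prefix <- if (matrix_name == "plasma") "PL" else "UR"
  cv_bio <- if (matrix_name == "plasma") spec$biological_cv_plasma
            else spec$biological_cv_urine
  s_tot2 <- .lncv2(cv_bio)
  s_subj <- sqrt(.ICC * s_tot2)
  s_visit <- sqrt((1 - .ICC) * s_tot2)
  s_tech <- sqrt(.lncv2(spec$technical_cv))

  ids <- sprintf("%s%03d", prefix, seq_len(nf))
  has_creat <- matrix_name == "urine"
  all_ids <- c(ids, if (has_creat) "creatinine", "IS_ClTyr")
  nfa <- length(all_ids)
  platform <- if (matrix_name == "plasma") {
    c(rep("MSI-CE-MS", nf - min(18, nf)), rep("GC-MS", min(18, nf)))
  } else {
    c(rep("MSI-CE-MS", nf - min(8, nf)), rep("CE-UV", min(8, nf)))
  }
  features <- data.frame(
    feature_id = all_ids,
    name = all_ids,
    mz = round(stats::runif(nfa, 60, 500), 3),
    rmt = round(stats::runif(nfa, 0.5, 1.5), 3),
    ion_mode = sample(c("+", "-"), nfa, replace = TRUE),
    platform = c(platform, if (has_creat) "MSI-CE-MS", "MSI-CE-MS"),
    id_level = sample(1:4, nfa, replace = TRUE, prob = c(.4, .3, .2, .1)),
    role = c(rep("analyte", nf), if (has_creat) "creatinine",
             "internal_standard"),
    stringsAsFactors = FALSE)

  abundance <- 10^stats::runif(nfa, 4, 7)
  names(abundance) <- all_ids
  abundance["IS_ClTyr"] <- 1e6
  if (has_creat) abundance["creatinine"] <- 5e6

  # per-feature biological structure: subject level + visit deviation
  subj <- matrix(stats::rnorm(nf * n, 0, s_subj), nf, n)
  vis <- array(stats::rnorm(nf * n * 2, 0, s_visit), c(nf, n, 2))

  # planted effects and nutrient coupling through the visit layer
  pf <- spec$planted_features
  planted_here <- if (!is.null(pf)) pf[pf$matrix == matrix_name, , drop = FALSE]
                  else NULL
  lam_m <- sqrt(abs(spec$nutrient_effect_r))
  eff <- matrix(0, nf, n)  # log effect at week 2
  if (!is.null(planted_here) && nrow(planted_here) > 0) {
    for (k in seq_len(nrow(planted_here))) {
      f <- planted_here$feature[k]
      match_arm <- if (planted_here$direction[k] == "prudent-up") "W-P" else "P-W"
      on <- participants$arm_effective == match_arm
      eff[f, on] <- log(planted_here$fold_change[k])
      # couple the week-2 visit deviation of treated participants to the
      # adherence latent that also drives their nutrient deltas
      if (s_visit > 0 && any(on)) {
        vis[f, on, 2] <- s_visit * (lam_m * z[on] +
                                      sqrt(1 - lam_m^2) *
                                        stats::rnorm(sum(on)))
      }
    }
  }

  # cross-fluid coupled features: shared per-(participant, visit) factor
  cp <- spec$cross_fluid_pairs
  if (!is.null(cp) && nrow(cp) > 0 && !is.null(g_shared)) {
    s_bio <- sqrt(s_tot2)
    att_p <- .atten(.lncv2(spec$biological_cv_plasma), .lncv2(spec$technical_cv))
    att_u <- .atten(.lncv2(spec$biological_cv_urine),
                    .lncv2(spec$technical_cv) + .lncv2(0.2) + .lncv2(spec$technical_cv))
    for (k in seq_len(nrow(cp))) {
      f <- if (matrix_name == "plasma") cp$plasma_feature[k] else cp$urine_feature[k]
      if (matrix_name == "plasma") {
        dev <- s_bio * g_shared
      } else {
        r_gen <- min(0.99, cp$r[k] / max(att_p * att_u, 1e-9))
        dev <- s_bio * (r_gen * g_shared +
                          sqrt(1 - r_gen^2) * matrix(stats::rnorm(n * 2), n, 2))
      }
      subj[f, ] <- 0
      vis[f, , ] <- dev  # n x 2, whole biological deviation is shared
    }
  }

  # assemble study samples: 2 timepoints per participant
  tps <- c("baseline", "week2")
  sample_ids <- as.vector(outer(participants$participant_id, c("T0", "T2"),
                                function(p, t) sprintf("%s_%s_%s", prefix, p, t)))
  n_study <- 2 * n
  resp <- matrix(NA_real_, nfa, n_study)
  dilution <- rep(1, n_study)
  if (has_creat && spec$dilution_cv > 0) {
    s_dil <- sqrt(.lncv2(spec$dilution_cv))
    dilution <- exp(stats::rnorm(n_study, -s_dil^2 / 2, s_dil))
  }
  names(dilution) <- sample_ids
  creat_bio <- if (has_creat) matrix(stats::rnorm(n * 2, 0, sqrt(.lncv2(0.2))),
                                     n, 2) else NULL
  for (t in 1:2) {
    for (i in seq_len(n)) {
      col <- (t - 1) * n + i
      lg <- log(abundance[seq_len(nf)]) + subj[, i] + vis[, i, t] +
        (if (t == 2) eff[, i] else 0)
      vals <- exp(lg)
      if (has_creat)
        vals <- c(vals, abundance["creatinine"] * exp(creat_bio[i, t]))
      vals <- c(vals, abundance["IS_ClTyr"])
      if (has_creat) {
        vals[seq_len(nfa - 1)] <- vals[seq_len(nfa - 1)] * dilution[col]
      }
      # technical noise on every measured response (IS at higher precision)
      tech <- exp(stats::rnorm(nfa, 0, s_tech))
      tech[nfa] <- exp(stats::rnorm(1, 0, sqrt(.lncv2(min(0.03, spec$technical_cv)))))
      resp[, col] <- vals * tech
    }
  }

  samples <- data.frame(
    sample_id = sample_ids,
    participant_id = rep(participants$participant_id, 2),
    arm = rep(participants$arm, 2),
    timepoint = rep(tps, each = n),
    matrix = matrix_name,
    age = rep(participants$age, 2),
    sex = rep(participants$sex, 2),
    bmi = rep(participants$bmi, 2),
    run_id = NA_character_,
    injection_position = NA_integer_,
    is_qc = FALSE,
    stringsAsFactors = FALSE)

  # QC injections: one pooled QC per run of six study samples, runs filled
  # in randomized sample order, QC at a random position within each run
  ord <- sample(n_study)
  n_runs <- ceiling(n_study / 6)
  qc_ids <- sprintf("%s_QC%02d", prefix, seq_len(n_runs))
  qc_resp <- matrix(NA_real_, nfa, n_runs)
  for (r in seq_len(n_runs)) {
    tech <- exp(stats::rnorm(nfa, 0, s_tech))
    tech[nfa] <- exp(stats::rnorm(1, 0, sqrt(.lncv2(min(0.03, spec$technical_cv)))))
    qc_resp[, r] <- abundance * tech
  }
  qc_samples <- data.frame(
    sample_id = qc_ids, participant_id = NA_character_, arm = NA_character_,
    timepoint = NA_character_, matrix = matrix_name, age = NA_real_,
    sex = NA_character_, bmi = NA_real_, run_id = NA_character_,
    injection_position = NA_integer_, is_qc = TRUE,
    stringsAsFactors = FALSE)

  resp_all <- cbind(resp, qc_resp)
  samples_all <- rbind(samples, qc_samples)
  # interleave: assign run ids and global injection positions
  pos <- 0L
  for (r in seq_len(n_runs)) {
    members <- ord[(6 * (r - 1) + 1):min(6 * r, n_study)]
    qc_at <- sample(length(members) + 1, 1)
    run_cols <- append(members, n_study + r, after = qc_at - 1)
    for (cc in run_cols) {
      pos <- pos + 1L
      samples_all$run_id[cc] <- sprintf("R%02d", r)
      samples_all$injection_position[cc] <- pos
    }
  }
  ft <- feature_table(resp_all, features, samples_all)

  # drift (feature-specific rates around the nominal value), then LOD
  drift_info <- NULL
  if (spec$drift_per_injection != 0) {
    dd <- apply_drift(ft, spec$drift_per_injection, feature_jitter = 0.5)
    ft <- dd$table
    drift_info <- dd$drift
  }
  lod <- NULL
  if (spec$lod_quantile > 0) {
    cl <- censor_lod(ft, spec$lod_quantile,
                     exempt = c("IS_ClTyr", if (has_creat) "creatinine"))
    ft <- cl$table
    lod <- cl$lod
  }
  list(table = ft, drift = drift_info, lod = lod,
       dilution = if (has_creat) dilution else NULL)
}

# attenuation of a log-scale correlation by added independent noise
.atten <- function(v_signal, v_noise) {
  if (v_signal <= 0) return(1)
  sqrt(v_signal / (v_signal + v_noise))
}

#' Apply multiplicative signal drift along the injection sequence
#'
#' Each response is multiplied by `(1 + rate)^position` where `position`
#' is the sample's global injection index.  With `feature_jitter = 0`
#' every feature drifts at `drift_per_injection`; a positive jitter draws
#' per-feature rates uniformly from `drift * (1 +/- jitter)`, emulating
#' ionization-dependent drift that no single-channel normalization can
#' fully remove.
#'
#' @param ft a `feature_table` with `injection_position` populated.
#' @param drift_per_injection nominal fractional drift per injection.
#' @param feature_jitter relative spread of per-feature drift rates.
#' @return list with `table` (drifted) and `drift` (list of per-feature
#'   `rates` and the feature-by-sample factor matrix).
#' @export
apply_drift <- function(ft, drift_per_injection, feature_jitter = 0) {
  validate_feature_table(ft)
  pos <- ft$samples$injection_position
  if (any(is.na(pos)))
    stop("injection_position must be set for every sample", call. = FALSE)
  nf <- nrow(ft$responses)
  rates <- if (feature_jitter > 0) {
    drift_per_injection * stats::runif(nf, 1 - feature_jitter,
                                       1 + feature_jitter)
  } else rep(drift_per_injection, nf)
  names(rates) <- ft$features$feature_id
  factors <- outer(rates, pos, function(r, p) (1 + r)^p)
  dimnames(factors) <- dimnames(ft$responses)
  ft <- set_responses(ft, ft$responses * factors)
  list(table = ft, drift = list(rates = rates, factors = factors))
}

#' Censor responses below a per-feature LOD quantile
#'
#' For each feature, responses strictly below the empirical
#' `lod_quantile` quantile (over nonmissing values) are set to missing,
#' emulating below-detection-limit dropout.
#'
#' @param ft a `feature_table`.
#' @param lod_quantile fraction in `[0, 1)`.
#' @param exempt feature ids never censored (e.g. internal standard,
#'   creatinine).
#' @return list with `table` and `lod` (named threshold vector).
#' @export
censor_lod <- function(ft, lod_quantile, exempt = character(0)) {
  stopifnot(lod_quantile >= 0, lod_quantile < 1)
  resp <- ft$responses
  lod <- rep(NA_real_, nrow(resp))
  names(lod) <- ft$features$feature_id
  if (lod_quantile > 0) {
    for (f in seq_len(nrow(resp))) {
      if (ft$features$feature_id[f] %in% exempt) next
      v <- resp[f, ]
      thr <- stats::quantile(v, lod_quantile, na.rm = TRUE, names = FALSE,
                             type = 7)
      lod[f] <- thr
      resp[f, !is.na(v) & v < thr] <- NA_real_
    }
  }
  list(table = set_responses(ft, resp), lod = lod)
}
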