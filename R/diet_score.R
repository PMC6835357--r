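#' Prudent/Western diet quality index
#'
#' One Prudent point for each of: poly:sat ratio > 1.0, saturated fat
#' < 7% energy, total fiber > 28 g/day, fruits + vegetables > 5
#' servings/day, potassium > 3500 mg/day.  One Western point for each
#' of: poly:sat < 0.5, saturated fat > 16%, total fiber < 9 g/day,
#' fruits + vegetables < 5 servings/day, potassium < 3500 mg/day.  All
#' comparisons are strict, so boundary values earn no point; each score
#' ranges 0-5.
#'
#' @param poly_sat_ratio polyunsaturated:saturated fat intake ratio.
#' @param sat_fat_pct saturated fat as % of energy.
#' @param total_fiber_g_day total fiber, g/day.
#' @param fruits_veg_servings_day fruits + vegetables, servings/day.
#' @param potassium_mg_day potassium, mg/day.
#' @return list of class `diet_score`: `prudent_points`, `western_points`,
#'   `classification` (see [classify_predominant()]).
#' @export
score_diet <- function(poly_sat_ratio, sat_fat_pct, total_fiber_g_day,
                       fruits_veg_servings_day, potassium_mg_day) {
  args <- list(poly_sat_ratio = poly_sat_ratio, sat_fat_pct = sat_fat_pct,
               total_fiber_g_day = total_fiber_g_day,
               fruits_veg_servings_day = fruits_veg_servings_day,
               potassium_mg_day = potassium_mg_day)
  missing_f <- names(args)[vapply(args, function(x)
    is.null(x) || length(x) != 1 || is.na(x), logical(1))]
  if (length(missing_f) > 0)
    stop("missing scored field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  prudent <- sum(poly_sat_ratio > 1.0,
                 sat_fat_pct < 7,
                 total_fiber_g_day > 28,
                 fruits_veg_servings_day > 5,
                 potassium_mg_day > 3500)
  western <- sum(poly_sat_ratio < 0.5,
                 sat_fat_pct > 16,
                 total_fiber_g_day < 9,
                 fruits_veg_servings_day < 5,
                 potassium_mg_day < 3500)
  sc <- structure(list(prudent_points = as.integer(prudent),
                       western_points = as.integer(western)),
                  class = "diet_score")
  sc$classification <- classify_predominant(sc)
  sc
}

#' Predominant-diet classification
#'
#' `"predominantly-prudent"` when Prudent minus Western points is at
#' least 2, `"predominantly-western"` when Western minus Prudent is at
#' least 2, otherwise `"mixed"`.
#'
#' @param score a `diet_score` (or list with `prudent_points`,
#'   `western_points`).
#' @return character classification.
#' @export
classify_predominant <- function(score) {
  d <- score$prudent_points - score$western_points
  if (d >= 2) "predominantly-prudent"
  else if (d <= -2) "predominantly-western"
  else "mixed"
}

#' Score all participants in a nutrient record table
#'
#' @param records data.frame as from [read_nutrient_records()].
#' @param period which period to score.
#' @return data.frame of per-participant scores and classifications.
#' @export
score_diet_records <- function(records, period = "baseline") {
  rec <- records[records$period == period, , drop = FALSE]
  out <- lapply(seq_len(nrow(rec)), function(i) {
    s <- score_diet(rec$poly_sat_ratio[i], rec$sat_fat_pct[i],
                    rec$total_fiber_g_day[i],
                    rec$fruits_veg_servings_day[i],
                    rec$potassium_mg_day[i])
    data.frame(participant_id = rec$participant_id[i], period = period,
               prudent_points = s$prudent_points,
               western_points = s$western_points,
               classification = s$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Two-tailed Student's t with equal variances, computed from per-group
#' mean, SD and n.  When both SDs are zero: equal means give `t = 0,
#' p = 1`; unequal means give an infinite t and the smallest
#' representable p.
#'
#' @param mean1,sd1,n1 first group summaries (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summaries.
#' @return list with `t`, `df`, `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean1 - mean2) * Inf, df = df,
                p = .Machine$double.xmin))
  }
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), df)
  if (p == 0) p <- .Machine$double.xmin
  list(t = t, df = df, p = p)
}

#' Per-arm nutrient intake deltas with between-arm comparison
#'
#' For each nutrient category: per-participant delta (intervention minus
#' baseline), then per-arm mean and SD, and a pooled-variance two-sample
#' t-test between arms.  A Bonferroni flag marks categories significant
#' at `alpha / m` where `m` is the family size.
#'
#' @param records nutrient records (both periods per participant).
#' @param arms named character vector mapping participant_id to arm
#'   (`"W-P"`/`"P-W"`).
#' @param categories nutrient columns to summarize; defaults to the
#'   intersection of the known categories with the record's columns.
#' @param alpha significance level before adjustment.
#' @param m Bonferroni family size; defaults to the number of categories
#'   tested.
#' @return data.frame with one row per category: per-arm mean/SD/n, t,
#'   df, p, and `bonferroni_significant`.
#' @export
nutrient_deltas <- function(records, arms,
                            categories = intersect(nutrient_categories()$category,
                                                   names(records)),
                            alpha = 0.05, m = length(categories)) {
  base <- records[records$period == "baseline", , drop = FALSE]
  intv <- records[records$period == "intervention", , drop = FALSE]
  common <- intersect(base$participant_id, intv$participant_id)
  incomplete <- setdiff(unique(records$participant_id), common)
  if (length(incomplete) > 0)
    warning("excluding participant(s) missing a period: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  base <- base[match(common, base$participant_id), , drop = FALSE]
  intv <- intv[match(common, intv$participant_id), , drop = FALSE]
  arm <- arms[common]
  if (length(unique(stats::na.omit(arm))) < 2)
    stop("both arms must be represented", call. = FALSE)
  rows <- lapply(categories, function(cc) {
    d <- intv[[cc]] - base[[cc]]
    d1 <- d[arm == "W-P"]; d2 <- d[arm == "P-W"]
    tt <- summary_ttest(mean(d1), stats::sd(d1), length(d1),
                        mean(d2), stats::sd(d2), length(d2))
    data.frame(category = cc,
               wp_mean = mean(d1), wp_sd = stats::sd(d1), wp_n = length(d1),
               pw_mean = mean(d2), pw_sd = stats::sd(d2), pw_n = length(d2),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_significant <- out$p < alpha / m
  out[order(out$p), ]
}

#' Per-participant nutrient deltas as a matrix
#'
#' Helper for correlation analyses: intervention minus baseline intake
#' per participant and category.
#'
#' @param records nutrient records.
#' @param categories nutrient columns.
#' @return numeric matrix, participants x categories, with participant
#'   ids as rownames.
#' @export
nutrient_delta_matrix <- function(records,
                                  categories = intersect(nutrient_categories()$category,
                                                         names(records))) {
  base <- records[records$period == "baseline", , drop = FALSE]
  intv <- records[records$period == "intervention", , drop = FALSE]
  common <- intersect(base$participant_id, intv$participant_id)
  base <- base[match(common, base$participant_id), , drop = FALSE]
  intv <- intv[match(common, intv$participant_id), , drop = FALSE]
  m <- as.matrix(intv[, categories, drop = FALSE]) -
    as.matrix(base[, categories, drop = FALSE])
  rownames(m) <- common
  m
}
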