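# dietmet

Discovery of robust dietary biomarkers from paired metabolomic feature
tables.

## The problem

Nutritional epidemiology leans on food-frequency questionnaires and diet
records that are prone to bias and selective reporting. Short-term
feeding studies with two contrasting arms — a *Prudent* diet (fruits,
vegetables, whole grains, lean protein) versus a *Western* diet
(saturated/trans fat, sodium, processed foods) — make it possible to
look for metabolites whose circulating (fasting plasma) or excreted
(single-spot urine) responses track what people actually ate. `dietmet`
is an R implementation of the full analysis chain for such paired
two-arm designs, for analysts who have feature-level metabolomics tables
(responses by samples), pooled-QC injections, and per-participant
nutrient records.

The chain:

1. **QC and normalization** — internal-standard normalization,
   creatinine normalization of urine, a ≥ 75% detection filter over
   study samples, a < 30% QC coefficient-of-variation filter,
   half-minimum imputation, empirical-Bayes batch correction anchored on
   the pooled QC in each injection run, then generalized-log
   (`glog(x) = log2((x + √(x² + λ²))/2)`) transformation and
   autoscaling.
2. **Statistics** — volcano analysis of paired week-2/baseline ratios
   (fold change ≥ 1.3, Benjamini–Hochberg q), paired OPLS-DA with
   stratified 7-fold Q² and label-permutation testing (n = 1000), a
   moderated Hotelling T² timecourse statistic
   `T² = (n₁n₂/(n₁+n₂)) dᵀ S̃⁻¹ d` with
   `S̃ = (n_p S + ν S₀)/(n_p + ν)`, a mixed diet×time ANOVA computed
   through its exact difference-score equivalence (adjusted for age,
   sex, BMI), partial Pearson correlations of metabolite responses to 20
   nutrient-intake categories, and Mann–Whitney ROC analysis of single
   and ratiometric markers.
3. **Calling** — a metabolite is a *robust dietary biomarker* when it
   passes at least 2 of the 3 models **and** correlates (|r| > 0.30,
   p < 0.05) with at least 2 nutrient categories. Prudent/Western diet
   quality scores (5 points each, strict thresholds) classify
   participants' habitual diets.
4. **Synthetic studies** — a generator with known ground truth (planted
   fold changes 1.5–5, technical CV ~10%, biological CV 45%/70%, signal
   drift, below-LOD censoring, urinary dilution, non-adherent
   participants, nutrient coupling) makes every stage testable without
   cohort data.

## Worked example

```r
library(dietmet)

study <- generate_study(simulation_spec(seed = 7))
study$plasma
#> feature_table: 81 features x 98 samples (14 QC)
#>   matrix: plasma
#>   missing: 400 of 7938 cells

cfg <- pipeline_config()
pp <- preprocess_matrix(study$plasma, cfg, matrix_name = "plasma")

vol   <- volcano(pp$ratios)
meba  <- meba_t2(pp$glog)
anova <- mixed_anova_interaction(pp$glog)
head(meba[order(meba$rank), ], 3)
#>   feature_id        t2            p rank
#> 1      PL001 118.43161 2.204215e-12    1
#> 2      PL002  97.92062 3.291548e-11    2
#> 3      PL003  87.52804 1.516557e-10    3
```

The three top-ranked features by T² are planted diet-responders (the
generator's ground truth lists `PL001`–`PL006`). Adding the
covariate-adjusted nutrient correlations and applying the decision rule:

```r
nd <- nutrient_delta_matrix(study$nutrients)
sm <- pp$glog$samples
wk <- which(!qc_mask(pp$glog) & sm$timepoint == "week2")
x <- pp$glog$responses[, wk]; colnames(x) <- sm$participant_id[wk]
covs <- sm[wk, c("age", "sex", "bmi")]
covs$sex <- as.numeric(factor(covs$sex)) - 1
rownames(covs) <- colnames(x)
pc <- partial_correlation_table(x, nd, covs)

calls <- call_robust(meba, anova, vol, pc, cfg)
subset(calls, robust,
       select = c(feature_id, n_models_passed, n_nutrient_hits))
#>   feature_id n_models_passed n_nutrient_hits
#> 1      PL001               3              20
#> 2      PL002               3              20
#> 3      PL003               3              20
#> 4      PL004               3              20
#> 5      PL005               3              20
#> 6      PL006               3               9
```

All six planted plasma biomarkers are called, each passing all three
models and correlating with many nutrient categories (intakes are
strongly co-linear within the Prudent and Western blocks, so genuine
responders correlate broadly). A summary-statistics t-test reproduces a
printed intake contrast — insoluble fiber, 14.0 ± 5.3 g/2000 kcal
(n = 24) versus −5.0 ± 3.5 (n = 18):

```r
tt <- summary_ttest(14.0, 5.3, 24, -5.0, 3.5, 18)
sprintf("t = %.2f on %d df, p = %.2g", tt$t, tt$df, tt$p)
#> [1] "t = 13.19 on 40 df, p = 3.8e-16"
```

A one-command version of the whole chain, with every intermediate
written as CSV plus a JSON manifest:

```r
run_pipeline(pipeline_config(rng_seed = 1), "out/", synthetic = TRUE)
```

or from a shell, `Rscript inst/cli/dietmet.R run --synthetic --out out/`.

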