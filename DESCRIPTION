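Package: dietmet
Title: Dietary Biomarker Discovery from Paired Metabolomic Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of short-term dietary intervention
    metabolomics with a paired two-arm design: quality-control filtering
    (detection fraction and QC coefficient of variation), internal-standard
    and creatinine normalization, half-minimum imputation, empirical-Bayes
    batch correction anchored on pooled QC injections, generalized-log
    transformation and autoscaling, complementary statistics (volcano with
    Benjamini-Hochberg FDR, paired OPLS-DA with cross-validation and
    permutation testing, a moderated Hotelling T-squared timecourse
    statistic, mixed diet-by-time ANOVA with covariates, covariate-adjusted
    partial Pearson correlation to nutrient intake, ROC analysis), a
    Prudent/Western diet quality index, and a robust-biomarker decision
    rule.  Ships a synthetic-study generator with known ground truth so the
    whole pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
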