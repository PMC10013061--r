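Package: parenclitic
Title: Parenclitic Network Analysis of Clinical Cohorts for Survival
    Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-patient physiological network mapping from routine
    clinical and laboratory variables. Pairwise regression models are
    fitted in a reference class (12-month survivors) after
    Bonferroni-corrected Spearman screening; each patient's orthogonal
    residual deviation from every reference line becomes the weight of a
    network edge, and weighted topology indices (degree centrality,
    characteristic path length, diameter, global efficiency) summarise the
    individual network. A survival layer evaluates prognostic value via
    Mann-Whitney comparisons, Cox proportional-hazards models, ROC curves
    with Youden cutoffs, Kaplan-Meier/log-rank tests, and a combined
    MELD-deviation index. A synthetic cohort generator with the same
    statistical structure supports validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
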