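# parenclitic

Per-patient physiological network analysis for survival prognosis in
cirrhosis, from seven routine clinical/laboratory variables: serum albumin
(ALB), total bilirubin (Bil), prothrombin time (PT), serum creatinine (Cr),
ammonia (NH4), serum sodium (Na) and hepatic encephalopathy grade (HE).

Cirrhosis is a multi-organ disease: single-organ severity scores such as
MELD or Child-Pugh summarise *levels* of individual markers but ignore the
*relationships between* markers, which carry their own prognostic signal
(e.g. albumin that stays high while bilirubin climbs, or encephalopathy out
of proportion to ammonia). A parenclitic network makes those relationships
measurable for one patient at a time:

1. **Reference model.** In the reference class (12-month survivors,
   transplant counted as death), all p(p−1)/2 = 21 variable pairs are
   screened by Spearman correlation with pairwise deletion; pairs
   significant at the Bonferroni-corrected level α/m = 0.05/21 ≈ 0.0024
   get an ordinary least-squares reference line *y = a + bx*.
2. **Parenclitic deviation.** For each patient and each reference pair,
   the deviation ∂ is the orthogonal residual of the patient's point from
   the reference line. With vertical residual *v = |y₀ − (a + bx₀)|* and
   horizontal residual *h = v/|b|*, ∂ = v·h/√(v² + h²), computed here via
   the equivalent perpendicular-distance form ∂ = v/√(1 + b²).
3. **Network topology.** Each patient's ∂-weighted undirected network
   (nodes = screened variables, edge weights = ∂, larger deviation =
   longer distance = weaker connectivity) is summarised by weighted degree
   centrality (mean and SD over nodes), characteristic path length,
   diameter and global efficiency.
4. **Survival layer.** Mann-Whitney contrasts of every ∂ and topology
   index between survivors and non-survivors; univariate and
   severity-adjusted Cox models (Efron ties); ROC curves with
   Youden-optimal cutoffs; Kaplan-Meier/log-rank tests of the
   dichotomised scores; and the combined index
   MELD−∂ = β₁·MELD + β₂·∂ with β from the bivariate Cox model.

Because suitable patient-level data are rarely shareable, the package
includes a synthetic cohort generator (`generate_cohort()`) that plants the
structure the analysis assumes — correlated variable pairs in survivors,
inflated deviations on disrupted axes in non-survivors, hazard rising with
deviation magnitude, severity scores tied to the underlying biology — so
the whole pipeline is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the study end to end on the
default synthetic cohort and write every table under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_reference_network.R
Rscript analysis/03_parenclitic_deviations.R
Rscript analysis/04_network_topology.R
Rscript analysis/05_survival_analysis.R
```

Step 02 prints the survivor reference map — the screening keeps the
strongly correlated axes and drops everything involving sodium and
creatinine:

```
  reference class: 367 survivors
  screening: 21 pairs at threshold 0.00238 (alpha 0.05 / m 21)
  significant pairs: 7
    pair     rho    p_value n_complete    slope intercept
 ALB_Bil -0.9202 4.448e-145        353 -2.50279  119.8492
  ALB_PT -0.7848  1.508e-75        356 -0.42368   28.8748
  ...
```

Step 03 compares deviations between outcome groups (median (IQR), two-sided
Mann-Whitney): non-survivors sit far from the survivor reference lines,

```
  ALB_Bil   1.80 (0.87- 3.20) vs  4.82 (2.64- 8.72)  p = 5.19e-21
  ALB_PT    1.68 (0.73- 2.64) vs  4.01 (2.08- 6.09)  p = 1.31e-18
  NH4_HE    0.43 (0.23- 0.72) vs  0.68 (0.31- 1.04)  p = 0.000195
```

and step 05 shows the prognostic pay-off: each unit of Alb-Bil deviation
multiplies the 12-month hazard by 1.23 (95% CI 1.20–1.26), deviations stay
predictive with MELD in the model, and adding the deviation to MELD lifts
the AUC,

```
  ALB_Bil          AUC 0.780 (0.729-0.831)  cutoff 3.679
  MELD             AUC 0.655 (0.598-0.711)  cutoff 16.000
  MELD_d_ALB_Bil   AUC 0.810 (0.762-0.859)  cutoff 2.277
```

with log-rank chi-square 122.9 (p < 0.001) for the cutoff-dichotomised
Alb-Bil deviation. A patient's network can also be inspected directly:

```r
library(parenclitic)
cohort <- generate_cohort(synthetic_config(), seed = 1)
refset <- build_reference_set(cohort, analysis_config())
profile <- compute_profile(cohort[1, ], refset)
compute_topology(build_network(profile, refset))
```

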