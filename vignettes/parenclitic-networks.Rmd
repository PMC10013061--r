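---
title: "Parenclitic networks for survival prognosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parenclitic networks for survival prognosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the model, the
assumptions behind it, the synthetic cohort that stands in for patient
data, and the numerical conventions adopted wherever the method leaves a
choice open. It states no empirical result beyond what the package's tests
and `scripts/acceptance.R` themselves compute.

## The model

Conventional severity scores compress a patient's laboratory panel into a
weighted sum of *levels*. A parenclitic network instead asks how far a
patient departs from the *relationships between* variables that hold in a
reference population. The analysis has four stages.

**Reference screening.** In the reference class — patients alive and not
transplanted at the 365-day horizon — every pair of the seven clinical
variables (ALB g/L, Bil µmol/L, PT s, Cr µmol/L, NH4 µmol/L, Na mmol/L, HE
ordinal grade 0/1/2) is tested by Spearman correlation. Each pair uses the
rows where both members are observed (pairwise deletion), midranks for
ties, and the large-sample t approximation for the two-sided p-value. With
p = 7 variables there are m = 21 pairs, and the family-wise level α = 0.05
gives the Bonferroni-corrected threshold α/m ≈ 0.0024. The denominator is
always the full pair count: pairs with fewer than `min_pair_n` (default
10) complete observations are flagged "insufficient data" and excluded
from testing but still counted in m, so the corrected level does not drift
with missingness. Screening is invariant to monotone transforms of either
variable; the fitted lines below are not, which is one reason variables
stay on their raw clinical scales throughout.

**Reference lines and deviations.** Each significant pair gets an ordinary
least-squares line y = a + bx fitted on the reference class. The
orientation is fixed by convention — the earlier variable in the ordered
set (ALB, Bil, PT, Cr, NH4, Na, HE) is the predictor — because orthogonal
distance to a least-squares line depends on which variable is regressed on
which, and the source method does not state its orientation. A patient's
deviation on a pair is the orthogonal residual: with vertical leg
v = |y₀ − (a + bx₀)| and horizontal leg h = v/|b|, the altitude of the
right triangle is ∂ = v·h/√(v² + h²). The implementation uses the
algebraically identical perpendicular distance ∂ = v/√(1 + b²), which
avoids the indeterminate 0/0 for points on the line and the h = v/|b|
singularity for horizontal lines (where ∂ → v); tests verify both forms
agree to 10⁻⁹ over random lines and points. Deviations are unsigned (they
serve as edge weights) and in raw response units, so they are comparable
across patients within an axis but not across axes; no cross-axis
normalisation is applied, matching the method's original formulation.
Whether to normalise before topology is a genuinely open choice — raw ∂
was kept for fidelity, and the consequence is that axes with large
response scales (e.g. Bil) dominate weighted-degree sums.

**Per-patient networks and topology.** Nodes are the variables appearing
in at least one screened pair (variables that never screen in are excluded
from networks entirely); each screened pair with both members observed
contributes an undirected edge weighted by ∂; missing members leave the
edge absent and the nodes possibly isolated. Deviations are read as
*distances*: more deviation means weaker physiological connectivity.
Indices, using standard weighted-graph definitions:

* *degree centrality* — weighted degree (strength), the sum of incident
  ∂; summarised by its mean and its sample (n−1) standard deviation over
  nodes. The method's "in-degree" is implemented as undirected strength,
  since a regression-derived network has no natural edge direction.
* *characteristic path length* — mean shortest-path distance over
  connected node pairs (Dijkstra on non-negative weights).
* *diameter* — largest finite shortest-path distance.
* *global efficiency* — mean of 1/distance over all node pairs, with
  unreachable pairs contributing zero.

Degenerate cases are defined, not failed: an edgeless network returns zero
for every index; unreachable pairs are excluded from path length and
diameter. A zero-weight edge (a patient exactly on a line) would make an
inverse distance infinite; with continuous data this has probability zero
and the convention is left untouched rather than capped.

**Survival layer.** Every ∂ and topology index is compared between
survivors and non-survivors by the two-sided Mann-Whitney U test
(continuity-corrected normal approximation with midrank tie correction,
the convention of mainstream clinical software; verified against the
exact permutation null at small n) with median (IQR) per group. Cox
proportional-hazards models use the Efron tie approximation —
clinical-scale day resolution produces many ties, and Efron is both more
accurate than Breslow and the default of mainstream survival software —
with Wald standard errors, exp(β ± 1.96 SE) confidence intervals, and
complete-case handling. ROC analysis computes the AUC as the normalised
Mann-Whitney statistic from midranks (identical to the trapezoidal area),
a Hanley-McNeil 95% CI, and the cutoff maximising Youden's
J = sensitivity + specificity − 1 over observed score values ("optimum
sensitivity and specificity" is not otherwise formalised); ties in J break
toward the lower cutoff, favouring sensitivity, and scores are oriented
"higher = worse" with an orientation check that flips and flags any score
whose raw AUC falls below 0.5. Patients at or above the cutoff form the
"predicted non-survivor" group for Kaplan-Meier curves and the 1-df
Mantel-Cox log-rank test. For axes whose deviation remains significant
(p < 0.05, HR > 1) alongside MELD in a bivariate Cox model, the combined
index β₁·MELD + β₂·∂ is scored through the same ROC/KM machinery. The
survival layer deliberately applies no multiple-testing correction beyond
the network-screening Bonferroni, reproducing the source analysis; its
p-values should be read accordingly. Events beyond the horizon are
administratively censored at 365 days before any analysis.

## The synthetic cohort generator

No patient-level data ship with the package, so `generate_cohort()` draws
cohorts with the statistical structure the analysis assumes. All defaults
were fixed from design considerations before the acceptance checks were
run.

Two latent groups are drawn. The *reference-structure* group (default
n = 400) follows four generative axes on raw clinical scales:

* ALB ~ Uniform(20, 45) g/L;
* Bil = 120 − 2.5·ALB + ε, ε ~ N(0, 8) µmol/L;
* PT = 30 − 0.45·ALB + ε, ε ~ N(0, 2.5) s;
* latent HE severity HE\* = 2.4 − 0.055·ALB + u, u ~ N(0, 0.35), observed
  as grades 0/1/2 by thresholding HE\* at 0.5 and 1.1 — the analysis
  treats the 3-level grade linearly, and a discretised latent keeps that
  approximately valid;
* NH4 = 40 + 90·u + ε, ε ~ N(0, 6) µmol/L.

Ammonia deliberately couples to u, the albumin-*independent* component of
HE severity, not to HE\* itself: hyperammonaemia-encephalopathy is its own
physiological axis, and coupling through full HE\* would drag ammonia into
correlation with the entire albumin hub. With this structure the survivor
correlation map contains the six axes the analysis expects (ALB-Bil,
ALB-PT, ALB-HE directly; Bil-PT, PT-HE induced through the albumin hub;
NH4-HE through u) — plus, unavoidably, the transitive Bil-HE edge: with
injected correlations this strong at n ≈ 400, any second-order correlation
above ~0.16 clears the Bonferroni cut, so a six-edge map with no seventh
edge is not attainable from a faithful generative model. Creatinine and
sodium are independent noise and never join the network.

The *disrupted* group (default n = 100) is identical except that the noise
SD on the disrupted axes (default all four generative axes) is multiplied
by `deviation_inflation` (default 3). On the HE axis the inflation is
added as an independent extra component so that the part shared with
ammonia is preserved — this is what actually breaks the NH4-HE relation:
inflating ammonia's own noise mostly slides points along the fitted line,
whereas extra HE noise moves them perpendicular to it. The disrupted group
also has albumin shifted down by `severity_shift` (default 4 g/L); level
shifts move patients *along* the reference lines, not away from them, so
deviations are untouched while conventional severity worsens.

Event times are exponential with log-hazard
log(h₀) + Σ cₐ·|true deviationₐ| + s·(severity − 10), censored at 365
days. The per-axis coefficients cₐ default to 0.8 per noise-SD of
deviation, the baseline h₀ to 10⁻⁵/day, and the severity slope s to 0.2
per unit of the noiseless MELD signal (1.2·log Bil + 0.8·(PT − 10) +
0.15·(45 − ALB)); MELD is that signal plus N(0, 1.5) rounded and clamped
to 6–40, Child-Pugh an analogous monotone function including the HE grade.
These choices give roughly 5% twelve-month event probability in the
reference-structure group, high event probability in the disrupted group,
and an overall event fraction near a quarter — the scale of a tertiary
cirrhosis cohort. Setting `severity_coeff = 0` and `severity_shift = 0`
recovers a pure deviation-only hazard, in which conventional severity
carries no prognostic signal at all; the defaults keep a severity path so
that "independent of MELD" is a meaningful claim to test. Missingness is
completely at random per cell (default 2%), matching an analysis whose
only missing-data correction is pairwise deletion.

What the generator does *not* emulate: real marginal shapes (skewed
bilirubin, heavy-tailed ammonia), correlated missingness, competing risks,
ACLF-like subgroups, non-linear pair relationships, or calendar-time
effects. Passing tests therefore demonstrate that the machinery recovers
planted structure of realistic strength under the model's own assumptions
— not that those assumptions hold in any particular clinical population.

## Test design and problem sizes

Every operation with a closed-form or enumerable answer is checked against
an independent oracle written naively in the test suite: rank-Pearson
Spearman, closed-form three-point OLS, the residual-leg product form of ∂,
Floyd-Warshall all-pairs topology, exhaustive-pair AUC, exact-permutation
Mann-Whitney, a grid/golden-section maximiser of the Efron partial
likelihood, and hand-tabulated log-rank risk sets. Monte-Carlo properties
use the default cohort size (500) over 100 generator seeds for screening
power and parameter recovery, 200 seeds of null cohorts (n = 50, all
slopes zero) for the family-wise false-positive rate, and smaller cohorts
(n = 120–200) for pipeline plumbing; these sizes keep the full suite to a
few minutes while leaving binomial margins far wider than the observed
variation.

## Known limitations

* Deviations are unsigned and unnormalised: topology indices mix units,
  and axes with large response scales dominate degree sums.
* The linear reference model is assumed, not checked; strongly curved
  relationships would inflate deviations for extreme-but-healthy values.
* The 3-level HE grade enters regressions as a number; the discretised
  latent in the generator mirrors this approximation rather than fixing
  it.
* The ROC cutoff optimises in-sample Youden's J and is not
  cross-validated; reported sensitivities/specificities are optimistic.
* With a single reference class from one cohort, fitted lines inherit
  that cohort's case mix; deviations of external patients are only
  interpretable against comparable populations.
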