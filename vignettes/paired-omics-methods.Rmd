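---
title: "Methods: paired multi-omics differential analysis with effect-direction classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired multi-omics differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(directomics)
```

## The analytical problem

Proliferative diabetic retinopathy (PDR) patients receiving a preoperative
anti-VEGF injection differ at baseline (simple vitreous hemorrhage, simpleVH,
versus hemorrhage with tractional retinal detachment, VH_TRD) and change over
the week between injection and vitrectomy. A study design that profiles the
aqueous humor proteome and metabolome of every patient both at baseline and
post-treatment supports two orthogonal comparison axes:

* **cross-sectional** — VH_TRD versus simpleVH at baseline (unpaired): which
  molecules mark the severe phenotype;
* **longitudinal** — post-treatment versus baseline across all patients
  (paired by patient): which molecules the treatment moves.

Molecules significant on *both* axes are the interesting ones, and their two
direction estimates admit a simple dichotomy. Anchoring the "pathological
direction" to the cross-sectional deviation of the severe phenotype:

* **improvement-type** — the treatment-induced change opposes the
  severe-phenotype deviation (discordant signs): treatment normalizes the
  molecule;
* **aggravation-type** — the change continues in the same direction
  (concordant signs): treatment pushes the molecule further along the
  pathological axis, the signature hypothesized to mark post-injection
  fibrovascular "crunch".

`classify_direction()` implements exactly this rule; it is total on
$\{\text{up},\text{down}\}^2$ and symmetric under a simultaneous sign flip of
both axes. Features with an exactly zero change on either axis are rejected
rather than silently assigned; with continuous data this is a
measure-zero event, and a caller that produces one has a degenerate input to
inspect.

## Preprocessing

Each omics layer is processed independently, on the raw intensity scale
until the final transformation:

1. **Presence filtering** (`filter_presence()`): a feature is kept when its
   observed fraction strictly exceeds 50% in at least one design cell. We
   read "over 50%" literally as a strict inequality, so 2-of-4 is removed.
   The filtering cells are the group × timepoint combinations by default:
   the natural units of this design, so a feature robustly measured in any
   one clinical state survives (a clinical-group reading is available via
   `by = "group"`).
2. **KNN imputation** (`knn_impute()`): neighbours are *features* (rows),
   the mass-spectrometry convention, with distance the root-mean-square
   difference over co-observed samples (normalising by the co-observation
   count keeps features with different missingness patterns comparable).
   Each missing cell takes the inverse-distance-weighted mean of the
   `k = 10` nearest features observed in that sample; a feature with no
   eligible donor falls back to its own observed mean, and the event is
   logged. Imputation runs before the log transform, on the raw scale.
3. **Normalization** (`normalize_layer()`): protein tables are
   log2-transformed and median-normalized — every column is shifted so its
   median equals the grand median of column medians, a scale-stable target;
   metabolite tables are log2-transformed and quantile-normalized (via
   `limma::normalizeQuantiles`, ties receiving the average of their
   quantile values). Both transforms are rank-preserving within columns.

## Per-feature differential statistics

Because aqueous-humor abundances at $n \le 25$ are frequently non-Normal,
each feature passes an **assumption gate** (`assess_assumptions()`) before
testing, at gate level $\alpha = 0.05$: Shapiro–Wilk normality on each arm
(on the paired differences for the longitudinal axis) and classic Levene
(centre = mean) variance homogeneity for the unpaired case. The decision
table is: both arms Normal and homoscedastic → Student *t*; Normal but
heteroscedastic → Welch; otherwise Wilcoxon rank-sum (paired: Normal
differences → paired *t*, else signed-rank, exact for ≤ 25 non-zero
tie-free differences). Arms too short to assess route to the rank tests.
Degenerate inputs follow fixed conventions: two zero-variance arms return
$p = 1$ with a warning.

Fold changes are ratios of **linear-scale** group means (data are
back-transformed from log2 before averaging), group-of-interest over
reference (VH_TRD / simpleVH; post / baseline). The protein threshold
"FC > 1.5" is applied two-sidedly as $\max(\mathrm{FC}, 1/\mathrm{FC}) >
1.5$, since down-regulated molecules are called significant too.

**PLS-DA VIP** for metabolites: a PLS1 discriminant model is fitted by
NIPALS on autoscaled features with the centred class indicator as response,
one model per axis on all features jointly, with 2 latent components by
default (the conventional choice when VIP is the goal; the first component
carries nearly all the explained class variance in these designs). With
unit-norm weight vectors $w_a$ and per-component explained response sum of
squares $\mathrm{SSY}_a$,

$$\mathrm{VIP}_j = \sqrt{\,p \cdot \frac{\sum_a \mathrm{SSY}_a\, w_{ja}^2}
{\sum_a \mathrm{SSY}_a}\,},$$

which satisfies $\sum_j \mathrm{VIP}_j^2 = p$ exactly — the identity is
asserted to $10^{-8}$ in the test suite against an independently coded
NIPALS reference.

**Dual-threshold significance** (`call_significant()`): proteins need
$p < 0.05$ and two-sided FC > 1.5; metabolites need $p < 0.05$ and
VIP > 1. Mirroring the upstream design, no multiplicity correction is
applied by default; Benjamini–Hochberg is available behind
`adjust = "BH"`.

## Intersection, classification, enrichment

`intersect_significant()` joins the two axes' significant sets over a
common feature universe; `summarize_classification()` reports counts and
percentages (one decimal); `waterfall_table()` orders records by class
(aggravation block first) and then by decreasing $|\log_2 \mathrm{FC}|$ of
the longitudinal axis, ties broken deterministically by feature id.
`ora_hypergeometric()` computes the upper-tail hypergeometric
over-representation p-value per pathway after intersecting memberships
with the background universe — all features surviving the presence filter
for the relevant layer(s), which is the set that had a chance to be called.
Combining layers is equivalent to running the union hit set against the
union background, a property the tests assert.

## Validation-phase statistics and quantification

The validation cohort (10 controls, 5 simpleVH, 5 VH_TRD) is small and
makes no normality claims, so its statistics are nonparametric throughout:
Kruskal–Wallis across the three groups (tie-corrected, chi-square
approximation), pairwise Wilcoxon rank-sum tests gated on a significant
overall test (exact small-sample distributions where tie-free; raw p-values
by default, Holm behind a flag), and paired Wilcoxon signed-rank for the
within-patient axis (zero differences dropped, exact to 25 pairs).

Targeted absolute quantification fits a calibration line of response ratio
(analyte / isotope-labelled internal standard) on nominal concentration in
nmol/L, weighted $1/x$ by default — the bioanalytical convention that
equalizes relative accuracy across a range spanning orders of magnitude;
`quantify_absolute()` inverts the line and flags extrapolation beyond the
calibrated range instead of censoring. QC series are gated at CV < 20%
(sample SD over mean; scale-invariant). Wound closure is
$(A_{0h} - A_t)/A_{0h} \times 100\%$ and gel contraction is reported as
relative gel area $A_t/A_{0h} \times 100\%$; areas are taken as given, no
image processing is attempted.

## Effect sizes, power, ANCOVA

Cohen's *d* uses the pooled-SD standardization; its 95% CI inverts the
noncentral-*t* distribution of the two-sample statistic (exact under
normality) rather than the normal-approximation standard error — coverage
at $d = 0.5$, $n = 15$ per arm is verified by simulation in the suite.
Post hoc power and prospective sample size use the noncentral-*t* power
function with $\mathrm{ncp} = d\sqrt{n_1 n_2/(n_1+n_2)}$; the sample-size
routine returns the smallest integer *n* whose power reaches the target,
verified against exhaustive search. The ANCOVA sensitivity analysis fits
`log2 abundance ~ group + age + sex + diabetes_duration + hba1c` on
baseline samples and reports the partial-F p-value for the group term; sex
enters as a treatment-contrast indicator, covariates with missing values
trigger listwise deletion with a warning, and constant or aliased
covariates are dropped with a warning rather than silently absorbed.

## The synthetic cohort generator

No raw matrices accompany the study design this package targets, so every
stage is exercised on synthetic cohorts with known ground truth
(`sim_config()`, `generate_discovery_cohort()`,
`generate_validation_cohort()`). The generator emulates:

* the paired design — 13 simpleVH + 12 VH_TRD patients, baseline and
  day-7 post-treatment samples; a validation design of 10 controls plus
  5 + 5 paired PDR patients;
* layer sizes of 1432 proteins and 1542 metabolites;
* log-normal abundances: per-feature baseline log2 means uniform on
  (14, 24) — a typical MS dynamic range — technical noise whose log2 SD is
  chosen so the linear-scale CV equals `tech_cv` (default 0.2, a plausible
  overall biological + technical spread; the published QC figures report
  instrument precision only, not biological variance, so this is a free
  parameter chosen once), and a per-patient-per-feature random intercept
  (SD 0.3). The patient effect is deliberately per-feature: a global
  per-sample shift would be removed by normalization, whereas per-feature
  between-subject variance is exactly what makes the paired design gain
  power, which the generator should reproduce;
* planted effects of ±1 log2 unit: per layer, cross-only features
  (66 / 81 for protein / metabolite), long-only (49 / 187), improvement
  (3 / 32, opposite-signed cross and longitudinal effects) and aggravation
  (2 / 1, same-signed) — planted counts mirror the discovery and
  intersection tallies of the motivating design;
* missingness as the union of an intensity-dependent (MNAR) logistic
  mechanism — masking probability
  $\mathrm{logit}^{-1}((m - v)\,s)$ at log2 abundance $v$, midpoint
  $m = 12$, slope $s = 0.8$ — and MCAR dropout at rate 0.05, together
  yielding ~8% missing cells.

One seed governs all draws; the order (design covariates, then per layer:
planting, baseline means, patient effects, noise, missingness) is fixed,
so identical configurations are byte-identical.

What the generator does **not** emulate: correlated feature blocks
(pathway co-regulation), batch or injection-order effects, heavy-tailed or
skewed biological outliers, peptide-to-protein rollup and shared-peptide
ambiguity, and interference in targeted channels. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under the
stated model, not that real aqueous-humor data satisfy that model.

## Problem sizes and numerical choices

The suite runs the type-I calibration on 20 effect-free cohorts of 1000
features and the end-to-end recovery on 20 full-size cohorts; the
acceptance script repeats the recovery on 10 cohorts and the calibration
on 5 — sizes chosen so Monte-Carlo error on the reported rates is a few
per mille while a complete run stays comfortably interactive. NIPALS
stops early when the residual weight norm or score variance falls below
$10^{-12}$ (rank exhaustion); constant features are dropped with a warning
before autoscaling. Quantile-normalization ties take average quantile
values; waterfall and ORA orderings break ties by id so outputs are
permutation-invariant.

## Known limitations

* **VIP > 1 is largely redundant with p < 0.05 at these sample sizes.** At
  $n = 25$ samples, a metabolite reaching $p < 0.05$ by chance has
  $|r| \gtrsim 0.4$ with the class label, which already exceeds the
  root-mean-square loading when a few hundred features carry real signal —
  so nearly every chance p-significant feature also clears VIP > 1. The
  practical consequence, visible in the synthetic recovery runs, is that
  roughly 5% of features with a real effect on only *one* axis leak into
  the two-axis intersection, where about half land in each direction
  class. Aggravation-type calls are rare by construction, so this leakage
  dominates their false-discovery proportion (the acceptance script
  reports it as `aggravation_fdr`). With raw-p dual thresholds this is a
  property of the method being modelled, not an implementation artifact;
  `adjust = "BH"` suppresses it at the cost of sensitivity.
* Zero-variance and flat-direction degenerate cases follow documented
  conventions (p = 1 with warning; explicit error) rather than attempting
  inference.
* The ANCOVA is a fixed-effects sensitivity analysis on baseline samples
  only; no mixed models or rank-based power analyses are provided.
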