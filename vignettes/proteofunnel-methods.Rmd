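---
title: "Methods: from LFQ intensities to a CSF biomarker candidate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from LFQ intensities to a CSF biomarker candidate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

proteofunnel re-implements, as a reusable and tested pipeline, a complete
label-free-quantification (LFQ) brain-proteomics analysis for an
amyloid-pathology mouse study: two tissues (cortex, hippocampus), three
ages (2, 5, 8 months), transgenic (TG) versus wild-type (WT) animals, five
biological replicates per cell and two technical replicates per sample
(three for the 5-month hippocampus). This vignette explains the models,
their assumptions, the tunable parameters, and the choices made where the
underlying design was genuinely open.

## Missingness and the reliability filter

LFQ non-detections are reported as zero intensity and are missing not at
random (MNAR): the probability of a dropout grows as abundance falls.
Imputing such values biases fold-changes, so the pipeline never imputes.
Instead it filters: a protein is *reliable* in a condition (tissue x age x
genotype) when strictly fewer than half of the condition's samples are
missing; technical replicates count as samples, so the comparison
`n_missing < n_samples / 2` is exact and odd sample counts (the 15-sample
5-month hippocampus) behave deterministically (7 missing is reliable, 8 is
not).

The phrase "unreliable in each individual condition" admits two readings.
The default (`reading = "all-conditions"` in `filter_tissue()`) excludes a
protein from a tissue only when it is unreliable in *every* condition
there; the alternative (exclusion when unreliable in *any* condition) is
also implemented. The default was chosen because the stricter reading
would make the subsequent genotype-pair step redundant: `pairwise_analysis_set()`
additionally requires reliability in both genotypes of the specific
(tissue, age) being compared, which only adds information under the
lenient tissue-level rule.

The full (two-tissue, all-age) model needs proteins reliable in every
condition, and cortex and hippocampus are quantified as separate datasets
whose protein groups need not match. `full_model_set()` links protein
groups across tissues through shared accessions and drops every
many-to-many component of that bipartite graph (one-to-many components are
dropped by default, retainable by flag). This identifier-overlap
reconciliation is an approximation: the original peptide-level evidence
behind group assignment is not available to this package.

## Batch adjustment

Log10 LFQ intensities are adjusted per tissue with a parametric
empirical-Bayes location/scale model: per-protein standardization by a
covariate fit, per-batch location and scale estimates shrunk towards
batch-level priors (normal for locations, inverse-gamma for scales, both
moment-matched), then removal of the shrunk effects on the standardized
scale. This is the classic parametric formulation; it is implemented here
natively so that missing entries stay missing and are excluded from every
estimate (reference implementations require complete matrices). On
complete data it agrees with the reference to within iteration tolerance
(cross-checked in the test suite). Condition effects are protected by
default through condition covariates; a batch perfectly confounded with a
covariate level (rank-deficient joint design) is refused. Batches with
fewer than two observed values for a protein fall back to the prior means
and are logged in the model's `fallback` table.

The generator's default batch structure is one batch per (tissue,
acquisition half) — the real study does not describe its batch covariate,
so it is a free parameter of both the generator and `adjust_batch()`.

## Moderated differential abundance

Technical replicates of one animal share its biology. The pipeline
estimates a single consensus within-animal correlation: per protein, a
pooled one-way (animal within condition) variance decomposition gives an
intraclass correlation; the per-protein estimates are Fisher
z-transformed, robust-averaged with a 10%-trimmed mean, and transformed
back. The fits then use generalized least squares with block
compound-symmetry covariance at that consensus rho (rho = 0 reduces
exactly to ordinary least squares). A cheaper alternative —
`collapse_tech_reps()`, averaging replicates per animal — is provided as a
documented deviation.

Residual variances are moderated: with per-protein variance s²_g on d_g
degrees of freedom, the prior (d0, s0²) is estimated by moment matching on
log s²_g (mean and trigamma inversion, Newton solve to 1e-8), and the
posterior variance is the convex combination
(d0 s0² + d_g s²_g) / (d0 + d_g). The moderated t has d0 + d_g degrees of
freedom; `prior_df = 0` and `prior_df = Inf` expose the no-shrinkage and
full-pooling limits. Benjamini-Hochberg adjustment (via `p.adjust`) is
applied *within each contrast independently*, and a protein is significant
at FDR < 0.05.

Two model families are fitted. The *pairwise* model compares TG vs WT
within one (tissue, age) on the proteins reliable in both genotypes there
(`DE.hippo.Age8` and friends). The *full* model fits all twelve condition
means jointly on the cross-tissue reliable set and adds interaction
contrasts: transgene-effect differences between ages (`A82TC` = age 8 vs 2
in cortex) and between tissues (`A5THC` = hippocampus vs cortex at 5
months); difference contrasts have zero-sum coefficients. Effects are
estimated on log10 (`log_scale = "log2"` converts by log2(10)). A protein
missing a whole condition touched by a contrast gets no row for that
contrast, so downstream counts equal set cardinalities. The pipeline also
reports the Pearson correlation between full-model and pairwise t
statistics per condition as a model-consistency diagnostic.

## Aggregate-trajectory classification

Four aggregate readouts are tracked per tissue across the three ages:
membrane-filter-assay signal, plaque load (% of region volume in plaques
of at least 50 µm³, `plaque_load()`), and plaque counts by 6E10 and
Thioflavin-S staining. Each differentially expressed protein's 3-point
trajectory of pairwise log10 fold-changes is Pearson-correlated with each
readout trajectory of its tissue; it is classified *corr* (resp. *acorr*)
when any readout gives r > 0 (r < 0) with two-tailed t-test p < 0.05.
With three points the test has one degree of freedom, so the critical
correlation is `critical_r(3, 0.05)` = t₀.₉₇₅,₁ / sqrt(t² + 1) ≈ 0.9969 —
an extremely strict gate. Perfect correlations (r = ±1, p = 0) are
classified; excluding them (a literal open-interval reading) would be
statistically indefensible. When one readout says corr and another acorr,
the smaller p wins (tie: |r| closer to 1) and the conflict is flagged.
The canonical mode correlates the three per-age mean fold-changes, not
per-animal values.

## Cross-species concordance and signatures

Mouse and human results meet only through an ortholog map; symbols are
never case-folded across species. Both translation directions are
combined into one bipartite graph; only one-to-one connected components
resolve, many-to-many components are always dropped, one-to-many
components are dropped by default. A protein is *concordant* when it is
significant with the same effect sign in at least one mouse dataset (the
hippocampus 5- and 8-month and cortex 8-month families) and at least one
human dataset; a stricter all-datasets rule is available. Signatures take
the 15 most up- and 15 most downregulated concordant proteins ranked by
the maximum |mouse log fold-change| over significant mouse datasets, with
lexicographic tie-breaks so results never depend on row order. Human
effect sizes stay on their native scales; only signs and ranks cross the
species boundary.

## The candidate funnel

`run_funnel()` applies six conjunctive, fully audited stages to the
hippocampus data: (S1) reliably present proteins; (S2) significant DEPs at
any age; (S3) resolved ortholog significant in at least one human dataset;
(S4) concordant direction; (S5) aggregate-(anti)correlated *and* in the
per-age top-25 effect ranking at all three ages; (S6) annotation filter
(default terms: lysosome, endo-lysosomal). "Effect size" for the top-25
ranking is read as the moderated-statistic magnitude, with |logfc| ranking
behind a flag, since no formula is attached to the phrase in the source
analysis; ties break by the other criterion, then lexicographically. The
human-overlap universe at S3 is hippocampus-restricted (the global union
variant remains available through the inputs). Every stage's surviving
set is recorded, counts are non-increasing by construction, and the report
serializes to JSON losslessly.

## CSF biomarker evaluation

The ROC curve sweeps all observed thresholds; ties contribute one half
(midrank convention), so the trapezoidal AUC equals the Mann-Whitney U
statistic divided by n₁n₂ exactly, and the AUC is invariant under strictly
monotone transforms. No covariates enter the ROC. Group comparison is a
classic equal-variance two-tailed t-test (Welch behind a flag, since the
variance assumption is not stated in the source analysis). Associations
with established biomarkers (Aβ42, Aβ40, Aβ42/40, t-tau, p-tau) use
Spearman correlation with the t-approximation p, unadjusted by default to
match the usual single-table presentation.

## The synthetic-data generator

`simulate_lfq()` draws intensity = per-protein baseline (log10 scale,
mean 7, sd 0.8) + planted genotype effect + per-batch additive shift and
multiplicative noise scale + animal noise (sd 0.08) + technical noise
(sd 0.05), then masks values with probability
`plogis(missing_slope * (missing_midpoint - y))` (midpoint 5.5, slope 2
per log10 unit — roughly 10% missing overall, concentrated at low
abundance). Planted effects carry age-trajectory structure: generic DEPs
grow in magnitude with age; aggregate-tracking proteins are affine in one
readout trajectory (true trajectory correlation exactly ±1); one
candidate protein is hippocampus-specific, monotone increasing, strongly
ranked at every age, human-concordant and lysosome-annotated. Every
random draw flows from a single seed through named substreams, so any one
table regenerates in isolation and runs are byte-identical.

What the generator does *not* emulate: peptide-level quantification,
retention-time structure, correlated protein modules, heavy-tailed
contaminant intensities, or shared-peptide ambiguity beyond the
identifier-overlap model. Passing tests therefore demonstrate the
correctness of the statistical machinery under the stated generative
model, not performance on raw instrument output.

Default problem sizes were chosen as desk-scale stand-ins for the real
study (1500 proteins versus roughly 5000 quantified per tissue; the
`smoke` preset uses 200 for fast end-to-end runs) — the statistical
structure, not the raw dimension, is what the pipeline's behavior depends
on. The `funnel-demo` preset lowers biological and technical noise
(sd 0.02) and is the engineered construction on which the funnel provably
converges to the planted candidate; under the realistic default noise the
candidate's *estimated* 3-point trajectory clears the 0.9969 critical
correlation only part of the time, which is a faithful reproduction of how
fragile a 3-point correlation gate is, not a defect of the implementation.

## Numerical choices and limitations

* Trigamma inversion for the moderation prior: Newton iteration,
  relative tolerance 1e-8.
* Batch EB iteration: fixed point, absolute tolerance 1e-8, cap 100.
* The consensus correlation is clamped to (-0.45, 0.9999) before GLS so
  block covariance matrices stay positive definite for blocks up to three
  replicates.
* Degenerate inputs error loudly: zero-variance vectors in correlations,
  empty groups in ROC, missing seeds in every generator.
* `run_pipeline()` re-runs are deterministic per (config, seed); the
  manifest records a hash over all stage outputs so two runs compare by
  hash equality. There is no stage-level caching: a run is cheap enough
  that incremental recomputation would buy complexity, not time.
* The hypergeometric marker-enrichment p-values are discrete and
  therefore super-uniform under the null (conservative, never
  anti-conservative).
* The WT expression analysis splits at the median after omitting a
  configurable central band (default: the middle third), resolving the
  internal tension of a "median split" that yields three groups; odds
  ratios use the Haldane 0.5 correction when a cell is empty.

```{r example}
library(proteofunnel)
run <- run_pipeline(pipeline_config(seed = 1, preset = "5xfad"))
run$funnel
autoplot(run$roc)
```
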