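---
title: "Finding hypoxia-inducible prognostic genes in neuroblastoma: models and design"
author: "nbhypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding hypoxia-inducible prognostic genes in neuroblastoma: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neuroblastoma spans a remarkable clinical range, from spontaneous regression
to rapidly fatal disease, and tumor hypoxia is one of the forces pushing
toward the aggressive end. `nbhypoxia` implements an integrative workflow for
finding genes that are both induced by hypoxia in neuroblastoma cell lines
and associated with poor overall survival in patients: per-dataset
differential expression with clinical covariate adjustment, a dual
significance/magnitude gene filter, intersection of the resulting signatures
across independent datasets with a permutation null for the overlap,
sliding-window survival cutpoint scanning with Cox modelling, and qRT-PCR
fold-change quantification for bench validation. A synthetic-data module
generates every input with known ground truth, so the whole chain is testable
without any external download.

## Differential expression

**Patient cohorts.** For each gene the package fits the ordinary linear
model

    y ~ status + MYCN

where `y` is normalized log2 expression, `status` contrasts deceased against
surviving patients, and MYCN amplification enters as a fixed effect because
it is the dominant molecular prognostic factor in this disease and is
correlated with outcome; omitting it would attribute MYCN-program expression
to survival. The reported effect is the status coefficient — a log2 fold
change, deceased minus survivors — with its classical two-sided t-test
p-value. Fitting is vectorized across genes with `limma::lmFit`, but the
statistics are plain OLS, not empirical-Bayes moderated: with hundreds of
samples per cohort, variance moderation is unnecessary and would change the
estimator the workflow is defined by. Features with zero residual variance
get `log2fc = 0`, `p = 1` and a `degenerate` flag so downstream filters are
deterministic; a design in which status and MYCN are perfectly confounded
drops the MYCN column with a warning rather than failing 20,000 times.

**Cell-line panels.** Hypoxia experiments pair each line's normoxic and
hypoxic cultures, so between-line variation must be absorbed before the
oxygen contrast is tested. The package fits the Gaussian linear mixed model

    y ~ condition + MYCN + growth_pattern + (1 | line)

per gene (`lme4`, with Satterthwaite degrees of freedom from `lmerTest`).
The response is normalized log intensity, so a Gaussian identity-link model
is the appropriate reading of a "generalized" mixed model here. Line-level
covariates that do not vary in a given panel are dropped from the fixed
effects. With a single line the model degenerates and the package falls back
to fixed-effects OLS with a warning; non-converged fits likewise fall back,
and both paths are flagged per feature.

**Probe collapse.** Where a probe-to-gene map exists, the probe with the
smallest p-value represents the gene; ties break by larger absolute fold
change, then lexicographically smallest probe ID, so results are invariant
to row order.

**q-values.** False discovery rates are Storey q-values computed in the
package: the null proportion pi0 is estimated on the lambda grid 0.05 to
0.95 with a cubic smoothing spline read off at the largest lambda and
clamped to (0, 1]; below 100 p-values, or when the smoother misbehaves, pi0
falls back to 1, where q-values coincide exactly with Benjamini-Hochberg
adjusted p-values (the identity the test suite exploits against
`p.adjust`).

**The DEG filter.** A gene is called differentially expressed when `q <
0.01` *and* its signed log2 fold change lies in the top or bottom 10% of
the fold-change distribution. Two points were genuinely open and are fixed
as defaults with config switches: the decile is computed over the full
tested universe (`fc_decile_scope = "universe"`; the alternative restricts
it to the FDR-significant subset), and the deciles are of *signed* fold
change — top and bottom tails separately — rather than of magnitude. Zero
fold changes are recorded as "up" with a warning; they occur only in
degenerate fixtures.

## Integration

Signatures intersect by gene symbol; a shared gene is direction-consistent
only when its direction agrees in **every** member dataset. Candidate genes
are exactly the direction-consistent members of the all-datasets
intersection.

The overlap's permutation null draws, per replicate, a uniform random gene
set of the observed signature size from **each dataset's own tested
universe** (the platforms differ, so the universes differ; an option
intersects universes first for sensitivity analysis), counts the k-way
intersection, and repeats 100,000 times. The primary p-value is the plain
counting rule — the number of replicates with an overlap at least as large
as observed, divided by the number of replicates. That estimator can return
an exact 0, which understates the evidence (100,000 replicates cannot
distinguish p below 1e-5), so the bias-guarded estimate (count + 1)/(n + 1)
is always reported alongside. For two datasets on a common universe the null
is exactly hypergeometric; `exact_overlap_pvalue()` provides that closed
form and anchors the permutation sampler in the tests, as does exhaustive
subset enumeration for three sets on tiny universes.

Over-representation analysis against a GMT collection uses the same
hypergeometric kernel per gene set with q-values across the collection
(significance at q < 0.05). Peak-to-gene annotation flags a gene when a peak
overlaps the half-open window [TSS − w, TSS + w) around its strand-adjusted
TSS; w defaults to 2,000 bp because "regulatory region" has no canonical
width, and the boundary semantics follow the BED convention (a peak exactly
abutting the window end does not overlap). Interval work is done with
`GenomicRanges`.

## Survival analysis

**Cutpoint scan.** Patients are dichotomized at every admissible expression
threshold: cutpoints are midpoints between consecutive distinct order
statistics, stepping one patient at a time, such that both arms keep at
least 2% of patients (`ceiling(min_fraction * n)` per side). Samples equal
to the cutpoint fall in the low group (high means strictly greater). Each
window gets a two-group log-rank test — implemented directly as the
observed-minus-expected sum with the conditional hypergeometric variance,
ties handled by the standard correction, because the scan needs thousands of
cheap evaluations; the kernel agrees with `survival::survdiff` to machine
precision. Zero-event windows return p = 1 with a warning rather than NaN.

The per-gene minimum p over windows is strongly anti-conservative (the test
suite demonstrates it rejecting far above nominal under the null), which is
exactly why multiplicity is corrected over **all (gene, window) pairs
jointly**: every window p-value across every gene enters one q-value
computation, and the per-gene minimum q is reported with its cutpoint. The
pooled computation uses pi0 = 1 by default: minimum-p selection distorts the
pooled p-value histogram, so a smoother-based pi0 estimate on that pool
would be anti-conservative.

A practical identifiability note: the best cutpoint is only estimable to the
extent the expression distribution separates the risk groups and events are
plentiful. The localization test therefore runs at roughly 50% events with a
clearly bimodal expressor profile; under heavy censoring with overlapping
expression mixtures the minimum-p location is diffuse even though the test's
size is controlled.

**Cox models.** Each gene's expression enters a proportional-hazards model
univariately and, in the adjusted model, together with MYCN status, INSS
stage, and age at diagnosis. Stage is an unordered categorical with stage 1
as the reference: 4S is a biologically distinct metastatic-infant category,
not a level above 4 (an ordinal encoding is available by configuration).
Ties use the Efron approximation; convergence tolerance 1e-9 with at most
100 iterations. Non-identifiable designs (for example, a gene collinear with
MYCN) and non-converged fits are flagged and excluded from the per-model
q-value computation, never silently dropped. q-values are computed per model
(univariate and multivariate) across genes.

**DEG-prognosis permutation.** To ask whether the candidates' prognostic
behavior could arise by chance, the package draws a fixed number of genes
from each cohort's DEG list (without replacement), counts how many drawn
genes are prognostic — scan minimum q below 1% — in *both* cohorts, repeats
100,000 times, and reports one upper-tail p per cohort's draw with the same
counting rule and bias-guarded companion as the overlap test. When nearly
every DEG is prognostic in both cohorts (as in strongly planted synthetic
studies) the statistic saturates and the p-value is 1 by construction; the
test is informative precisely when DEG status and prognosis are partially
decoupled.

## qRT-PCR quantification

Relative expression follows the pure 2^-ddCt rule with no amplification-
efficiency correction: per condition, delta-Ct is the mean over replicates
of Ct_gene − Ct_reference, pairing each gene well with the reference well of
the same replicate index (same plate run; when pairing is impossible the
condition-mean reference is used with a warning); delta-delta-Ct is treated
minus control; the fold change is 2^(−ddCt) exactly. Significance is a Welch
t-test on the per-replicate delta-Ct values — the plate's replicate-level
observable — with "significantly up" meaning p < 0.05 and a positive log2
fold. Identical replicate vectors return p = 1 rather than an error.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known truth. The
patient-cohort generator works through a latent high-risk state `z`: the
top `1 − threshold_quantile` fraction of patients (default 40%) is
high-risk; prognostic genes are shifted by `effect_size` log2 units in those
patients; the death hazard is `baseline_hazard * exp(log_hazard_ratio * z)`
with exponential event times; censoring times are uniform on (0, c_max)
with c_max calibrated numerically so the realized censoring fraction matches
`censor_rate`. Thresholding a planted gene's expression at
`threshold_quantile` therefore separates the hazard groups, which is what
the cutpoint scan is meant to find. MYCN amplification is assigned with
higher probability among high-risk patients (marginal fraction preserved),
and a disjoint gene set responds to MYCN only — the confound the survivor
model's MYCN term exists to absorb. INSS stage and age are drawn with
risk-dependent distributions so the multivariate Cox covariates carry
signal.

One consequence is worth stating plainly: the deceased-versus-survivor
expression gap equals `effect_size` times `P(z | deceased) − P(z |
survivor)`, which is below 1 whenever outcome and risk state are imperfectly
linked. Under the defaults the realized gap is roughly 0.4 of the planted
shift. Tests that assert recovery of the configured shift as a group-mean
difference therefore use strong-separation configurations (large hazard
ratio, low baseline hazard, moderate censoring) in which the event indicator
nearly coincides with `z`.

Defaults were calibrated once, at design time, to emulate a strongly
powered study of the kind the workflow targets: cohorts of several hundred
patients with ~19% deaths and ~15% MYCN amplification, planted prognostic
shifts of 2.5 log2 units on the latent risk state (realized gap ~1 log2
unit), a risk-group hazard ratio of 5, 81% censoring; cell-line panels of
11 lines with between-line intercept sd 0.5 and a 2 log2-unit (4-fold)
hypoxia induction, the magnitude typical of glycolytic HIF targets at 1%
oxygen. The qPCR generator writes Ct values in which hypoxia lowers a
target's Ct by its true log2 fold (reference gene untouched), so zero-noise
plates invert exactly.

All randomness descends from one master seed through
`derive_seed(master, stage)` — a deterministic string hash kept below
2^31 — so stages are independently reproducible and no two stages share a
stream.

What the generator does **not** emulate: probe-level chemistry, RMA or any
normalization artifacts, batch effects, and — importantly — correlation
between genes (each gene's noise is independent). Passing tests therefore
demonstrate that the estimators and the orchestration are correct under a
clean generative model, not that the thresholds would behave identically on
real arrays, where correlated genes inflate the variance of overlap counts
and FDR estimates.

## Desk-scale study design

The bundled analysis scripts and the acceptance checks run a complete
synthetic study at desk scale: 2,000 genes with 25 planted
hypoxia-and-prognosis genes, two cohorts of 600 patients, one single-line
experiment with six replicate pairs, one 11-line panel, 100,000 permutation
replicates. Cohort size was chosen so the planted effects are comfortably
detectable at the study's q < 0.01 plus top-decile filter given the
calibrated effect sizes (per-gene t around 7); the four-way intersection
compounds per-dataset misses, so an underpowered design would test power,
not correctness. The global-null replicates use 500-gene panels.

## Known limitations

- The q-value pi0 smoother is the simple spline-at-max-lambda variant;
  bootstrap pi0 selection is not implemented.
- The mixed model is refit per gene (no shared-design acceleration), which
  dominates runtime on large cell-line panels.
- The cutpoint scan reports the minimum-q window only; no inference is
  offered for the cutpoint location itself.
- Overall survival is the only endpoint; no competing risks or event-free
  survival.
- The permutation tests treat genes as exchangeable within universes;
  correlated expression would require a resampling scheme the source data
  formats do not support.
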