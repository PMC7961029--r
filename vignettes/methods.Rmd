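---
title: "Methods and design notes for multi-region case-control RNA-seq analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurobulk)
```

This vignette documents the statistical models behind `neurobulk`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the methodology left room.

## Study design and data model

The package targets matched case-control post-mortem designs: a handful of
affected subjects (default 7) each matched to an unaffected comparison
subject (default 8), every subject sampled in several brain regions
(default BA11, BA47, caudate, NAcc — two orbitofrontal cortical areas and
two striatal structures). Expression tables are tibbles whose first column
is `gene` and whose remaining columns are samples; metadata carries one row
per sample with `subject`, `region`, `diagnosis` (`case`/`comparison`) and
the donor covariates sex, age (years), post-mortem interval (hours), tissue
pH and RNA integrity number.

## Quality control

Two gene-level filters are applied in sequence:

1. **Expression filter.** A gene is kept if it reaches `min_cpm` (default
   1 CPM) in at least `ceiling(min_sample_frac * n_r)` samples of at least
   one region (default half, rounded up for odd region sizes — "at least
   half" read conservatively). The per-region disjunction keeps genes
   expressed only in, say, striatum.
2. **CV filter.** Over all samples, `CV_j = sd_j / mean_j`; genes with
   `CV_j < T` are kept, `T = mean(CV) + cv_sd_multiplier * sd(CV)` (default
   multiplier 3). Genes with zero mean are excluded beforehand and logged.
   Two deliberate edge rules: when `sd(CV) = 0` (all CVs equal, including a
   single gene) everything is retained — an outlier filter has nothing to
   cut in a degenerate spread; and the cutoff is estimated *once* on the
   gene set the filter sees. Re-estimating `T` on already-filtered output
   would keep shrinking the threshold (trimming the tail shrinks `sd(CV)`),
   so exact idempotence is provided by re-applying the stored `threshold`
   argument rather than by re-estimation.

## Consensus correlation and region merging

The consensus correlation between two regions is defined as: center each
gene on its mean across all samples, compute for every subject sampled in
both regions the Pearson correlation across genes between its two samples,
and take the median over subjects (the mean is also reported). Centering is
essential: raw expression profiles of any two brain samples correlate above
0.95 simply because gene baselines are shared, which would make the statistic
useless for deciding which regions are near-replicates. On centered data the
statistic isolates subject-and-region-specific deviations, and cortical pairs
separate cleanly from cortico-striatal pairs. The median (not mean) is used
because with 7–8 subjects a single outlying donor should not drive the merge
decision. One caveat of centering: with very few total samples *m* it induces
a mechanical correlation of about −1/(m−1) between independent samples; at
the package's design sizes (m ≥ 40) this bias is below 0.03.

Merging is config-driven: when the consensus of the designated cortical pair
reaches `merge_threshold` (default 0.5) the two regions are collapsed into
one pseudo-region (default label "OFC") by per-subject arithmetic averaging;
a subject with only one of the merged regions passes its single sample
through. The threshold is a parameter, not a hard-coded region identity, so
the same logic applies to any near-replicate pair.

## Differential expression

Per gene, ordinary least squares of `log2(CPM + prior)` (prior 1) on
diagnosis plus region (global analysis only) plus covariates. Rationale for
Gaussian OLS on log CPM: with 15 subjects the model must be simple and
closed-form testable; the diagnosis t-test from OLS has an exact oracle
(the pooled two-sample t in the covariate-free case), which anchors the test
suite. A caveat documented rather than hidden: effects planted on the log2
abundance scale are slightly attenuated on the `log2(CPM + 1)` scale for
weakly expressed genes (at 4 CPM a true twofold change reads as ~0.85);
the recovery tests therefore measure systematic bias as the mean signed
error along the planted direction.

Diagnosis is coded comparison = 0, case = 1, so positive log2FC means higher
expression in cases. Fixed covariates are diagnosis, region, sex and pH;
age, PMI and RIN are *candidates*, admitted by `select_model()` when they
associate with any of the top 5 expression principal components at p < 0.01.
This mirrors the practice of including only covariates that demonstrably
drive expression. At n = 15 subjects the rule occasionally admits a noise
covariate (3 candidates × 5 PCs at the 1% level); that is the price of
data-driven selection at small n and is visible in the pipeline report.

BH correction is applied within each analysis scope (global, and each
region separately), matching the convention of reporting separate DEG
counts per scope. Regional models drop the region term and are fitted on
the region's samples only. The global model contains no diagnosis-by-region
interaction; the global/regional split plays that role.

**Independence and merging.** The generator gives the two cortical regions
a shared subject-level latent signal. Two unmerged cortical samples of one
subject are therefore correlated, which violates the OLS independence
assumption and inflates the diagnosis type-I error if the model is fitted on
all four raw regions. The pipeline's stage order — merge first, then fit —
resolves this: after averaging, the latent appears once per subject and is
absorbed into residual noise. The test suite fits after merging for exactly
this reason.

## Enrichment and directionality

Gene sets are tested for over-representation of the DEG list by the
one-sided Fisher exact test (upper hypergeometric tail), after intersecting
each set with the background (the tested gene universe). Sets overlapping
the DEG list in fewer than `min_overlap = 3` genes are skipped to avoid
degenerate 2×2 tables; BH correction runs across the tested sets of one
collection (separate collections are corrected separately).

For each enriched set the fraction of its overlapping DEGs that are
downregulated (`frac_down`) summarizes direction. Three tests operate on
these fractions across set clusters:

* focal cluster vs all remaining sets: pooled two-sample t with
  `df = n1 + n2 − 2`;
* one-way ANOVA across clusters (F = 0 is returned for exactly constant
  input, where the 0/0 statistic is conventionally undefined);
* per cluster, a one-sample t of `frac_down` against 0.5, two-sided, with
  Bonferroni correction by the number of tested clusters. A down-biased
  cluster yields a positive t by construction. The exact form of the
  per-cluster direction test is an interpretive choice (the convention
  reproduces the sign behaviour one expects: down-bias → positive
  statistic); it is stated here as an assumption. Singleton clusters are
  excluded from per-cluster tests with a warning.

## Co-occurrence network and clustering

Set-set similarity is the Jaccard index |A∩B| / |A∪B| over the DEG-restricted
sets — "fraction of genes present in both pathways given the unique genes in
either" read with a union denominator. Clustering is average-linkage
agglomeration on distance 1 − J with a fixed-k cut (default k = 4), replacing
by-eye dendrogram cutting with a reproducible parameter. Sets are sorted
lexicographically before clustering so the partition is invariant to input
order. Network edges connect every pair with J > 0; an edge is "strong" when
J ≥ 0.5, i.e. at least half of the union co-occurs.

## Cell-type deconvolution

The linear mixing model: bulk expression of gene g is
`sum_k f_k * S[g, k]` for cell-type fractions `f` and a linear-scale
signature `S` (log-scale references would break additivity). Markers are
chosen per type by the ratio of the type's mean expression to the maximum
of the other types' means (top `n_markers` with ratio > 1). Fractions are
estimated per sample by nonnegative least squares followed by sum-to-one
renormalization — a transparent solver whose behaviour is validated by
recovery simulations (exact on noiseless full-rank mixtures; mean absolute
error below 0.05 at 5% noise) rather than by identity with any published
deconvolution package. Estimates are scale-invariant in the bulk sample.

Region panels encode anatomy: cortical samples are solved without medium
spiny neurons, striatal samples without excitatory projection neurons; the
across-region average for a subject uses only regions where a type exists.
Group comparisons are OLS of the fraction on diagnosis plus covariates (sex
and pH by default, mirroring the DE model; the covariate set is
configurable) on the raw fraction scale, with raw p-values reported (as is
conventional for cell-composition panels) alongside BH q-values.

## Cross-study concordance

Internal and partner DE tables are inner-joined on gene id; the Pearson
correlation of log2FCs gets its two-sided p from
`t = r·sqrt(n−2)/sqrt(1−r²)` on n − 2 df. The internal p-values of matched
genes are fitted with the beta-uniform mixture
`f(p) = λ + (1−λ)·a·p^(a−1)`, `0 < a, λ < 1`, by bounded L-BFGS-B from a
fixed lattice of six starts (deterministic by design — the fit should not
consume random-number state), parameters constrained to `(1e-4, 1−1e-4)`.
`π̂ = λ + (1−λ)a` (the density at p = 1) bounds the null proportion;
`1 − π̂` is the signal fraction. p-values of exactly 0 are clamped to
machine epsilon with a warning (the power-law density diverges at 0);
p = 1 is retained.

The p-cutoff for a target FDR inverts the mixture FDR in closed form:
`τ = ((π̂ − fdr·λ)/(fdr·(1−λ)))^(1/(a−1))`, with τ = 1 when
`π̂ ≤ fdr·λ` (the requested FDR is met everywhere). A limiting-case note:
as both λ and a approach 1 (a near-uniform fit) the closed form drives τ to
0, not 1 — under a fit that says "almost everything is null", no cutoff
except a vanishing one achieves a 20% FDR, so nothing is selected. This is
the statistically correct behaviour and is what the package implements and
tests.

Congruence below τ requires strict sign equality of the two studies'
log2FCs; a zero log2FC counts as non-congruent (a documented convention —
zero carries no direction).

## The synthetic-data generator

`simulate_study()` draws negative-binomial counts
(`size = 1/dispersion`, default dispersion 0.1) around log-normal gene
baselines (log2 mean 3, sd 2), with per-sample library sizes uniform on
1–2 million reads. It emulates:

* the matched cohort (7 vs 8 subjects, covariates drawn around published
  cohort summaries: age ≈ N(47.5, 14) years, PMI ≈ N(16.5, 6.5) h,
  pH ≈ N(6.65, 0.15), RIN ≈ N(7.7, 0.55), sexes balanced);
* planted diagnosis effects of ±`de_log2fc` (default 1 log2 unit), 100
  global genes plus region-specific genes concentrated in striatum
  (defaults: 20 caudate, 50 NAcc);
* genuine covariate drivers: per-gene sex and pH coefficients
  (sd 0.2 / 0.3 log2 units per standardized unit), so covariate selection
  has true positives to find;
* a shared cortical latent: for each subject a gene-level signal common to
  BA11 and BA47. Its variance is set analytically so that the *observed*
  consensus correlation on log2 CPM lands at the configured target
  (default 0.71): if σ_r² is the per-sample biological variance and m̂ the
  delta-method variance contributed by negative-binomial counting noise on
  the log2(CPM+1) scale, the shared variance is
  `σ_sh² = ρ/(1−ρ) · (σ_r² + m̂)`, whence the centered correlation
  `σ_sh²/(σ_sh² + σ_r² + m̂) = ρ`. Without this correction the counting
  noise would dilute the target by 20–30%.

Gene-set, mixture, reference and partner-study generators plant,
respectively: enriched sets loaded with true DE genes under a configurable
downregulation bias; bulk mixtures from known fractions with
truncated-Gaussian noise; cell-type references with block markers; and a
partner DEG table sharing a configurable fraction of true DE genes with
configurable sign agreement, all reported at p < 0.01 as external DEG
tables typically are.

Cell-composition shifts default to medium spiny neurons −0.04,
astrocytes +0.04, vascular cells +0.035 in cases, on a Dirichlet base with
concentration 30 (between-subject SD ≈ 2 percentage points per type).
These values are calibrated so that the emulated study reproduces the
significance pattern reported for the corresponding published comparisons
at 7 vs 8 subjects (expected |t| ≈ 3.2–3.6); they are design constants of
the generator, not fitting targets.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artifacts (mapping bias, duplication,
3' bias), transcript-level quantification uncertainty, batch and RIN-driven
degradation structure beyond a linear covariate, correlated gene modules
beyond the single cortical latent, heavy-tailed outlier samples, and sample
swaps (the package reports between-region correlations in its QC output but
does not attempt automated swap repair). Results on synthetic data certify
the *machinery* — estimator identities, error control, recovery under the
stated model — not robustness to every failure mode of post-mortem tissue.

## Determinism and problem sizes

Every generator takes an explicit seed and uses `withr::with_seed`, so no
global RNG state leaks; the pipeline derives stable per-stage sub-seeds from
its master seed, and identical config + seed yields an identical report.
The test suite runs its simulations at deliberately chosen sizes — 2000
genes for distributional checks (uniformity of null p-values, consensus
calibration), 300–600 genes for replicated recovery and FDR experiments
(10–20 replicates), 30 samples for deconvolution recovery, 5000 p-values
for mixture-model recovery — sizes at which the asserted statistical
properties are stable, as the fixed tolerance bands in the tests document.
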