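---
title: "Methods: integrative expression and methylation analysis of trisomy 21 tissue"
author: "trisomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative expression and methylation analysis of trisomy 21 tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisomics)
```

# Scope and model

`trisomics` implements a complete analysis chain for paired bulk RNA-seq and
array-based DNA methylation data from small two-group studies of trisomy 21
(Down syndrome, DS) tissue versus euploid controls:

1. sample quality control (marker-gene tissue identity, projection-pursuit
   robust PCA outlier detection);
2. negative-binomial Wald differential expression with a sex covariate and
   chromosome-level dosage-enrichment statistics;
3. differential methylation at single-CpG (DMP) and region (DMR) level,
   the latter by bump hunting with a sample-permutation null;
4. cis pairing of DMRs with differentially expressed genes and an
   integrative methylation-expression (eQTM) analysis based on Pearson
   correlation with bootstrap confidence intervals and permutation
   p-values;
5. preranked gene-set enrichment (GSEA) with normalized enrichment scores,
   parent-set collapsing and Jaccard clustering.

Because cohorts of this kind are small (a handful of samples per group) and
the underlying data are typically access-restricted, the package ships a
synthetic-data generator (`simulateStudy()`) that emulates the statistical
structure such a study presents, with a truth ledger against which every
stage is tested.

# The synthetic study generator

`simulationConfig()` encodes the study conditions. The defaults describe a
fetal-tissue cohort of 6 DS and 6 control samples in which two DS samples
are contaminated with skeletal-muscle-like tissue and one control sample is
a gross expression outlier — so that after quality control 4 DS and 5
control samples remain, the cohort geometry typical of such studies.

**Expression.** Counts are negative binomial, $y_{gi} \sim
\mathrm{NB}(\mu_{gi}, \alpha)$ with $\mathrm{Var} = \mu + \alpha\mu^2$ and
$\alpha = 0.02$ by default (a good-quality homogeneous bulk tissue).
Baseline expression is log-normal; per-sample library scales are uniform on
a two-fold range. Every chromosome-21 gene carries the trisomic dosage
effect: its expected count is multiplied by `dosage_factor` (default 1.5,
the three-copy expectation) in DS samples. Whether a chr21 gene then
reaches significance is a property of the analysis, not of the generator —
as in a real trisomy, where only a fraction of chromosome-21 genes test
significant at a given cohort size. In addition, 140 non-chr21 genes (7% of
the 2000-gene toy genome, a typical genome-wide DE rate for this contrast)
receive planted log2 fold changes of random sign with magnitudes in
[0.5, 2].

**Methylation.** Beta values follow a logit-normal model: noise with
standard deviation `beta_noise_sd` (default 0.3) is added on the logit
scale and back-transformed, which respects the [0, 1] range and makes
group-mean invariants exactly testable. Planted DMRs are clusters of five
consecutive CpGs whose DS group mean is shifted by ±0.15 in beta. Sex
effects enter both data types; a technical batch effect (balanced across
condition) enters the *measured* beta values only, which is precisely the
structure the residual-PCA surrogate variable is meant to absorb.

**Cis coupling.** For four planted DMRs placed in gene promoters, the
per-sample *biological* median methylation of the region (i.e. excluding
the technical batch term) is coupled to the host gene's log2 expected
expression with slope ±6 log2 units per beta unit, two couplings of each
sign. Across the planted 0.15 beta shift this is a ~0.9 log2-unit
expression difference — a strong promoter effect, chosen so that the cis
genes are reliably recoverable as DEGs at the default cohort size, which
the analysis design requires (a cis pair can only be tested if its gene
survives the DE filter). Coupling to the biological rather than the
measured methylation reflects that array batch artifacts do not regulate
transcription; it also keeps the coupling from inflating the gene's
apparent biological dispersion.

**Contaminants and outliers.** Contaminant samples swap thyroid
(TPO, TG, TSHR, SLC5A5) for muscle (MYH1, MYOD1) marker expression and
receive a broad tissue-mixture perturbation; the outlier sample receives
independent per-gene log2 noise with standard deviation 1.5 (a degraded
library). Their methylation profiles are left intact, mirroring how such
samples present in practice: contamination is an expression-side
phenomenon.

What the generator does *not* emulate: count-level GC or length biases,
probe chemistry and detection p-values, cell-composition heterogeneity,
copy-number changes beyond whole-chromosome trisomy, and correlated
(co-expression) noise. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to every
artifact of real data.

# Quality control

`markerGeneCheck()` computes per-sample medians of log2(CPM+1) over the
thyroid and muscle marker genes and flags samples whose muscle median
reaches the thyroid median (ties flag — conservative). Flagged samples are
removed *before* robust PCA, fixing the QC order.

`pcaGrid()` implements grid projection pursuit: each loading direction
maximizes a robust scale — the median absolute deviation scaled by 1.4826 —
of the projected samples, found by scanning angles in the planes spanned by
the current direction and each coordinate axis and halving the angular
aperture each sweep (10 angles per plane, 25 sweeps). Data are deflated
between components and loadings kept orthonormal. The search runs in the
SVD-reduced sample subspace: directions orthogonal to the span of the
centered samples have identically zero projections, so nothing is lost and
the search cost stops depending on the number of genes.

`detectOutliers()` flags samples whose robust score distance
$\sqrt{\sum_j (s_{ij}/\hat\sigma_j)^2}$ exceeds
$\sqrt{\chi^2_{k,q}}$. The QC pipeline additionally applies the standard
robust-PCA *orthogonal distance* rule (normal approximation on
$\mathrm{OD}^{2/3}$): in a genes >> samples study, a gross outlier lies
almost entirely outside any low-dimensional score subspace, and the score
distance alone cannot see it. Two calibration choices matter at n ≈ 10
samples and are deliberate: the rPCA input uses log2(CPM + 5) — the larger
prior count damps low-count heteroscedasticity that otherwise inflates
individual clean samples' orthogonal distances — and the pipeline cutoff
quantile is 0.99 per sample rather than 0.975, because ten 0.975-level
tests false-flag some sample in roughly one cohort in five. `k = 2`
components are used for outlier calling by default; the choice is
configurable and results are insensitive to k in the simulated conditions.

# Differential expression

Genes are prefiltered (kept when at least 4 samples show at least 10
counts), and size factors come from the median-of-ratios: per gene the
geometric mean over samples (genes containing zeros excluded), per sample
the median ratio to that reference.

`nbWaldTest()` fits, per gene, a negative-binomial log-link GLM of counts
on condition plus sex with log size factors as offsets, by iteratively
reweighted least squares. Control is the reference level, so positive log2
fold changes mean higher expression in DS. The dispersion plugged into the
weights is `max(trend(mu), MoM)`: a method-of-moments estimate stratified
by design cell, and a trend $a_0 + a_1/\mu$ fitted across genes by
30%-trimmed least squares (genes with mean normalized count below 3 are
excluded from trend fitting). The Wald statistic uses the expected
information; p-values are two-sided normal, adjusted by Benjamini-Hochberg.
Under the default null simulation this combination holds the empirical
type-I error within two percentage points of the nominal 5% — the
conservatism of taking the max roughly offsets the anticonservatism of the
plug-in normal Wald test at nine samples.

Fold-change shrinkage is ridge shrinkage under a normal prior N(0, tau^2)
with tau^2 moment-matched from the marginal spread of the estimates
(`tau^2 = var(lfc) - mean(se^2)`, falling back to `median(se^2)` when
non-positive); the shrunken estimate is `lfc * tau^2/(tau^2 + se^2)`. This
preserves the qualitative contract of posterior-mode shrinkage — stronger
contraction for noisier genes, never past zero — in closed form.

Chromosome-level statistics are Pearson chi-squared tests without
continuity correction: a 2x2 test of DEG status against chr21 membership; a
goodness-of-fit test of per-chromosome DEG counts against expectations
proportional to expressed genes (chr21 excluded); and a homogeneity test of
up/down counts across chromosomes (chr21 excluded). For the latter two,
chromosomes with expected counts below 5 are pooled.

# Differential methylation

Probes flagged allosomal, chromosome-21, polymorphic or cross-reactive are
removed. Single-CpG tests are ordinary least squares on M-values
(`log2(beta/(1-beta))`, beta clipped at 1e-6) with condition, sex and
surrogate covariates; effects are also reported as group differences on the
beta scale, where they are interpretable as methylation fractions.

The surrogate variable is the first principal component of the residuals
after projecting M-values on the known design, scaled to unit variance — a
deliberate, transparent simplification of iterative surrogate variable
analysis that is exact for a single additive batch axis orthogonal to the
design, which is the structure the generator plants and the situation the
method is used in here.

`findDMRs()` performs bump hunting. Per-CpG condition coefficients are
computed on the *beta* scale (so the 0.05 area cutoff reads as a
methylation difference) adjusting for covariates; within clusters of CpGs
at most 500 bp apart they are smoothed by a window-3 running mean — a
deterministic stand-in for loess smoothing that preserves bump structure
and makes hand-checkable examples possible. Candidate regions are maximal
single-sign runs of at least three CpGs with |smoothed coefficient| >= 0.05,
scored by the area (sum of absolute smoothed coefficients).

The null distribution pools candidate areas from 100 condition-label
permutations, and `p = (1 + #{null >= area}) / (1 + #null)`; BH-adjusted
p-values below 0.01 are significant. Two restrictions on the permuted
labelings matter at this cohort size:

* **Balance.** Permuted "DS" groups draw half their members from each true
  condition, so genuine group effects cancel instead of leaking into the
  null pool (with 4v5 samples, an unrestricted permutation frequently
  realigns with the true grouping).
* **Covariate transfer.** Balance alone is computed on raw group
  membership, but the coefficient is estimated after partialling out sex
  and surrogate covariates, which reweights samples and can silently undo
  the balance — or, worse, a draw nearly collinear with the surrogate
  absorbs the genome-wide batch effect into the permuted condition
  coefficient. Draws are therefore rejected when their covariate-adjusted
  contrast would inherit more than 25% of a true condition effect, or when
  their R^2 on the covariates exceeds 0.75.

A small-sample property worth knowing: with ~9 samples the pool of distinct
admissible labelings is finite, so permutation p-values have a floor of
roughly 1/(1 + #null regions). When every observed candidate is a true
region, the BH-adjusted value sits near that floor times (m/k), and in a
minority of simulated cohorts this lands just above the 0.01 cutoff —
aggregate sensitivity over replicate cohorts is the meaningful quantity,
and is above 0.8 under the default conditions with zero false positives.

# Integrative methylation-expression analysis

Significant DMRs (FDR < 0.01) are paired with significant DEGs
(FDR < 0.05) whenever the region overlaps the gene span extended by 2000 bp
on both sides; annotation categories are promoter (strand-aware
[TSS-2000, TSS], which wins ties), gene body, or flanking. The promoter
window is fixed at 2000 bp to match the cis window; exon structure is not
modeled, so regions inside the span are uniformly "gene_body". A
`scope = "all-dmr-genes"` flag relaxes the partner set to all tested genes
in cis of a significant DMR, since the analysis is well-defined for either
choice.

For each pair, per-sample median beta over the DMR's CpGs is correlated
(Pearson) with `log2(count/sizefactor + 1)`; the log2(x+1) transform
matches the DE normalization and handles zeros. The 95% confidence interval
is the 2.5%/97.5% percentile interval over paired bootstrap resamples
(degenerate zero-variance resamples are redrawn); the p-value compares |r|
to a null built by permuting the expression vector against the methylation
vector, `p = (1 + #{|r_perm| >= |r|}) / (n_perm + 1)`, so p can never be 0
and its floor is 1/(n_perm + 1). Bootstrap (for the CI) and permutation
(for the p) are kept separate on purpose: resampling pairs estimates
sampling variability of r, while permuting one margin builds the
exchangeable no-association null. Defaults are 100 000 bootstrap resamples
and 10 000 permutations. Raw p < 0.05 defines significance, as appropriate
for a handful of candidate pairs; a BH-adjusted column is reported
alongside. At nine samples the percentile bootstrap under-covers slightly
(coverage ~90-95% at nominal 95% in bivariate-normal checks); this is a
known small-n property of the percentile interval, accepted for fidelity
to the simple method.

# Gene-set enrichment

Genes are ranked by Wald z, descending, ties broken by gene id (the ranking
metric is configurable; z is the default because it encodes both effect and
precision). The enrichment score is the classic weighted Kolmogorov-Smirnov
running sum with weight exponent 1; the normalized score divides by the
mean |ES| of same-sign null scores from gene-label permutations (random
same-size sets), and the p-value is sign-matched — positive-ES sets are
compared only to the positive null tail, avoiding the bimodal-null mixing
problem. Gene-label rather than sample-label permutation is the only
defensible choice at this cohort size. Sets are size-filtered to 15-500
members in the universe; BH FDR < 0.01 defines significance. Note the
permutation floor: with n_perm permutations, roughly half land in each sign
class, so FDR < 0.01 for an isolated enriched set requires n_perm large
relative to the collection size.

Significant sets are reduced in two ways: greedy parent-set collapsing
(keep sets in p order, absorbing any later set with Jaccard >= 0.5 to an
already-kept set) and connected-component clustering at Jaccard >= 0.25
with the lowest-p member as representative. The two thresholds serve
different purposes — collapse removes near-duplicates; clustering groups
related biology — hence the two knobs. A hypergeometric
overrepresentation test over the same collections is included for
completeness.

# Pipeline, reproducibility and problem sizes

`runPipeline()` executes QC -> DE (+ chromosome enrichment) -> DMP/DMR ->
pairing -> eQTM -> GSEA, writes every stage as TSV (plus BED for
significant DMRs), and emits a JSON manifest with package and R versions,
all parameters, derived child seeds, content checksums of the inputs and
per-stage feature counts. All randomized stages draw independent child
seeds from one root seed, and a rerun with identical inputs and
configuration is byte-identical.

The shipped test-suite and acceptance computations use the default
simulated conditions: 2000 genes, 5000 CpGs, 12 samples (9 after QC), 100
DMR permutations, and 20 replicate cohorts for the dosage-recovery and
enrichment summaries; bootstrap/permutation counts are scaled to a few
thousand where full-size runs would add nothing but runtime. These sizes
are the package's own choices for a reproducible desk-scale demonstration
of the methods' operating characteristics.

# Known limitations

* The NB dispersion trend is a two-parameter curve with trimmed fitting,
  not an empirical-Bayes shrinkage of gene-wise dispersions; at very small
  counts the Wald test inherits the usual plug-in optimism.
* The LFC shrinkage prior is normal, so very large true effects are
  contracted slightly more than a heavy-tailed posterior mode would.
* The DMR p-value floor is bounded by the number of admissible
  permutations at small n (see above).
* The surrogate estimator extracts principal components of residual
  variation; it will absorb any strong unmodeled structure, including
  genuine biology that happens to be orthogonal to the design.
* Interval annotation models genes as single spans: promoter and gene-body
  categories are exact, but exon-level categories are collapsed into the
  gene body.
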