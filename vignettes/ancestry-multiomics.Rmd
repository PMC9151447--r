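---
title: "Methods: ancestry-stratified multi-omics analysis"
author: "AncestryOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-stratified multi-omics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AncestryOmics)
```

This vignette documents the statistical models, the design choices behind
them, and what the synthetic-data generator does and does not emulate. The
package implements a complete desk-scale pipeline for contrasting tumor
cohorts of African (AFR) and European (EUR) genetic ancestry across
genotype, somatic-mutation, expression, immune, regulatory and methylation
layers.

## Ancestry inference

Genotype dosages (0/1/2) are normalized per variant: missing values are
mean-imputed, the column mean is subtracted, and values are divided by
`sqrt(p(1-p))` with the smoothed allele frequency
`p = (1 + sum(g)) / (2 + 2n)`. Zero-variance variants are dropped. The
smoothing keeps monomorphic-after-imputation columns finite and is the
standard population-genetics variance normalization for genotype PCA.

Reference and query samples are **co-embedded in one PCA** (rather than
projecting queries onto reference-only loadings): the matrices are combined
before decomposition, which matches how reference panels are typically used
with tumor cohorts and avoids shrinkage of projected query scores. Each
reference label defines a centroid as the mean of its samples' scores on
PC1–PC3 — exactly three components, the convention for continental-ancestry
assignment — and every query is assigned to the nearest centroid by
Euclidean distance. Exact ties are broken lexicographically and flagged.
Ten components are computed by default for diagnostics. No variant pruning
(LD or otherwise) is applied; all supplied variants are used.

The sign of each component is fixed by making the largest-magnitude loading
positive, so results are reproducible across eigensolvers.

## Cohort statistics

Clinical variables are cross-tabulated against ancestry with missing
categories ("Missing", "Unknown", `NA`) tallied and excluded. The test is
the **uncorrected Pearson chi-squared** statistic; no Yates continuity
correction is applied, because the uncorrected statistic is the one that
reproduces the published stage-by-ancestry association in this setting.
Structural zero margins are an error rather than a silent NaN.
Multiple-testing adjustment is Benjamini–Hochberg throughout the package
(`bhAdjust()` delegates to `p.adjust`).

## Somatic mutations

MAF tables from several callers are merged by the union rule: a variant is
kept when at least one caller reports it, keyed on (sample, chromosome,
position, ref, alt), with the reporting callers recorded as provenance.
Conflicting reference alleles at one genomic site abort the merge. Tumor
mutation burden is the raw per-sample count of merged variants — all
variant classifications count, and no per-megabase normalization is applied
(the capture size needed for a denominator is not part of the inputs).

The hotspot score groups a gene's mutation positions into maximal clusters
whose adjacent positions are at most `gapMax` (default 5 bp) apart and
returns the Simpson concentration `sum(f_c^2)` of cluster fractions: 1
exactly when a single hotspot holds every mutation, `1/m` for `m` scattered
singletons. It is translation-invariant and weakly increasing in `gapMax`.

## Differential expression

Counts are normalized with median-of-ratios size factors and transformed to
`log2(count/sf + 1)`. Per gene, an ordinary least-squares model with design
`~ ancestry + age_group + tumor_location` is fit on the transformed scale;
the AFR-vs-EUR coefficient is reported as the log2 fold change with its
two-sided t-test p-value and BH q. A plain OLS engine was chosen over a
negative-binomial Wald model deliberately: on the log scale with moderate
dispersion it is well calibrated (the null-simulation KS checks in the test
suite verify uniform p-values), it is transparent enough to oracle-test
against `lm()`, and the package's validation currency is parameter recovery
on simulated truth rather than replication of any particular cohort's DEG
counts. Rank-deficient designs are an error naming the aliased columns.

DEGs are classified as up when fold change exceeds 1.5 with q < 0.05, down
below 0.5 with q < 0.05. Over-representation of a gene set in a query list
uses the hypergeometric upper tail over a user-supplied universe, BH-adjusted
across sets; no annotation database is bundled.

## Immune deconvolution

The score of an immune population in a sample is the arithmetic mean of the
transformed expression of that population's marker genes — the MCP-counter
definition. Scores are comparable across samples within a population only;
the package never compares scores across populations. A default marker file
(`inst/extdata/mcp_markers.gmt`) ships with canonical markers for ten
populations and is user-editable; all tests use synthetic markers.

Group comparisons use the **unpaired two-sided Wilcoxon rank-sum** test.
When both groups have at most 8 samples the p-value is computed by complete
enumeration of group assignments on midranks, which remains exact under
ties (`wilcox.test` cannot produce exact p-values with ties); larger groups
use the normal approximation with tie correction and no continuity
correction. A paired signed-rank test would be inapplicable here because
the ancestry groups are independent and of different sizes.

Confounding checks fit `score ~ ancestry * factor2` and report Type II
F-tests (via `car::Anova`), which are invariant to factor ordering under
imbalance. The continuous score is analyzed directly rather than
dichotomized into high/low: dichotomization discards information and
introduces an arbitrary cut point. When an ancestry-by-factor cell is
empty, the interaction is dropped with a warning.

## Promoter motifs and composite modules

TRANSFAC-format count matrices are regularized with a pseudocount of 0.01
per cell (fixed, for reproducibility) and scored as log2 odds against a
uniform background over the window −1000 bp to +100 bp around the TSS. Both
strands are scanned; reverse-strand hits are reported at their
forward-strand leftmost base. The default hit threshold is 60% of the
motif's maximum attainable score — a conventional operating point when
per-matrix curated cutoffs are not available — and is configurable
per motif. Binding-site enrichment between a yes-set and a no-set
dichotomizes regions by hit presence and tests the 2×2 table (Pearson
chi-squared, or Fisher's exact test when any expected cell is below 5),
with BH across the library.

Composite modules — sets of motifs whose sites co-occur within a confined
window — are found by a genetic algorithm over motif subsets of size at
most K (default 10). The module score of a region is the maximum over
sliding windows of width W (default 200 bp) of the sum across members of
the best hit log-odds inside the window (0 for a member without a hit).
Fitness is the rank AUC separating yes-set from no-set module scores minus
`0.01·|members|`; AUC was chosen because it is rank-based (robust to score
scale) and mirrors the Mann–Whitney criterion described for this class of
module-discovery methods, and the size penalty keeps modules minimal. The
GA uses tournament selection (size 3), elitism (2), and add/remove/swap
mutation at probability 0.3 over a population of 50 for 100 generations,
is deterministic under its seed, and returns the best subset ever seen. On
libraries small enough to enumerate, the GA provably reaches the exhaustive
optimum (asserted in the tests).

## Master regulators

The signaling network is a directed multigraph of typed molecular
interactions. For every non-TF node `v`, the enriched TFs reachable within
a BFS radius R (default 10) are collected with their distances, and

```
score(v) = (sum over reached t of 1/d(v, t)) * |T_v| / |T|
```

rewards proximity and coverage jointly; ties break by smaller mean distance,
then node name. The inverse-distance coverage form was chosen because it is
monotone (reaching one more TF never lowers a score), has no free weights
beyond R, and is simple enough to verify against an exhaustive per-node BFS
oracle. A candidate closes a **positive feedback loop** when a TF it reaches
regulates a differentially expressed gene whose product is the candidate
itself; the witness TF, gene, and candidate-to-TF path are returned.

## Methylation

Probes are removed — in a documented precedence order (unannotated, missing
value, cross-reactive, sex chromosome, non-CpG, SNP-related, multi-hit) —
with a per-rule tally. Type-II probe betas are quantile-mapped within each
sample onto that sample's type-I distribution: a rank-preserving map that
keeps all output in [0, 1], standing in for mixture-based normalization
while retaining its two invariants (rank order and range). Tests run on
M-values (`log2(beta/(1-beta))`, betas clipped at 1e-6) with the same OLS
engine and covariates as expression; effects are reported on the beta scale
as group mean differences, with direction (hyper/hypo) from the sign.

Tumor-specific DMPs are derived in two passes: tumor-vs-normal DMPs
(q < 0.05) within each ancestry form a candidate set by **union** — the
permissive reading, configurable — and the covariate-adjusted AFR-vs-EUR
tumor contrast is then restricted to the candidates with BH over candidates
only (adjusting over the tested set matches the restriction). CpGs map to
gene features strand-awarely: promoter iff the TSS-relative offset lies in
the closed window [−1200, +200], then UTR, then gene body, then enhancer
(when supplied), else intergenic; all matching genes are reported.

A differentially expressed gene is **methylation-sensitive** when, for its
lowest-q associated CpG, the Pearson correlation between beta and
normalized expression is negative with p < 0.05; pooled and per-ancestry
correlations are reported, with inclusion decided on the pooled value.
Finally, TFs partition by methylation context: a TF is "hyper" when any of
its binding sites lies within ±1 kb of a hypermethylated DMP associated
with a downregulated gene, "hypo" analogously for hypomethylated DMPs near
upregulated genes; hyper-only, hypo-only, and shared sets are disjoint by
construction.

## The synthetic-data generator

The generator is first-class, tested code: every planted effect is returned
(and written) as machine-readable truth so each downstream stage has a
parameter-recovery test.

* **Genotypes** follow the Balding–Nichols construction: ancestral
  frequency Uniform(0.05, 0.95), population frequency
  Beta(p(1−F)/F, (1−p)(1−F)/F) at divergence F, binomial dosages. F
  defaults to 0.1, a typical continental Fst.
* **Metadata** mirrors the demographic imbalances of observational
  colorectal cohorts — AFR patients more often diagnosed under 50 (20% vs
  11%) and with right-sided tumors (52% vs 33%), stage distributions taken
  from the published cohort table — so covariate adjustment is genuinely
  exercised. Default cohort sizes (55 AFR / 456 EUR) mirror the multi-omics
  cohort scale; tests and the acceptance script use 40–50 per group.
* **Expression** is negative binomial (dispersion 0.1 by default) around
  `baseline · 2^(Xβ)`: planted genes carry the configured ancestry log2
  effect, a random 10% of genes carry mild age/location effects (SD 0.5),
  and each population's markers gain 4 log2 units per unit of that sample's
  latent immune fraction. Fractions are independent Beta(2, 2) draws — only
  marker-mediated effects are modeled, which is precisely the assumption
  marker-mean deconvolution makes — shifted by −0.3 for AFR cytotoxic
  lymphocytes and neutrophils by default. A marker planted as DE with a
  sign conflicting its population's shift is rejected.
* **Methylation** is inverse-logit of Normal(logit(base) + effects, 0.5),
  so betas cannot leave (0, 1). Planted DMPs receive a fixed 0.8-logit
  tumor shift in both ancestries (making them tumor-specific) plus an
  ancestry shift computed on the tumor baseline so the realized AFR-vs-EUR
  beta difference matches the configured delta. Planted
  methylation-sensitive CpGs are drawn with the stated-sign coupling to
  their gene's standardized log2 expression, and are placed in their gene's
  promoter on a synthetic coordinate system (gene g at TSS 10000·g).
* **Promoters** are i.i.d. uniform nucleotides; each yes-set promoter
  carries one site sampled from every planted-module PWM, placed without
  overlap inside a shared 150-bp window at a random location, with true
  coordinates returned.
* **Networks** wire each planted master regulator to 60% of the TFs
  directly and 30% through one intermediate (≥80% coverage within ≤2
  steps) over a sparse random background; feedback-flagged regulators get a
  TF-to-encoding-gene regulation whose gene is differentially expressed.

All generators are byte-identical under a fixed seed (each derives its
stream from `seed` plus a fixed per-generator offset via
`withr::with_seed`).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium and admixture, read-level
sequencing noise and library composition effects, transcript-length bias
(so "log FPKM" is realized as `log2(normalized count + 1)`; a length-aware
path applies when lengths are supplied), probe-type chemistry beyond the
type-I/II distinction, copy number, cell-type composition of methylation,
and realistic motif co-occurrence backgrounds. Recovery rates on this
generator are upper bounds on what identical settings would achieve on
real cohorts.

## Numerical choices and degenerate inputs

* Chi-squared with an empty margin, all-variants-dropped genotype
  matrices, empty region sets, and a TF set that maps nowhere are errors,
  not warnings.
* Mean imputation for missing dosages; zero-variance regulators and
  sub-3-sample correlation groups are skipped with warnings.
* BH inputs are validated to [0, 1]; q ≥ p always holds.
* The exact rank-sum enumeration bounds both groups at 8
  (C(16, 8) = 12870 assignments); beyond that the tie-corrected normal
  approximation is used.
* MAF coordinates are 1-based inclusive; BED-like inputs are 0-based
  half-open with converters provided.

## Problem sizes

The test suite and acceptance script run simulations at 40–100 samples per
group, 300–2000 features per layer, 500 variants, 20-motif libraries over
60+60 promoters, and 200-node networks — sizes chosen so the full suite
completes in about a minute while leaving every recovery margin wide (the
observed recovery rates sit at or near 100% against thresholds of 90–95%).

## Known limitations

The OLS surrogate does not shrink dispersions, so very small groups (n < 10
per arm) lose power relative to specialized count models; the quantile map
normalizes ranks but not mixture shapes; the master-regulator score treats
all edges equally regardless of interaction type; and TCGA-scale results
from the published analysis (DEG counts, enriched-TF counts, DMP totals)
depend on external data and proprietary motif/network content, so they are
out of scope for verification here.
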