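# AncestryOmics

A desk-scale R implementation of an ancestry-stratified multi-omics tumor
analysis. Cohorts of African (AFR) and European (EUR) genetic ancestry differ
in their colorectal tumor microenvironment — notably lower cytotoxic
lymphocyte and neutrophil infiltration in AFR patients — and this package
provides every analytic stage needed to dissect such differences, together
with a synthetic-data generator that plants known effects in every layer so
each stage carries a parameter-recovery test.

It is written for computational biologists who want a transparent, fully
testable version of this kind of pipeline:

- **Ancestry inference** — EIGENSTRAT-style genotype normalization
  (dosage `g` scaled by `sqrt(p(1-p))` with the smoothed frequency
  `p = (1 + Σg) / (2 + 2n)`), principal components, and nearest
  labeled-reference-centroid assignment by Euclidean distance on PC1–PC3.
- **Cohort statistics** — category-by-ancestry contingency tables with
  missing-value exclusion, uncorrected Pearson chi-squared tests, and
  Benjamini–Hochberg q-values.
- **Somatic mutations** — union-merge of MAF tables from multiple callers
  (MuSe, MuTect2, SomaticSniper, VarScan2) keyed on
  (sample, chromosome, position, ref, alt), tumor mutation burden, and a
  Simpson-concentration hotspot score `Σ f_c²` over gap-defined mutation
  clusters (1 iff one hotspot holds all mutations).
- **Differential expression** — per-gene OLS on
  `log2(count/sizeFactor + 1)` with ancestry + age + tumor-location design,
  median-of-ratios size factors, `>1.5`-fold / `<0.5`-fold and `q < 0.05`
  DEG gates, and hypergeometric over-representation tests.
- **Immune deconvolution** — marker-mean scores per immune population
  (the MCP-counter contract: comparable within a population across
  samples), exact small-sample Wilcoxon rank-sum comparisons, and Type II
  two-way ANOVA confounding checks.
- **Regulatory analysis** — log-odds PWM scanning of promoter windows
  (−1000/+100 around the TSS), binding-site enrichment, composite
  cis-regulatory module discovery by a genetic algorithm (AUC fitness over
  sliding-window co-occurrence scores), and master-regulator search over a
  directed signaling network scored by
  `score(v) = (Σ_t 1/d(v,t)) · |T_v|/|T|`, with positive-feedback-loop
  detection through differentially expressed genes encoding the regulator.
- **Methylation integration** — 450K-style probe filtering, quantile
  normalization of type-II onto type-I probes, M-value linear models with
  covariates, tumor-specific DMP derivation (tumor-vs-normal candidates,
  then an ancestry contrast restricted to them), promoter mapping
  (−1200/+200), a methylation-sensitive gene screen (lowest-FDR CpG,
  negative Pearson correlation with expression, p < 0.05), and a
  TFBS-by-methylation-state partition (±1 kb).

## Worked example

```r
library(AncestryOmics)

cfg <- simConfig(seed = 7, nAfr = 40, nEur = 40, nGenes = 1000,
                 nSnps = 300, networkSize = 120,
                 nYesPromoters = 30, nNoPromoters = 30)
md <- simulateMetadata(cfg)
ex <- simulateExpression(cfg, md)

de <- differentialExpression(ex$counts, md)
table(de$class)
#> down none   up
#>   54  896   50

head(de[order(de$q), ], 3)
#>      gene    log2fc            p            q class
#> 81 G00081  1.647482 3.102353e-28 3.102353e-25    up
#> 5  G00005  1.545849 2.146752e-27 1.073376e-24    up
#> 76 G00076 -1.748844 8.154102e-27 2.038525e-24  down

scores <- mcpScores(vstLikeTransform(ex$counts), ex$markerSets)
anc <- setNames(md$ancestry[match(colnames(scores), md$sample_id)],
                colnames(scores))
cmp <- rankSumCompare(scores, anc)
cmp[cmp$population %in% c("cytotoxic_lymphocytes", "neutrophils"), ]
#>              population n1 n2 statistic            p
#> 3 cytotoxic_lymphocytes 40 40      1155 7.660302e-06
#> 8           neutrophils 40 40      1219 1.140271e-04

nw <- simulateNetwork(cfg)
head(findMasterRegulators(nw$network, nw$tfs), 3)
#>   node    score n_reached mean_dist                            reached
#> 1 MTR2 7.750000        10       1.6 TF01,TF02,...,TF10
#> 2 MTR1 7.666667        10       1.8 TF01,TF02,...,TF10
#> 3 N082 4.700000        10       2.5 TF01,TF02,...,TF10
```

The generator planted 100 ancestry-affected genes (50 up at +1.5 log2, 50
down); the DEG table recovers 50 up and 54 down. The AFR samples were
simulated with a −0.3 shift in their latent cytotoxic-lymphocyte and
neutrophil fractions, and the rank-sum comparison finds both populations
significantly lower in AFR. The two planted master regulators top the
network ranking, each reaching all 10 TFs within 2 steps.

`runPipeline(cfg, outDir = "out")` chains all stages and writes every
stage's TSV tables plus a machine-readable `truth/planted.tsv` for
comparison against the planted ground truth.

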