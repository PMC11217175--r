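# ChemoResNet

Analysis pipeline for paired pre-/post-treatment blood transcriptome cohorts
stratified by chemotherapy-resistance pattern, as used in small-cell lung
cancer (SCLC) studies of platinum/etoposide (EP) resistance. The design it
targets: a small cohort of patients (by default 5 with primary resistance,
PR, and 12 with acquired resistance, AR), each contributing one
pre-treatment and one post-treatment log2-scale expression profile, with
per-patient time to tumor progression.

The pipeline chains five analysis stages:

1. **Normalization and differential expression.** Quantile normalization
   (every sample is mapped onto the row-means-of-sorted-columns reference
   distribution), then moderated t-tests — paired one-sample t on
   within-patient (post − pre) differences, or pooled two-sample t for
   PR_pre vs AR_pre — with empirical-Bayes variance shrinkage. A gene is
   called differentially expressed when its Benjamini–Hochberg adjusted
   p ≤ 0.05 **and** |log2FC| > 0.3 (inclusive on p, strict on fold change).
2. **Pseudo-single-cell scoring.** A single-sample rank-weighted enrichment
   statistic scores user-supplied cell-type signatures (GMT) per sample:
   genes are ranked by decreasing expression and the score is
   Σᵢ (in-set cumulative weight fraction − out-set cumulative fraction),
   with rank weights (N − i + 1)^α, α = 0.25. Composite immune/stromal/
   microenvironment scores and rank tests compare groups.
3. **Co-expression network and hub genes.** Over a cancer-gene panel,
   adjacency wᵤᵥ = |cor(u,v)|^β (β = 6); edges with weight ≤ 0.01 are
   dropped, each gene keeps its top 30% of incident edges (union
   semantics), and the maximum-weight spanning forest (minimum total
   distance 1 − w) is extracted. Genes with tree degree > 4 are hubs.
4. **Hub associations.** Pearson correlation of hub expression with cell
   scores and with per-sample pathway activity scores (or median-split rank
   tests).
5. **Progression analysis.** Patients are split at the median hub
   expression (pre-treatment samples); Kaplan–Meier curves and the
   two-group log-rank test assess time to progression.

Because studies of this design rarely deposit their arrays, the package
includes a seeded synthetic-cohort generator (`simulateCohort()`) that
plants known differential expression, hub-centered co-expression modules
and expression-dependent progression hazards, and reports the planted truth
for recovery testing.

## Worked example

```r
library(ChemoResNet)

cohort <- simulateCohort(simConfig(
  nGenes = 1000, seed = 42,
  deSpec = data.frame(gene = 1:50, delta = 1.5, contrast = "pre_vs_post"),
  moduleSpec = data.frame(hub = c(101, 111), nLeaves = 9, rho = 0.9),
  survBeta = 1))
se <- cohort$experiment
se
#> ResistanceExperiment: 1000 genes x 34 samples
#>   samples: AR_post=12, AR_pre=12, PR_post=5, PR_pre=5

deg <- diffExpr(se)          # paired pre/post, empirical-Bayes moderation
sum(deg$is_deg)
#> [1] 46
head(deg[order(deg$adj_p), c("gene_id","log2fc","t_stat","adj_p","is_deg")], 3)
#>    gene_id log2fc t_stat    adj_p is_deg
#> 21   G0021   2.20   6.40 3.98e-07   TRUE
#> 38   G0038   2.13   6.22 3.98e-07   TRUE
#> 42   G0042   2.14   6.26 3.98e-07   TRUE

panel <- rownames(se)[96:195]      # the "cancer-related" gene panel
hubs <- findHubs(spanningForest(filterNetwork(buildAdjacency(se, panel))))
head(hubs, 3)
#>    gene degree is_hub
#> 1 G0101      9   TRUE
#> 2 G0111      8   TRUE
#> 3 G0115      3  FALSE

unlist(truthRecoveryReport(cohort$truth, deg = deg, hubs = hubs))
#> deSensitivity         deFdp   hubRecovery
#>          0.92          0.00          1.00
```

46 of the 50 planted DE genes are recovered with no false calls at the
planted effect size, and both planted module hubs are the only genes whose
spanning-tree degree exceeds 4. Median-split progression analysis of the
planted prognostic hub:

```r
md <- as.data.frame(SummarizedExperiment::colData(se))
pre <- md[md$timepoint == "pre", ]
sp <- medianSplit(SummarizedExperiment::assay(se)[, pre$sample_id], cohort$truth$survGene)
logrankTest(pre$progression_days, pre$progression_event, sp)
#> Log-rank test: chi-square = 7.174 (1 df), p = 0.007397
#>              high     low
#> n        8.000000  9.0000
#> observed 7.000000  8.0000
#> expected 3.223602 11.7764
```

High pre-treatment expression of the planted hub carries more than twice
the expected number of progression events relative to the log-rank null,
as planted (`survBeta = 1` per SD of hub expression raises the hazard of
high-expression patients).

`runPipeline(config, outDir, seed)` (or
`Rscript inst/scripts/run-pipeline.R --out <dir> --seed <int>`) runs all
five stages end-to-end — on real TSV/GMT inputs or in synthetic mode — and
writes every intermediate as TSV plus a `manifest.yaml`; identical config
and seed give byte-identical outputs.

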