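---
title: "Methods: paired blood-transcriptome chemoresistance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired blood-transcriptome chemoresistance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemoResNet)
```

# The design and its data model

ChemoResNet analyses a small paired oncology cohort: each patient
contributes a pre-treatment and a post-treatment log2-scale expression
profile, and belongs to one resistance group — primary resistance (PR,
progression during treatment) or acquired resistance (AR, relapse shortly
after treatment). The central container, `ResistanceExperiment`, extends
`SummarizedExperiment` and enforces the design invariants at construction:
unique gene and sample identifiers, finite values, at most one sample per
patient and timepoint, and a resistance group constant within each patient.
Gene identifiers are opaque case-sensitive strings; no symbol remapping or
probe collapsing is attempted, because panels and signatures are supplied
by the user and must match the matrix verbatim.

The default cohort geometry — 5 PR and 12 AR patients, 34 samples — is the
scale every default and every calibration in this package is tuned to.
Statistical power at this scale is intrinsically modest; the package's role
is to make the analysis reproducible and its operating characteristics
measurable, not to overcome the sample size.

# Normalization and differential expression

`quantileNormalize()` maps every sample onto the common reference
distribution formed by the row means of the column-sorted matrix; ties
receive the mean of the reference values they span, so within-sample rank
order is preserved exactly. A caveat worth stating: quantile normalization
assumes the samples' expression distributions differ only technically. If a
large, direction-biased fraction of genes truly shifts between arms (we
observe this in simulation when ~10% of genes all move the same way), the
forced distribution equality leaks part of that shift into null genes and
inflates the false-discovery proportion of the downstream test. With
roughly balanced up/down changes, or modest DE fractions, the effect is
negligible.

`diffExpr()` supports the two contrasts the design admits:

* **paired_pre_post** — one-sample t on within-patient differences, with
  the declared sign convention log2FC = mean(post − pre);
* **group_pre_vs_pre** — pooled-variance two-sample t at the pre
  timepoint, log2FC = mean(groupA) − mean(groupB) with the group order
  explicit in the call (there is no canonical direction for this contrast,
  so it is never implicit).

`moderation = "empirical_bayes"` (default) shrinks per-gene variances
toward a prior fitted across genes before forming t and its augmented
degrees of freedom — the standard moderated-t machinery, appropriate when
thousands of genes share information and n is ~17 pairs.
`moderation = "none"` is the plain textbook t, retained as a
hand-checkable oracle path and used in the calibration tests (its null
p-values are exactly uniform by construction, which the suite verifies at
the 10,000-gene scale: unadjusted type-I error 0.05 ± 0.01).

A gene is called differentially expressed when adjusted p ≤ 0.05
(inclusive) **and** |log2FC| > 0.3 (strict), thresholds applied literally
as printed conventions of the field; both are parameters. The default
criterion uses Benjamini–Hochberg adjusted p; `useAdjusted = FALSE`
switches to raw p for users who want the laxer screening variant. Genes
with zero residual variance have no defined t under
`moderation = "none"`; they are recorded with p = 1 and flagged — never
p = 0 — so constant genes cannot become discoveries.

# Single-sample signature scoring

Trained cell-type deconvolution methods ship fitted signatures,
calibration curves and spillover corrections that are data products, not
procedures; re-deriving them is out of scope. `ssgseaScore()` instead
computes the rank-weighted single-sample enrichment statistic that
underlies such scores, over *user-supplied* GMT signatures: per sample,
genes are ranked by decreasing expression (ties broken by gene id,
lexicographic — deterministic and platform-stable), the in-set cumulative
fraction weights the gene at rank *i* by (N − i + 1)^α normalized over
in-set weights, the out-set cumulative fraction steps by 1/(N − |S|), and
the score sums the pointwise differences. α defaults to 0.25, the common
choice in single-sample enrichment practice; α = 0 gives the unweighted
statistic with the exact antisymmetry score(S) = −score(S^c), which the
suite uses as a brute-force cross-check. The statistic is a pure rank
functional: strictly monotone per-sample transforms leave it unchanged, so
scores are comparable across normalization choices.

Composite scores keep the microenvironment summary deliberately simple:
immune = mean of immune-signature scores, stromal = mean of
stromal-signature scores, microenvironment = immune + stromal. Group
comparisons use rank tests (Mann–Whitney unpaired, Wilcoxon signed-rank
paired), exact for small untied samples (combined n ≤ 12, which covers the
5-vs-12 comparison) and tie-adjusted continuity-corrected normal
approximation otherwise; paired comparisons whose differences are all zero
return p = 1 with a flag rather than an error.

# Co-expression network and hub discovery

`buildAdjacency()` forms the weighted-correlation adjacency
|cor(u,v)|^β over the user's gene panel. β = 6, unsigned, is the
conventional default for weighted co-expression screening when no
scale-free fit is attempted; both the power and the signed variant
(((1 + r)/2)^β) are exposed. The two-stage filter is applied in a fixed
order: first every edge with weight ≤ 0.01 is removed (strict >), then
each gene marks its strongest ⌈0.30 · k⌉ incident edges and an edge
survives if **either** endpoint marked it. Ceil guarantees every
non-isolated gene keeps at least one edge; union (rather than
intersection) semantics preserve connectivity and match the dense
filtered networks this procedure is known to produce. The order matters —
sub-floor edges must not inflate a gene's incident count before the
fraction is taken — and the suite pins it with a case where the reversed
order yields a different graph.

Hubs are read from the maximum-total-weight spanning forest (Kruskal on
distance 1 − w, one tree per connected component) rather than from the
filtered graph: filtered co-expression graphs are dense enough that most
genes exceed any small degree bound, so degree only discriminates on the
tree. A gene is a hub when its tree degree strictly exceeds 4. All
tie-breaking — in edge ranking and in Kruskal's scan — is lexicographic on
node pairs, making the network, forest and hub report bit-reproducible.
The spanning forest is cross-checked in the suite against exhaustive
spanning-tree enumeration on small graphs and against an independent MST
implementation.

# Outcome association

`medianSplit()` labels samples above the across-sample median "high";
values exactly at the median go to "low", so the high group strictly
exceeds the median (the convention matters for odd n and tied values).
Progression analysis is patient-level: one time-to-progression and event
indicator per patient, with the split computed on pre-treatment expression
— baseline expression is the quantity available when a prognostic marker
would be used. Kaplan–Meier curves use the product-limit estimator
(events before censorings at tied times); the two-group log-rank test uses
the hypergeometric variance with the (n − d)/(n − 1) tie factor. With 17
patients split 8/9 the chi-square reference is slightly anticonservative;
the suite measures the realized type-I error at this exact scale and
requires it within 0.05 ± 0.02. No multiple-testing correction is applied
across candidate genes in survival screening by default, matching common
presentation of such screens; `bhAdjust()` is available when rigor is
preferred.

Pathway association offers both analyses a reader might assume: rank-sum
comparison of pathway scores between median-split halves, and Pearson
correlation of gene expression with pathway score (p from the t transform,
|r| = 1 reported as p = 0, zero-variance inputs flagged rather than
guessed).

# The synthetic cohort generator

`simulateCohort()` emulates a microarray-style paired cohort on the log2
scale — Gaussian intensities around a baseline of 8 with residual sd 1.0,
values typical of normalized two-color array data — with:

* a per-gene patient random intercept (sd 0.5) shared by a patient's two
  samples, which is what makes the paired analysis meaningful;
* planted DE genes, shifted additively by δ in the stated contrast arm;
* planted co-expression modules in star topology: each leaf is
  ρ·(hub) + √(1 − ρ²)·noise, so every leaf-hub correlation has expectation
  ρ and the hub is the unique within-module connector — an unambiguous
  ground truth for spanning-tree hub recovery (leaves occupy the indices
  immediately after their hub);
* exponential progression times with log hazard
  log(h₀) + survBeta · z, where z is the standardized pre-treatment
  expression of the first planted hub. h₀ = 0.004/day gives a ~6-month
  median time to progression, typical of extensive-stage SCLC on EP;
  censoring is administrative at rate 0.1 (nearly all such patients
  progress within follow-up).

The generator does **not** simulate probe-level artifacts, batch or
scanner effects, heavy-tailed intensity noise, or transcriptome-wide
correlation beyond the planted modules. Passing recovery tests therefore
demonstrates that the pipeline's logic recovers planted structure at the
study's scale — not that it would perform identically on real plasma
arrays, where background correlation makes hub discovery strictly harder.

Recovery at the default scale, as measured by the test suite: with two
planted star modules (9 leaves, ρ = 0.9) inside a 100-gene panel and 34
samples, both hubs are recovered in ≥ 80% of seeded replicates (the suite
observes essentially always). The DEG filter's empirical false-discovery
proportion stays ≤ 0.07 at q = 0.05 with 10% planted non-nulls.

One planted effect is *not* reliably detected at this scale, and that is a
property of the analysis, not a defect of the implementation: a continuous
log-linear hazard in hub expression, analysed by dichotomizing at the
median, loses a substantial fraction of the effect (the classic cost of
median splits), and with 17 patients the log-rank test's detection rate at
survBeta = 1/SD falls short of 80%. The acceptance script reports the
measured detection rate rather than hiding it; users planning validation
studies at this design scale should expect median-split progression
screens to be underpowered for continuous effects of this size.

# Numerical and reproducibility choices

* All randomness descends from a single integer seed; the pipeline derives
  a fixed per-stage offset from it, so a stage can be re-run in isolation.
  Identical config + seed give byte-identical output files.
* Expression and metadata writers print 17 significant digits, making
  write/read a bitwise round trip.
* Tolerances: exact equality is asserted wherever arithmetic is exact
  (thresholds, tie rules, round trips); simulation-based checks use the
  bands stated above at fixed problem sizes (10,000 genes × 17 pairs for
  t calibration; 2,000 replicates for log-rank calibration; 50–100
  replicates for recovery), chosen to keep the default suite within a few
  minutes on one CPU.
* Degenerate inputs follow a "flag, don't guess" rule: zero-variance genes
  in tests, all-zero paired differences, and zero-variance correlation
  inputs produce flagged records with conservative p-values; truly
  undefined requests (constant gene in `medianSplit()`, log-rank without
  events, empty gene-set overlap) are errors naming the offender.

# Pipeline orchestration

`validateConfig()` reads a flat YAML key-value file, rejects unknown keys
and out-of-range values, and enforces one input mode: either all five
real-data paths (expression, metadata, panel, signatures, pathways —
checked for existence before any stage runs) or synthetic mode.
`runPipeline()` executes the stages in order with START/END logging,
writes every intermediate as headered TSV, and records every file with its
row count in `manifest.yaml` together with the config echo. Two pragmatic
rules keep the network stage well-posed on sparse outcomes: if fewer than
10 panel genes survive the DEG filter the full panel is used (logged), and
if no gene exceeds the hub degree bound the three genes of highest tree
degree continue downstream as flagged candidates, so the association and
survival stages always produce inspectable output.

# Known limitations

* Signature scoring is a raw enrichment statistic; scores are not
  proportions, do not sum to one, and are not calibrated across cell
  types.
* The ESTIMATE-style composites are means of signature scores, preserving
  the *comparisons* such scores support without reproducing any fitted
  coefficients.
* Panels and signatures come from the user; no pathway database is
  queried.
* No Cox regression or hazard-ratio estimation — the survival layer
  mirrors the median-split log-rank screen and inherits its power
  limitations, quantified above.
* Quantile normalization's asymmetric-DE caveat, discussed in the
  normalization section.
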