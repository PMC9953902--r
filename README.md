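# layerscope

Layered molecular subtyping of tumor expression cohorts.

Bulk tumor expression data superimpose several independent biological
signals — stromal adhesion/extracellular-matrix content, immune
infiltration, and the tumor cells' own transcriptional program. A single
clustering of all genes collapses these axes into one partition and hides
the weaker ones. `layerscope` separates them: it iteratively finds the
genes carrying the dominant remaining source of sample-to-sample
variation (sparse k-means), partitions the samples on those genes alone
(consensus clustering), removes the genes, and repeats — peeling one
*layer* of information per round and merging redundant layers afterwards.
A decomposable Gaussian graphical model over the most variable genes
organizes them into functional nodes whose mean expression summarizes a
biological process per sample. Discovered groups are characterized by SAM
permutation differential expression, Kruskal–Wallis/Dunn node-activity
comparisons, hypergeometric gene-set labeling, and Kaplan–Meier /
log-rank disease-free-survival analysis.

The intended user is a computational biologist with a merged multi-cohort
expression matrix (genes × samples, log2) and a clinical table, who wants
adhesion-, immune- and tumor-intrinsic classifications of the same
samples rather than one entangled subtyping.

## The methods in brief

* **Sparse k-means** (Witten–Tibshirani): maximize
  `sum_j w_j BCSS_j` subject to `||w||_2 <= 1`, `||w||_1 <= s`,
  `w >= 0`; genes below the soft threshold get exactly zero weight, and
  the positive-weight genes define a layer. The bound `s` is tuned by a
  permutation gap statistic with the one-standard-error rule.
* **Consensus clustering** (Monti): co-clustering frequencies over
  subsamples; the number of groups k minimizes PAC (the proportion of
  ambiguous consensus entries), with near-ties resolved to the larger k
  so nested structure is not under-split.
* **Decomposable graphical model**: Chow–Liu maximum-likelihood spanning
  tree under Gaussian mutual information `MI = -0.5 ln(1 - rho^2)`,
  then greedy chordality-preserving edge additions scored by
  `dBIC = n ln(1 - r^2_{uv.S}) + ln n` (partial correlation given the
  minimal separator S); branches cut at high-betweenness edges become
  functional nodes, summarized by mean expression.
* **SAM**: moderated d-statistic `d = (xbar_2 - xbar_1)/(s_i + s_0)`
  with Tusher's CV rule for `s_0`, permutation null (exhaustive on small
  designs), automatic Delta at a target FDR, and a global permutation
  gate that keeps complete-null data call-free.
* **Survival**: Kaplan–Meier curves, log-rank tests, Mantel–Haenszel
  hazard ratios with `exp(ln HR ± 1.96 sqrt(1/E1 + 1/E2))` intervals,
  Cox estimates alongside.
* **Synthetic cohorts**: `generateCohort()` plants orthogonal adhesion
  (2-level), immune (2-level) and molecular (4-level) gene-block factors
  with additive batch offsets and exponential relapse hazard depending on
  the adhesion group — the ground truth every stage is validated against.

See the vignette (`vignettes/layered-subtyping.Rmd`) for the full model
descriptions, parameter conventions, and design rationale.

## Worked example

Generate a synthetic 400-sample cohort with planted layers, peel and
merge layers, score them against the truth, and stratify survival by the
discovered adhesion groups:

```r
library(layerscope)

cfg  <- cohortConfig(nSamples = 400L, seed = 7L)
sim  <- generateCohort(cfg)
expr <- correctBatchEffect(sim$expr)
expr
#> CohortExperiment: 600 genes x 400 samples, 3 batch(es)
#>   batches: batch1 (104), batch2 (25), batch3 (271)

layers <- peelLayers(expr, kRange = 2:5, nPerms = 5, nResamples = 200,
                     nstart = 3, seed = 7)
merged <- mergeLayers(layers, expr, nResamples = 200, nstart = 3, seed = 8)
merged
#> LayerSet: 3 raw layer(s), 3 merged layer(s)
#>   M1 <- raw {1}: 100 genes, k = 2
#>   M2 <- raw {2}: 98 genes, k = 2
#>   M3 <- raw {3}: 174 genes, k = 4

for (ly in c("adhesion", "immune", "molecular")) {
  best <- max(vapply(mergedLayers(merged), function(l)
    scorePartition(layerPartition(l), sim$truth, ly), numeric(1)))
  cat(sprintf("%-10s ARI vs planted truth: %.2f\n", ly, best))
}
#> adhesion   ARI vs planted truth: 1.00
#> immune     ARI vs planted truth: 1.00
#> molecular  ARI vs planted truth: 1.00
```

The pipeline found three layers: two 2-group layers (the planted
adhesion and immune factors, recovered exactly) and one 4-group layer
(the planted molecular factor). Survival by the discovered adhesion
groups, oriented so "low" is the group with lower adhesion-gene
expression:

```r
adh  <- mergedLayers(merged)$M1
grp  <- layerPartition(adh)[sim$clinical$sample_id]
act  <- colMeans(exprValues(expr)[layerGenes(adh), sim$clinical$sample_id])
low  <- names(which.min(tapply(act, grp, mean)))
oriented <- factor(ifelse(as.character(grp) == low, "low", "high"),
                   levels = c("high", "low"))
hazardRatio(sim$clinical$dfs_months, sim$clinical$relapse_event,
            oriented, reference = "high")
#> HR (low vs high) = 0.297, 95% CI (0.122-0.723); log-rank p = 0.008129
#>   Cox HR = 0.297, 95% CI (0.114-0.772)
```

Low-adhesion samples relapse less — the planted high-adhesion hazard
ratio of 2.4 is recovered as its reciprocal with a two-sided log-rank
p < 0.01. `runPipeline(config, outDir)` chains all of the above (plus the
graphical model, SAM tables, node-activity tests and cross-tabulations
against provided labels) into one reproducible run that writes TSV/JSON
artifacts and a manifest.

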