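# gepnet

Networks of coordinated gene expression programs from multi-sample
single-cell cohorts.

## The problem

In a cohort of single-cell RNA-seq samples (e.g. PBMCs from patients across
disease-activity groups and healthy controls), each major cell type carries
several **gene expression programs (GEPs)** — coordinated axes of expression
used to varying degrees by individual cells. How strongly each *sample*
expresses each program, and how programs in *different* cell types covary
across samples, is informative about system-level immune coordination:
hubs of co-regulated programs (such as a cross-cell-type type I interferon
module) can track clinical disease activity even when single-gene analyses
do not.

`gepnet` implements that analysis end to end:

1. **Program extraction per cell type.** Counts are restricted to the most
   overdispersed genes and cells scaled to 10,000; non-negative matrix
   factorization `X ≈ WH` (Frobenius objective, HALS updates) extracts
   loadings `W` (gene × k) and usages `H` (k × cell). The rank `k` is chosen
   by a *weighted-subtrees* stability metric: loading vectors pooled over
   random restarts are clustered on correlation distance, subtrees
   reproduced across ≥ 80% of restarts with mean intra-correlation ≥ 0.8
   count toward the metric, and `k` is the saturation point of the metric
   curve. The reported model is a consensus over restarts (median loadings
   per cluster, usages by non-negative least squares).
2. **Per-sample program scores and outlier filtering.** Score(s, p) = mean
   usage of program p over sample s's cells; programs dominated by a single
   sample (> 50% of score mass) or active in < 3 samples are removed.
3. **Program network.** Pairwise Pearson correlations of sample scores
   across all cell types; one-sided bootstrap p-values
   `(1 + #{r_b ≤ 0}) / (B + 1)`; edges kept when `r > 0` and `p < 0.05`;
   modules by seeded Louvain community detection; module gene-set themes by
   a permutation test on mean `−log10(FDR)` of per-program GSEA.
4. **Clinical association.** Cell type composition (Kruskal–Wallis + Dunn +
   Holm; Spearman vs the physician-global VAS, BH), per-program Welch
   t-tests (disease vs control), 4-group one-way ANOVA + Tukey across the
   activity ordering HC < Inactive < Active < TreatmentNaive, hierarchical
   gene-module derivation (Euclidean, complete linkage) with binned-control
   per-cell module scoring, and Spearman correlations with VAS.
5. **Signature transfer.** Top 5% marker genes per program (specificity
   z-score × loading) scored in an independent cohort by a per-cell
   rank-AUC (area under the gene-set recovery curve in the top-ranked
   genes), aggregated to pseudobulk means and validated by t-tests and
   Spearman vs VAS.
6. **Synthetic cohorts.** A generator plants loadings with anchor genes,
   sample-level program intensities from a Gaussian copula with module
   structure, Dirichlet per-cell usages, negative-binomial counts, a
   disease-activity covariate and a correlated ADT biomarker channel — with
   full ground truth for recovery and calibration studies.

## Worked example

```r
library(gepnet)

co <- simulate_cohort(synthetic_config(
  n_cell_types = 1, genes_per_type = 1000, programs_per_type = 5,
  cells_per_sample_per_type = 100, usage_concentration = 2,
  activity_effect = 0, seed = 3
))
X   <- prepare_matrix(co$counts$CT1, n_top_genes = 1000)
sel <- select_rank(X, k_grid = 2:8, n_restarts = 5, seed = 3)
print(sel)
#> Weighted-subtrees rank selection
#>  k metric
#>  2  0.000
#>  3  1.701
#>  4  3.999
#>  5  5.000
#>  6  4.460
#>  7  4.502
#>  8  5.270
#> chosen k: 5 ( 5 restarts )

fit <- consensus_gep(X, sel$chosen_k, n_restarts = 4, seed = 3,
                     cell_type = "CT1")
print(fit)
#> GEP model (NMF, consensus)
#>   cell type: CT1
#>   rank k: 5  genes: 967  cells: 2700
#>   objective: 2.59121e+09 after 1 sweeps
```

The metric climbs while added ranks are reproducible across restarts and
saturates at the planted rank 5, which `select_rank` picks; the consensus
model's five loading columns match the planted programs (mean matched
cosine 0.999 on this cohort). Downstream, `sample_program_scores()` +
`correlate_programs()` + `build_network()` + `detect_modules()` produce the
program network, `program_activity_anova()` and
`score_activity_correlation()` test disease association, and
`proxy_scores()` transfers signatures. `run_pipeline()` chains everything
from an on-disk cohort (MTX + TSV + CSV fixtures) to TSV result tables plus
a reproducibility manifest.

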