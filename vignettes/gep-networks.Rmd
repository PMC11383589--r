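---
title: "Gene expression program networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene expression program networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gepnet)
```

This vignette documents the models behind `gepnet`, the parameters that
matter, the synthetic cohorts the package tests itself on, and the places
where the design was genuinely open and a choice had to be committed.

## The factorization model

For one cell type, the raw gene-by-cell count matrix is reduced to the
most overdispersed genes (default 2,000, ranked by a variance-to-mean
dispersion z-scored within 20 mean-expression bins) and each cell scaled to
a total of 10,000. Raw-count NMF is otherwise dominated by library size;
per-cell scaling is the standard remedy and is recorded in the prepared
matrix's metadata. The scaled matrix `X` (genes × cells) is factorized as

`X ≈ W H`,  `W ≥ 0` (genes × k), `H ≥ 0` (k × cells),

minimizing the Frobenius reconstruction error. We use hierarchical
alternating least squares (HALS): each program column of `W`, then each
usage row of `H`, is updated by exact non-negative coordinate minimization.
Each sweep is therefore non-increasing in the objective, which the model
records (`objective_trace`) and the tests assert. The Frobenius objective
(rather than a Poisson/KL likelihood) was chosen because the quantities the
pipeline consumes — loadings, per-sample mean usages — are judged by
recovery, not likelihood, and the Frobenius HALS iteration is fast and
monotone. On return, columns of `W` are normalized to sum to one with `H`
rescaled compensatingly, so loadings are comparable across programs and
cell types.

Tunable parameters: `max_iter` (default 200 sweeps), `tol` (relative
objective change, default 1e-5), and the seed of the uniform random
initialization. Degenerate inputs are rejected (`NaN`, `k > min(dim)`);
a program column whose denominator collapses is simply left in place
(a "dead" program), which the consensus step then ignores.

## Rank selection by weighted subtrees

The rank `k` is the one free parameter NMF cannot set itself. We select it
by reproducibility across restarts: for each candidate `k`, `n_restarts`
(default 5) seeded fits are run with a *stability-scan* iteration budget
(60 sweeps, `tol` 1e-4) and all `k × n_restarts` loading vectors pooled.
An average-linkage tree on correlation distance (1 − Pearson) is cut into
its *maximal qualifying subtrees*: subtrees whose members span at least
`⌈0.8 · n_restarts⌉` distinct restarts and whose mean pairwise correlation
is at least 0.8. The metric for `k` is the sum of those subtrees' mean
intra-correlations — effectively "how many programs are reproducibly found,
weighted by how cleanly". Both thresholds are exposed as parameters.

As `k` grows the metric rises roughly one unit per genuinely distinct
program and then saturates; we choose the **saturation point**, the last
grid point whose relative gain over its predecessor is at least 5%
(`saturation_gain`). If the curve never stops gaining, the argmax is taken;
a one-point grid returns that point. The default grid 5–20 comfortably
covers the 11–17 range where per-cell-type ranks tend to land on
PBMC-scale data.

The shortened iteration budget during the scan is deliberate: it is the
*stability* of a rank that is being measured, not the converged optimum,
and under-converged over-complete factorizations reveal their
initialization dependence — exactly the signal the metric needs.

## Consensus model

At the chosen rank, `n_restarts` full fits are clustered with the same tree
machinery (`cutree` into `k` groups); each group's median loading
(renormalized) becomes a consensus column of `W`, and `H ≥ 0` is re-solved
against `X` by exact non-negative coordinate descent (the same routine
backs `predict()` for new cells). If clustering cannot produce `k` usable
groups, the best-objective single restart is returned with
`fallback = TRUE`. The tests require the consensus objective to stay within
5% of the best restart.

## From programs to a network

Per-sample program scores are the mean usage over a sample's cells
(samples under `min_cells = 10` cells are dropped with a warning). Programs
whose score mass is concentrated in one sample (share > 0.5) or active in
fewer than 3 samples are filtered as artifacts before network construction.

Edges are Pearson correlations of sample scores over the samples common to
a pair (at least 5), kept when `r > 0` and the one-sided bootstrap p-value
`(1 + #{r_b ≤ 0})/(B + 1)` (B ≥ 100, default 1,000 resamples of samples
with replacement) is below `alpha = 0.05` — the network is by construction
a positive-correlation graph. Degenerate bootstrap resamples (zero
variance) are counted as non-positive, which is conservative. Modules are
seeded Louvain communities on the r-weighted graph; module ids are
relabeled contiguously by decreasing size.

Module themes are tested by permutation: the statistic for module `M` and
gene set `g` is the mean over `M`'s programs of `−log10(max(FDR, 1e-10))`
from per-program GSEA, compared with `n_perm` random node subsets of size
`|M|`; BH across sets within module. The `1e-10` floor prevents infinities
and caps any single program's influence.

## Enrichment machinery

Preranked GSEA uses the classic running-sum enrichment score with hit
increments proportional to `|score|^w` (default `w = 1`) and uniform miss
decrements; on exact ± ties of the extrema the positive deviation is
reported. Significance comes from gene-label permutations; the p-value is
the tail fraction among same-sign null scores (never doubled — doubling
breaks null uniformity, which the calibration tests check), and NES is ES
over the mean same-sign |null ES|. FDR control is BH on those empirical
p-values within each program rather than the classic NES-binned scheme:
simpler, and well calibrated at the permutation counts used here. The
significance flag marks positive enrichment only; depleted sets keep their
p-values but are not flagged. Permutation p-values are floored at
`1/(n_perm + 1)`, so with the default FDR cutoff of 0.01 at least 1,000
permutations are needed for any set to be flaggable — the defaults are
chosen to satisfy that.

## Clinical statistics

All tests are thin, labeled wrappers over the standard machinery:
Kruskal–Wallis across the HC/Inactive/TreatmentNaive groups with Dunn's
post hoc z-tests (hand-computed with tie correction, Holm-adjusted within
cell type), Spearman of composition vs VAS BH-adjusted across cell types —
the two adjustment families are kept separate and labeled, because they are
genuinely different families. Case–control tests are Welch's t (group sizes
are unequal, so the unequal-variance form is the safe reading of "unpaired
t test"); disease-activity tests are 4-group one-way ANOVA with Tukey HSD.
Longitudinal samples from the same donor are treated as independent, as in
the source analyses; a donor-collapse step can be applied upstream by
averaging a donor's samples before testing, but no mixed model is fitted.

Gene modules are derived from genes differentially expressed in at least
two cell types (DE lists are *inputs*; the package does not fit DE models),
clustered on the row-standardized gene × (sample, cell type) average
log-expression matrix with Euclidean distance and complete linkage, and cut
into `n_modules` (default 7 — a reported, not derived, quantity, hence a
parameter). Per-cell module scores use expression-matched controls: genes
are binned into 24 bins by mean expression and 100 controls per set gene
are drawn from the gene's bin; when a bin is no larger than `n_ctrl` the
whole bin is used once each, which makes the degenerate one-bin
configuration exactly `mean(set) − mean(all genes)`.

## Proxy transfer

A program's identity travels as its top 5% marker genes (specificity
z-score × within-program loading, ties broken by gene id). In a target
cohort each cell is scored by the rank-AUC: genes ranked by descending
expression (ties by gene id), and the area under the set's recovery curve
within the top 5% of ranks, normalized by the best achievable area. Only
ranks enter, so raw counts are a valid input and the score is invariant to
any strictly monotone transform (asserted in tests). Pseudobulk means per
sample then feed the same Welch/Spearman validation statistics. The 5%
ranking window is a package default, logged with the scores, not an
externally fixed constant.

## The synthetic cohort generator

The generator is the package's study instrument, and its defaults define
the simulated study: 27 samples in four groups (5 HC / 6 inactive /
7 active / 9 treatment-naive), six cell types, five programs per cell type,
100 cells per sample per type, library size 2,000, negative-binomial
dispersion 0.5, planted modules spanning cell types, a designated activity
module shifted by `d = 2` latent standard deviations per group step, and an
ADT channel affine in the activity module's intensity. Sample-level program
intensities come from a Gaussian copula (intra-module correlation `ρ`, zero
across modules) pushed through `softplus(1 + z)`, which is near-linear in
the occupied range, so planted latent correlations survive to the intensity
scale within Monte-Carlo error. Per-cell usages are Dirichlet around the
sample mixture; counts are gene-wise negative binomial (Poisson at zero
dispersion). The disease-activity VAS is the rank of an *independent*
latent shifted by `d` per group step, mapped to 0–10, so at `d = 0` the VAS
carries no information about the modules.

Three generative choices deserve emphasis, because they define what
"identifiable planted programs" means here:

* **Anchors with flat backgrounds.** Each program carries five high-weight
  anchor genes (half the column mass) on a disjoint support, and a *flat*
  background weight over a random half of the remaining genes.
  Heterogeneous background weights would give over-complete factorizations
  a preferred, initialization-independent way to split programs, making
  extra factors spuriously reproducible; a flat background leaves program
  identity to the anchors and support, and splitting directionless.
* **Moderately pure cells.** The benchmark regime uses Dirichlet
  concentration 2 (cohort default 5). Thoroughly mixed cells put every
  profile deep inside the program simplex, where secondary mixture
  archetypes become stable pseudo-programs.
* **No clinical confound in the factorization benchmark.** The
  rank-selection and recovery studies run at `d = 0`: a strong group shift
  creates sample-level archetypes that act as extra reproducible factors.
  Disease-association studies use the cohort defaults with `d = 2`.

What the generator does **not** emulate: droplet artifacts (doublets,
ambient RNA), batch effects, donor-level repeated measures, gene-gene
correlation beyond the planted programs, or realistic marker-gene biology.
Passing recovery tests on these cohorts therefore demonstrates the
*algorithmic* correctness and calibration of the pipeline under its own
assumptions, not performance on any real data set.

## Study sizes and numerical conventions

The packaged studies use: ten benchmark cohorts (1,000 genes × 6,000
cells) for recovery and rank selection with grids 2–10 and 5 restarts;
500 independent pairs at 1,000 bootstraps for edge calibration; 200
replicates for each permutation-calibration check; and ten cohorts each
for filtering, disease-association and transfer studies. These sizes give
stable Monte-Carlo behavior at desk scale; all of them are parameters of
the corresponding functions, not limits of the method.

Determinism: every stochastic step takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage sub-seeds from one
global seed by a fixed offset table, so single stages can be rerun
reproducibly. Ties are broken lexicographically by gene or program id
throughout. Output tables are TSV with 12 significant digits.

## Known limitations

* HALS can park programs at zero ("dead" columns) at ranks far above the
  data's complexity; the consensus step's fallback covers the pathological
  case but the rank grid should start well below the expected rank.
* The weighted-subtrees thresholds (0.8/0.8/5%) are committed
  interpretations of a method whose exact constants are not published;
  they are parameters, and the saturation read-out is the last point of
  material gain rather than the first point without one — on planted data
  the latter systematically overshoots by one.
* Bootstrap edge p-values are one-sided for positive association by
  design; anticorrelation is never represented in the network.
* Module-enrichment permutations treat programs as exchangeable across
  cell types; if cell types differed grossly in GSEA signal strength the
  null would be optimistic for modules dominated by the strong cell type.
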