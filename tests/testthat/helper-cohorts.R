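# Shared study configurations and small data builders.

# Low-noise factorization benchmark: one cell type, 1,000 genes, K = 5
# planted programs, 30 samples x 200 cells, moderately pure cells and no
# disease-activity shift (pure factorization problem).
bench_config <- function(seed, ...) {
  synthetic_config(
    n_samples = 30L,
    group_sizes = c(HC = 7L, Inactive = 7L, Active = 8L, TreatmentNaive = 8L),
    n_cell_types = 1L, genes_per_type = 1000L, programs_per_type = 5L,
    cells_per_sample_per_type = 200L, usage_concentration = 2,
    activity_effect = 0, seed = seed, ...
  )
}

# Small, fast cohort for IO / pipeline plumbing tests.
small_cohort <- function(seed = 1L, n_cell_types = 2L) {
  simulate_cohort(synthetic_config(
    n_cell_types = n_cell_types, genes_per_type = 120L,
    programs_per_type = 3L, cells_per_sample_per_type = 15L,
    usage_concentration = 2, seed = seed
  ))
}

# Mean matched cosine between planted and fitted loadings.
matched_cosine <- function(true_W, fit) {
  S <- gepnet:::cosine_columns(true_W[rownames(fit$W), , drop = FALSE], fit$W)
  a <- gepnet:::match_columns(S)$assignment
  mean(S[cbind(seq_len(nrow(S)), a)])
}

# samples x programs score matrix built from the generator's per-cell true
# usages (independent of any NMF fit).
true_sample_scores <- function(cohort, cell_type = "CT1") {
  H <- cohort$truth$true_cell_usage[[cell_type]]
  meta <- cohort$cell_metadata
  sample_of <- meta$sample_id[match(colnames(H), meta$barcode)]
  samples <- sort(unique(sample_of))
  sc <- t(vapply(samples, function(s) {
    rowMeans(H[, sample_of == s, drop = FALSE])
  }, numeric(nrow(H))))
  colnames(sc) <- gepnet:::program_id(cell_type, seq_len(nrow(H)))
  rownames(sc) <- samples
  sc
}
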