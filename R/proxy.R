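#' Rank-AUC proxy score of a gene set per cell
#'
#' Scores each cell for a program's top-marker gene set by the area under
#' the set's recovery curve within the cell's top-ranked genes: genes are
#' ranked by descending expression (ties broken by ascending gene id, i.e.
#' row order after sorting rows by id), the recovery curve counts set genes
#' among the first `ceiling(top_fraction * n_genes)` ranks, and the AUC is
#' normalized by its maximum (all set genes at the very top).  Because only
#' ranks enter, the score is invariant to any strictly monotone transform
#' of a cell's expression values, so raw counts are a valid input.
#'
#' @param expression gene x cell matrix (raw counts or any monotone
#'   transform thereof), with gene ids as row names.
#' @param gene_set character vector; its intersection with the matrix rows
#'   must be nonempty.
#' @param top_fraction fraction of the ranking used as the scoring window,
#'   in (0, 1).
#' @return named numeric vector of per-cell AUCs in `[0, 1]`.
#' @export
rank_auc_score <- function(expression, gene_set, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)")
  }
  ord_rows <- order(rownames(expression))
  X <- as_dense(expression[ord_rows, , drop = FALSE])
  in_set <- rownames(X) %in% gene_set
  if (!any(in_set)) stop("gene set absent from matrix")
  n <- nrow(X)
  m <- sum(in_set)
  n_top <- ceiling(top_fraction * n)
  max_area <- sum(n_top - seq_len(min(m, n_top)) + 1)
  auc <- vapply(seq_len(ncol(X)), function(c) {
    ord <- order(-X[, c], seq_len(n))
    pos <- which(in_set[ord])
    sum(pmax(n_top - pos + 1, 0)) / max_area
  }, numeric(1))
  stats::setNames(auc, colnames(X))
}

#' Pseudobulk aggregation of per-cell scores
#'
#' Arithmetic mean of per-cell scores over the cells of each sample.
#'
#' @param cell_scores named vector (one program) or cells x programs matrix
#'   of per-cell scores, names/rownames being cell barcodes.
#' @param cell_metadata data.frame with `barcode` and `sample_id`.
#' @return samples x programs matrix; attributes `n_cells` (per sample) and
#'   `low_n` (samples with a single cell).
#' @export
pseudobulk <- function(cell_scores, cell_metadata) {
  if (is.null(dim(cell_scores))) {
    cell_scores <- matrix(cell_scores, ncol = 1,
                          dimnames = list(names(cell_scores), "score"))
  }
  idx <- match(rownames(cell_scores), cell_metadata$barcode)
  if (anyNA(idx)) {
    stop("unknown sample for cell ",
         rownames(cell_scores)[which(is.na(idx))[1]])
  }
  sample_of <- cell_metadata$sample_id[idx]
  samples <- sort(unique(sample_of))
  res <- vapply(samples, function(s) {
    colMeans(cell_scores[sample_of == s, , drop = FALSE])
  }, numeric(ncol(cell_scores)))
  out <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  dimnames(out) <- list(samples, colnames(cell_scores))
  n_cells <- as.integer(table(sample_of)[samples])
  attr(out, "n_cells") <- stats::setNames(n_cells, samples)
  low <- samples[n_cells == 1]
  if (length(low) > 0) {
    attr(out, "low_n") <- low
    message("pseudobulk: single-cell samples: ",
            paste(low, collapse = ", "))
  }
  out
}

#' Proxy-score signature transfer to a cohort
#'
#' Applies a trained model's top-marker gene sets to a (possibly
#' independent) cohort: per-cell rank-AUC scores for every program, then
#' per-sample pseudobulk means.
#'
#' @param markers `marker_table` of the trained model, or a precomputed
#'   named list of top-marker gene sets.
#' @param counts gene x cell count matrix of the target cohort.
#' @param cell_metadata metadata of the target cohort.
#' @param marker_fraction fraction of genes taken as top markers.
#' @param top_fraction ranking window for the AUC.
#' @return list with `cell_auc` (cells x programs), `sample_scores`
#'   (samples x programs), `gene_sets` used.
#' @export
proxy_scores <- function(markers, counts, cell_metadata,
                         marker_fraction = 0.05, top_fraction = 0.05) {
  gene_sets <- if (inherits(markers, "marker_table")) {
    top_markers(markers, fraction = marker_fraction)
  } else {
    markers
  }
  cell_auc <- vapply(gene_sets, function(gs) {
    rank_auc_score(counts, gs, top_fraction = top_fraction)
  }, numeric(ncol(counts)))
  rownames(cell_auc) <- colnames(counts)
  sample_scores <- pseudobulk(cell_auc, cell_metadata)
  list(cell_auc = cell_auc, sample_scores = sample_scores,
       gene_sets = gene_sets)
}

#' Validation statistics for transferred proxy scores
#'
#' Per program: Welch's two-tailed t-test of pseudobulk proxy scores in
#' disease versus healthy-control samples, and the Spearman correlation of
#' the scores with the disease-activity VAS; BH adjustment within each
#' family of tests.
#'
#' @param sample_scores samples x programs pseudobulk proxy scores.
#' @param clinical data.frame with `sample_id`, `group`, `vas_global`.
#' @return data.frame combining the `case_control` and
#'   `transfer_vas` families.
#' @export
transfer_validation <- function(sample_scores, clinical) {
  cc <- program_case_control(sample_scores, clinical)
  sp <- score_activity_correlation(sample_scores, clinical,
                                   family = "transfer_vas")
  cc$flag <- NULL
  sp$flag <- NULL
  rbind(cc, sp)
}
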