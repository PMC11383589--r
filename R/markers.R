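#' Marker gene scores for a program model
#'
#' Scores how specifically each gene marks each program.  With
#' column-normalized loadings `W`, the marker score of gene `g` in program
#' `p` is the z-score of `W[g, p]` across that gene's `k` program loadings
#' (its cross-program specificity) multiplied by the gene's within-program
#' normalized loading `W[g, p]` (its contribution to the program).  Genes
#' are ranked per program by descending score with ties broken by gene id.
#' At `k = 1` specificity is undefined; the raw normalized loadings are
#' returned and the result is flagged.
#'
#' @param model a `gep_nmf` model.
#' @return object of class `marker_table`: list with matrices `score` and
#'   `rank` (genes x programs), `cell_type`, and flag `specificity_defined`.
#' @export
marker_scores <- function(model) {
  stopifnot(inherits(model, "gep_nmf"))
  W <- model$W
  s <- colSums(W)
  W <- sweep(W, 2, ifelse(s > 0, s, 1), "/")
  if (model$k == 1) {
    score <- W
    flag <- FALSE
  } else {
    mu <- rowMeans(W)
    sd <- apply(W, 1, stats::sd)
    z <- (W - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    score <- z * W
    flag <- TRUE
  }
  rank_mat <- apply(score, 2, function(x) {
    ord <- order(-x, rownames(W))
    r <- integer(length(x))
    r[ord] <- seq_along(x)
    r
  })
  dimnames(rank_mat) <- dimnames(score)
  structure(list(score = score, rank = rank_mat,
                 cell_type = model$cell_type,
                 specificity_defined = flag),
            class = "marker_table")
}

#' @export
print.marker_table <- function(x, n_top = 5L, ...) {
  cat("Marker table:", nrow(x$score), "genes x", ncol(x$score), "programs\n")
  for (j in seq_len(min(ncol(x$score), 8))) {
    top <- rownames(x$score)[order(x$rank[, j])[seq_len(n_top)]]
    cat(sprintf("  %s: %s\n", colnames(x$score)[j],
                paste(top, collapse = ", ")))
  }
  invisible(x)
}

#' Per-sample program scores
#'
#' Averages each program's per-cell usage over the cells of each sample.
#' Samples contributing fewer than `min_cells` cells of this cell type are
#' dropped with a warning.
#'
#' @param model a `gep_nmf` model whose `H` columns are cell barcodes.
#' @param cell_metadata data.frame with columns `barcode` and `sample_id`
#'   covering every cell in the model.
#' @param min_cells minimum cells per sample.
#' @return samples x programs matrix (program columns named
#'   `<cell_type>_<j>` when the model carries a cell type, else `p<j>`);
#'   attribute `n_cells` gives cells per retained sample.
#' @export
sample_program_scores <- function(model, cell_metadata, min_cells = 10L) {
  H <- model$H
  idx <- match(colnames(H), cell_metadata$barcode)
  if (anyNA(idx)) {
    stop("cells missing from metadata, e.g. ",
         colnames(H)[which(is.na(idx))[1]])
  }
  sample_of <- cell_metadata$sample_id[idx]
  counts <- table(sample_of)
  keep <- names(counts)[counts >= min_cells]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped) > 0) {
    warning("dropping samples with < ", min_cells, " cells: ",
            paste(dropped, collapse = ", "))
  }
  scores <- t(vapply(keep, function(s) {
    rowMeans(H[, sample_of == s, drop = FALSE])
  }, numeric(nrow(H))))
  colnames(scores) <- if (!is.null(model$cell_type)) {
    program_id(model$cell_type, seq_len(model$k))
  } else {
    rownames(H)
  }
  rownames(scores) <- keep
  attr(scores, "n_cells") <- as.integer(counts[keep])
  scores
}

#' Filter outlier programs
#'
#' Drops programs whose per-sample score mass is dominated by a single
#' sample (share above `max_sample_share`) or that are active (score above
#' 10% of the program's maximum) in fewer than `min_active_samples`
#' samples.  Such programs typically reflect sample-specific artifacts
#' rather than shared biology, and are removed before network construction.
#'
#' @param scores samples x programs matrix from [sample_program_scores()]
#'   (or several cell types' matrices combined with [combine_scores()]).
#' @param max_sample_share maximal tolerated single-sample share of a
#'   program's total score mass.
#' @param min_active_samples minimal number of active samples.
#' @return list with `retained` (program ids) and `report` (data.frame with
#'   per-program share, active-sample count and the rule that fired).
#' @export
filter_outlier_programs <- function(scores, max_sample_share = 0.5,
                                    min_active_samples = 3L) {
  stopifnot(ncol(scores) >= 1)
  progs <- colnames(scores)
  share <- apply(scores, 2, function(x) {
    tot <- sum(x)
    if (tot <= 0) 1 else max(x) / tot
  })
  n_active <- apply(scores, 2, function(x) sum(x > 0.1 * max(x, 0)))
  rule <- rep("retained", length(progs))
  rule[n_active < min_active_samples] <- "too_few_active_samples"
  rule[share > max_sample_share] <- "single_sample_dominated"
  retained <- progs[rule == "retained"]
  if (length(retained) == 0) warning("all programs filtered out")
  list(retained = retained,
       report = data.frame(program = progs, max_share = share,
                           n_active = n_active, rule = rule,
                           row.names = NULL))
}

#' Combine per-cell-type sample score matrices
#'
#' Aligns several samples x programs matrices on the union of their sample
#' ids; samples absent from a cell type get `NA` for its programs.
#'
#' @param score_list named or unnamed list of matrices from
#'   [sample_program_scores()].
#' @return combined samples x programs matrix.
#' @export
combine_scores <- function(score_list) {
  samples <- sort(unique(unlist(lapply(score_list, rownames))))
  out <- do.call(cbind, lapply(score_list, function(s) {
    m <- matrix(NA_real_, length(samples), ncol(s),
                dimnames = list(samples, colnames(s)))
    m[rownames(s), ] <- s
    m
  }))
  out
}

#' Top marker genes of a program
#'
#' Returns the `ceiling(fraction * n_genes)` genes with the highest marker
#' score in the requested program, ties broken by gene id (the
#' lexicographically smaller id wins at the cutoff).
#'
#' @param markers a `marker_table` from [marker_scores()].
#' @param fraction fraction of genes to keep, in (0, 1].
#' @param program program column (index or name); `NULL` returns a named
#'   list over all programs.
#' @return character vector of gene ids (or list of them).
#' @export
top_markers <- function(markers, fraction = 0.05, program = NULL) {
  stopifnot(inherits(markers, "marker_table"))
  if (nrow(markers$score) == 0) stop("empty marker table")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  pick <- function(j) {
    x <- markers$score[, j]
    n <- ceiling(fraction * length(x))
    names(sort_by_score(x))[seq_len(n)]
  }
  if (is.null(program)) {
    out <- lapply(seq_len(ncol(markers$score)), pick)
    names(out) <- colnames(markers$score)
    out
  } else {
    pick(program)
  }
}

# Descending by score, ties by ascending gene id.
sort_by_score <- function(x) x[order(-x, names(x))]
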