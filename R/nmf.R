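#' Prepare a count matrix for program extraction
#'
#' Restricts a gene-by-cell count matrix to the most overdispersed genes and
#' rescales every cell to a fixed total of 10,000, the scale on which NMF is
#' run.  Overdispersion is ranked by a binned variance-to-mean residual: the
#' per-gene dispersion (variance/mean on cell-scaled data) is z-scored within
#' 20 mean-expression bins, so selection is not dominated by expression
#' level.  Ties are broken by row order, making the selection deterministic.
#'
#' @param counts gene-by-cell matrix of nonnegative counts (dense or
#'   `Matrix` sparse), with gene ids as row names.
#' @param n_top_genes number of genes to keep; capped at the number of genes
#'   with any expression.
#' @return gene-by-cell matrix of the selected genes with each cell summing
#'   to 10,000 (cells with no counts on the selected genes stay zero); the
#'   selected gene ids are attached as attribute `gene_subset`.
#' @export
prepare_matrix <- function(counts, n_top_genes = 2000L) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  }
  totals <- Matrix::colSums(counts)
  if (sum(totals) == 0) stop("count matrix is all zero")
  ## per-cell scaling (all genes) for the dispersion statistics
  sf <- ifelse(totals > 0, 10000 / totals, 0)
  Xs <- counts %*% Matrix::Diagonal(x = sf)
  mu <- Matrix::rowMeans(Xs)
  ex2 <- Matrix::rowMeans(Xs^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(counts) / max(ncol(counts) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  expressed <- which(mu > 0)
  n_top_genes <- min(n_top_genes, length(expressed))
  ## bin by mean expression, z-score dispersion within bin
  nb <- min(20L, length(expressed))
  bin <- ceiling(rank(mu[expressed], ties.method = "first") *
                   nb / length(expressed))
  z <- numeric(length(expressed))
  for (b in unique(bin)) {
    i <- which(bin == b)
    m <- mean(disp[expressed][i])
    s <- stats::sd(disp[expressed][i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[expressed][i] - m) / s
  }
  ord <- expressed[order(-z, expressed)]
  keep <- sort(ord[seq_len(n_top_genes)])
  X <- counts[keep, , drop = FALSE]
  totals_sub <- Matrix::colSums(X)
  sf_sub <- ifelse(totals_sub > 0, 10000 / totals_sub, 0)
  X <- X %*% Matrix::Diagonal(x = sf_sub)
  colnames(X) <- colnames(counts)
  structure(X, gene_subset = rownames(counts)[keep])
}

#' Fit a gene expression program model by NMF
#'
#' Factorizes a nonnegative gene-by-cell matrix `X` into loadings `W`
#' (gene x k) and usages `H` (k x cell) minimizing the Frobenius
#' reconstruction error, using hierarchical alternating least squares
#' (exact nonnegative coordinate descent per program), from a seeded random
#' nonnegative initialization.  The objective is recorded after every sweep
#' and is non-increasing.  On return `W` columns are renormalized to sum to
#' one with `H` rescaled compensatingly, so `W %*% H` is unchanged.
#'
#' @param X nonnegative matrix (dense or sparse); typically from
#'   [prepare_matrix()].
#' @param k rank (number of programs), `1 <= k <= min(dim(X))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective change below which iteration stops.
#' @param cell_type optional label stored on the model.
#' @return an object of class `gep_nmf`: list with `W`, `H`, `k`,
#'   `objective_trace`, `cell_type`, `gene_subset`, `seed`, `iterations`,
#'   `converged`.
#' @export
gep_nmf <- function(X, k, seed = 1L, max_iter = 200L, tol = 1e-5,
                    cell_type = NULL) {
  if (anyNA(if (inherits(X, "Matrix")) X@x else X)) stop("NaN/NA in X")
  if (k < 1 || k > min(dim(X))) stop("k must be in 1..min(dim(X))")
  gene_subset <- attr(X, "gene_subset")
  if (is.null(gene_subset)) gene_subset <- rownames(X)
  g <- nrow(X)
  n <- ncol(X)
  normX2 <- if (inherits(X, "Matrix")) sum(X@x^2) else sum(X^2)
  with_seed(seed, {
    scale0 <- sqrt(sum(X) / length(X) / k)
    W <- matrix(stats::runif(g * k), g, k) * scale0
    H <- matrix(stats::runif(k * n), k, n) * scale0
  })
  trace <- numeric(0)
  prev <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    ## W update
    HHt <- tcrossprod(H)
    XHt <- as_dense(Matrix::tcrossprod(X, H))
    for (j in seq_len(k)) {
      d <- HHt[j, j]
      if (d <= .Machine$double.eps) next
      W[, j] <- pmax(W[, j] + (XHt[, j] - W %*% HHt[, j]) / d, 0)
    }
    ## H update
    WtW <- crossprod(W)
    WtX <- as_dense(Matrix::crossprod(W, X))
    for (j in seq_len(k)) {
      d <- WtW[j, j]
      if (d <= .Machine$double.eps) next
      H[j, ] <- pmax(H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / d, 0)
    }
    obj <- normX2 - 2 * sum(WtX * H) + sum(crossprod(W) * tcrossprod(H))
    obj <- max(obj, 0)
    trace <- c(trace, obj)
    if (is.finite(prev) && prev > 0 && (prev - obj) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  model <- finalize_gep(W, H, k, trace, cell_type, gene_subset,
                        seed = seed, iterations = it, converged = converged)
  model
}

finalize_gep <- function(W, H, k, trace, cell_type, gene_subset, ...) {
  s <- colSums(W)
  pos <- s > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2, s[pos], "/")
  H[pos, ] <- H[pos, , drop = FALSE] * s[pos]
  colnames(W) <- paste0("p", seq_len(k))
  rownames(H) <- colnames(W)
  if (!is.null(gene_subset)) rownames(W) <- gene_subset
  model <- c(list(W = W, H = H, k = k, objective_trace = trace,
                  cell_type = cell_type, gene_subset = gene_subset),
             list(...))
  class(model) <- "gep_nmf"
  model
}

#' @export
print.gep_nmf <- function(x, ...) {
  cat("GEP model (NMF", if (isTRUE(x$consensus)) ", consensus" else "",
      ")\n", sep = "")
  if (!is.null(x$cell_type)) cat("  cell type:", x$cell_type, "\n")
  cat("  rank k:", x$k, " genes:", nrow(x$W), " cells:", ncol(x$H), "\n")
  if (length(x$objective_trace)) {
    cat("  objective:", format(utils::tail(x$objective_trace, 1), digits = 6),
        "after", length(x$objective_trace), "sweeps\n")
  }
  invisible(x)
}

#' @export
summary.gep_nmf <- function(object, n_top = 5L, ...) {
  cat("Top-loading genes per program:\n")
  for (j in seq_len(object$k)) {
    top <- utils::head(order(-object$W[, j]), n_top)
    cat(sprintf("  p%d: %s\n", j,
                paste(rownames(object$W)[top], collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.gep_nmf <- function(object, ...) object$W

#' @export
fitted.gep_nmf <- function(object, ...) object$W %*% object$H

#' Usages for new cells under a fitted program model
#'
#' Solves nonnegative least squares for the usage of each column of
#' `newdata` against the model's loadings, holding `W` fixed.
#'
#' @param object a `gep_nmf` model.
#' @param newdata gene-by-cell matrix over the model's gene subset.
#' @param ... unused.
#' @return k-by-cell usage matrix.
#' @export
predict.gep_nmf <- function(object, newdata, ...) {
  solve_usage(newdata, object$W)
}

# Nonnegative least squares for H given fixed W, by exact coordinate
# descent (HALS restricted to H); deterministic.
solve_usage <- function(X, W, max_iter = 1000L, tol = 1e-13) {
  k <- ncol(W)
  WtW <- crossprod(W)
  WtX <- as_dense(Matrix::crossprod(W, X))
  H <- matrix(0, k, ncol(X))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      d <- WtW[j, j]
      if (d <= .Machine$double.eps) next
      H[j, ] <- pmax(H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / d, 0)
    }
    obj <- sum(WtW * tcrossprod(H)) - 2 * sum(WtX * H)
    if (is.finite(prev) && abs(prev - obj) <= tol * max(abs(prev), 1)) break
    prev <- obj
  }
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(X)
  H
}
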