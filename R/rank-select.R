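#' Stability-based NMF rank selection by weighted subtrees
#'
#' For every rank in `k_grid`, runs `n_restarts` seeded NMF fits, pools all
#' `k * n_restarts` loading vectors, and builds an average-linkage tree on
#' correlation distance (1 - Pearson between loadings).  The stability
#' metric for a rank is the summed "weight" (mean intra-subtree Pearson
#' correlation) of the maximal subtrees whose members come from at least
#' `ceiling(0.8 * n_restarts)` distinct restarts and have mean intra-subtree
#' correlation of at least 0.8 — i.e. programs reproduced across restarts.
#' The chosen rank is the saturation point of the metric curve: the last
#' grid point before the relative gain over the previous grid point falls
#' below `saturation_gain`; if the metric keeps gaining over the whole grid
#' the argmax is taken.
#'
#' @param X nonnegative matrix from [prepare_matrix()].
#' @param k_grid increasing ranks to scan.  The default grid spans well past
#'   the 11-17 range where per-cell-type ranks typically land on PBMC-scale
#'   data.
#' @param n_restarts NMF restarts per rank (>= 3).
#' @param seed integer seed; restart `r` at grid entry `i` uses
#'   `seed + 100 * i + r`.
#' @param min_restart_frac fraction of restarts a subtree must span.
#' @param min_correlation mean intra-subtree Pearson threshold.
#' @param saturation_gain relative-gain threshold defining saturation.
#' @param max_iter,tol passed to [gep_nmf()].
#' @return object of class `gep_rank_selection`: list with `k_grid`,
#'   `metric`, `chosen_k`, `restarts`.
#' @export
select_rank <- function(X, k_grid = 5:20, n_restarts = 5L, seed = 1L,
                        min_restart_frac = 0.8, min_correlation = 0.8,
                        saturation_gain = 0.05,
                        max_iter = 60L, tol = 1e-4) {
  if (length(k_grid) == 0) stop("k_grid must be nonempty")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be ascending")
  if (n_restarts < 3 && length(k_grid) > 1) stop("need n_restarts >= 3")
  metric <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    loadings <- list()
    restart_of <- integer(0)
    for (r in seq_len(n_restarts)) {
      fit <- gep_nmf(X, k, seed = seed + 100L * i + r,
                     max_iter = max_iter, tol = tol)
      loadings[[r]] <- fit$W
      restart_of <- c(restart_of, rep(r, k))
    }
    pool <- do.call(cbind, loadings)
    metric[i] <- weighted_subtrees_metric(pool, restart_of,
                                          min_restart_frac * n_restarts,
                                          min_correlation)
  }
  chosen_k <- saturation_point(k_grid, metric, saturation_gain)
  structure(list(k_grid = k_grid, metric = metric, chosen_k = chosen_k,
                 restarts = n_restarts),
            class = "gep_rank_selection")
}

#' @export
print.gep_rank_selection <- function(x, ...) {
  cat("Weighted-subtrees rank selection\n")
  print(data.frame(k = x$k_grid, metric = round(x$metric, 3)),
        row.names = FALSE)
  cat("chosen k:", x$chosen_k, "(", x$restarts, "restarts )\n")
  invisible(x)
}

# Sum of mean intra-correlations over maximal qualifying subtrees of the
# average-linkage tree on 1 - cor(pool).
weighted_subtrees_metric <- function(pool, restart_of, min_restarts,
                                     min_correlation) {
  m <- ncol(pool)
  if (m < 2) return(0)
  C <- suppressWarnings(stats::cor(pool))
  C[is.na(C)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  n_nodes <- nrow(hc$merge)
  leaves <- vector("list", n_nodes)
  meancor <- numeric(n_nodes)
  qualifies <- logical(n_nodes)
  for (v in seq_len(n_nodes)) {
    kids <- hc$merge[v, ]
    lv <- unlist(lapply(kids, function(x) {
      if (x < 0) -x else leaves[[x]]
    }))
    leaves[[v]] <- lv
    np <- length(lv) * (length(lv) - 1) / 2
    meancor[v] <- (sum(C[lv, lv]) - length(lv)) / 2 / np
    qualifies[v] <- length(unique(restart_of[lv])) >= min_restarts &&
      meancor[v] >= min_correlation
  }
  # maximal = qualifying with no qualifying ancestor: walk down from the root
  total <- 0
  stack <- n_nodes
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (qualifies[v]) {
      total <- total + meancor[v]
    } else {
      kids <- hc$merge[v, ]
      stack <- c(stack, kids[kids > 0])
    }
  }
  total
}

# Saturation point: last k gaining at least `gain` relative to the previous
# grid point; argmax if the curve never saturates.
saturation_point <- function(k_grid, metric, gain) {
  if (length(k_grid) == 1) return(k_grid[1])
  rel <- diff(metric) / pmax(abs(metric[-length(metric)]),
                             .Machine$double.eps)
  below <- which(rel < gain)
  if (length(below) == 0) return(k_grid[which.max(metric)])
  # rel[i] is the gain realized at k_grid[i + 1]; the saturation point is
  # the last grid point that still gained, i.e. k_grid[below[1]]
  k_grid[below[1]]
}

#' Consensus program model over NMF restarts
#'
#' Runs `n_restarts` seeded NMF fits at a fixed rank, clusters the pooled
#' loading vectors into `k` groups with the same average-linkage correlation
#' tree used for rank selection, takes each group's (renormalized) median
#' loading as the consensus `W`, and solves the usages `H >= 0` by
#' nonnegative least squares against `X`.  If clustering fails to produce
#' `k` usable groups the best-objective single restart is returned, flagged
#' via `fallback = TRUE`.
#'
#' @inheritParams select_rank
#' @param k rank, typically `chosen_k` from [select_rank()].
#' @param cell_type optional label stored on the model.
#' @return a `gep_nmf` object with `consensus = TRUE`.
#' @export
consensus_gep <- function(X, k, n_restarts = 5L, seed = 1L,
                          max_iter = 150L, tol = 1e-5, cell_type = NULL) {
  fits <- lapply(seq_len(n_restarts), function(r) {
    gep_nmf(X, k, seed = seed + r, max_iter = max_iter, tol = tol,
            cell_type = cell_type)
  })
  if (n_restarts == 1) return(fits[[1]])
  pool <- do.call(cbind, lapply(fits, function(f) f$W))
  C <- suppressWarnings(stats::cor(pool))
  C[is.na(C)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  grp <- stats::cutree(hc, k = k)
  objs <- vapply(fits, function(f) utils::tail(f$objective_trace, 1),
                 numeric(1))
  if (length(unique(grp)) < k) {
    best <- fits[[which.min(objs)]]
    best$consensus <- TRUE
    best$fallback <- TRUE
    return(best)
  }
  W <- vapply(seq_len(k), function(g) {
    members <- pool[, grp == g, drop = FALSE]
    w <- apply(members, 1, stats::median)
    if (sum(w) > 0) w / sum(w) else w
  }, numeric(nrow(pool)))
  H <- solve_usage(X, W)
  gene_subset <- attr(X, "gene_subset")
  if (is.null(gene_subset)) gene_subset <- rownames(X)
  normX2 <- if (inherits(X, "Matrix")) sum(X@x^2) else sum(X^2)
  obj <- normX2 - 2 * sum(as_dense(Matrix::crossprod(W, X)) * H) +
    sum(crossprod(W) * tcrossprod(H))
  model <- finalize_gep(W, H, k, trace = obj,
                        cell_type = cell_type, gene_subset = gene_subset,
                        seed = seed, consensus = TRUE, fallback = FALSE,
                        restart_objectives = objs, objective = obj)
  model
}
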