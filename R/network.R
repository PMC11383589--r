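#' Pairwise program correlations with bootstrap significance
#'
#' Computes the Pearson correlation between every pair of program score
#' columns over their common samples, with a one-sided bootstrap p-value for
#' positive association: samples are resampled with replacement `n_boot`
#' times and `p = (1 + #{r_b <= 0}) / (n_boot + 1)`.  Pairs with fewer than
#' `min_common` common samples, or with a constant column, are marked
#' missing (`NA`).
#'
#' @param scores samples x programs matrix (combined across cell types with
#'   [combine_scores()]); `NA` entries mark samples absent from a cell type.
#' @param n_boot bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param min_common minimal number of common samples for a pair.
#' @return object of class `edge_stats`: list of matrices `r`, `p`, `n`.
#' @export
correlate_programs <- function(scores, n_boot = 1000L, seed = 1L,
                               min_common = 5L) {
  if (n_boot < 100) stop("need n_boot >= 100")
  P <- ncol(scores)
  ids <- colnames(scores)
  r <- p <- matrix(NA_real_, P, P, dimnames = list(ids, ids))
  n <- matrix(0L, P, P, dimnames = list(ids, ids))
  diag(r) <- 1
  with_seed(seed, {
    for (i in seq_len(P - 1)) {
      for (j in (i + 1):P) {
        ok <- which(!is.na(scores[, i]) & !is.na(scores[, j]))
        n[i, j] <- n[j, i] <- length(ok)
        if (length(ok) < min_common) next
        x <- scores[ok, i]
        y <- scores[ok, j]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r[i, j] <- r[j, i] <- stats::cor(x, y)
        rb <- bootstrap_cor(x, y, n_boot)
        pv <- (1 + sum(rb <= 0 | is.na(rb))) / (n_boot + 1)
        p[i, j] <- p[j, i] <- pv
      }
    }
  })
  structure(list(r = r, p = p, n = n, n_boot = n_boot),
            class = "edge_stats")
}

# Vectorized bootstrap of the Pearson correlation; degenerate resamples
# (zero variance) come back NA.
bootstrap_cor <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
  X <- matrix(x[idx], n)
  Y <- matrix(y[idx], n)
  sx <- colSums(X); sy <- colSums(Y)
  sxx <- colSums(X^2); syy <- colSums(Y^2); sxy <- colSums(X * Y)
  num <- n * sxy - sx * sy
  den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Build the program correlation network
#'
#' Keeps edges with positive correlation (`r > 0`) significant at `alpha`
#' (`p < alpha`), over the nodes of the score matrix.  Isolated nodes are
#' retained and flagged.  A seeded force-directed layout is attached for
#' plotting only.
#'
#' @param edge_stats from [correlate_programs()].
#' @param alpha significance level for edges.
#' @param seed seed for the layout.
#' @return object of class `program_network`: list with `graph` (igraph),
#'   `nodes` (data.frame: node, cell_type, program, isolated), `edges`
#'   (data.frame: from, to, r, p), `module_of` (NA until
#'   [detect_modules()] is run) and `layout`.
#' @export
build_network <- function(edge_stats, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(edge_stats, "edge_stats"))
  ids <- colnames(edge_stats$r)
  P <- length(ids)
  ut <- which(upper.tri(edge_stats$r), arr.ind = TRUE)
  keep <- !is.na(edge_stats$r[ut]) & !is.na(edge_stats$p[ut]) &
    edge_stats$r[ut] > 0 & edge_stats$p[ut] < alpha
  edges <- data.frame(
    from = ids[ut[keep, 1]], to = ids[ut[keep, 2]],
    r = edge_stats$r[ut][keep], p = edge_stats$p[ut][keep],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  igraph::E(g)$weight <- edges$r
  parts <- split_program_ids(ids)
  nodes <- data.frame(node = ids, cell_type = parts$cell_type,
                      program = parts$program,
                      isolated = igraph::degree(g) == 0,
                      stringsAsFactors = FALSE)
  layout <- with_seed(stage_seed(seed, "layout"), {
    igraph::layout_with_fr(g)
  })
  rownames(layout) <- ids
  structure(list(graph = g, nodes = nodes, edges = edges,
                 module_of = stats::setNames(rep(NA_integer_, P), ids),
                 layout = layout, alpha = alpha),
            class = "program_network")
}

split_program_ids <- function(ids) {
  cell_type <- sub("_[^_]*$", "", ids)
  program <- sub("^.*_", "", ids)
  list(cell_type = cell_type, program = program)
}

#' @export
print.program_network <- function(x, ...) {
  cat("Program network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (r > 0, p <", x$alpha, ")\n")
  if (!all(is.na(x$module_of))) {
    tab <- table(x$module_of)
    cat("  modules:", length(tab), "(sizes:",
        paste(as.integer(tab), collapse = ", "), ")\n")
  }
  if (any(x$nodes$isolated)) {
    cat("  isolated nodes:", sum(x$nodes$isolated), "\n")
  }
  invisible(x)
}

#' @export
plot.program_network <- function(x, ...) {
  col <- if (all(is.na(x$module_of))) "grey60" else x$module_of
  igraph::plot.igraph(x$graph, layout = x$layout,
                      vertex.color = col, vertex.size = 6,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Detect program modules by community detection
#'
#' Runs seeded modularity optimization (Louvain) on the r-weighted positive
#' graph.  Singleton components each get their own module.  Module ids are
#' contiguous from 1, ordered by decreasing size (ties by first node).
#'
#' @param network a `program_network`.
#' @param seed integer seed.
#' @return the network with `module_of` filled in.
#' @export
detect_modules <- function(network, seed = 1L) {
  stopifnot(inherits(network, "program_network"))
  g <- network$graph
  if (igraph::ecount(g) == 0) {
    warning("edgeless network: every node is its own module")
    membership <- seq_len(igraph::vcount(g))
  } else {
    comm <- with_seed(stage_seed(seed, "modules"), {
      igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    })
    membership <- igraph::membership(comm)
  }
  # relabel contiguously by decreasing module size (ties: first node index)
  sizes <- table(membership)
  first <- tapply(seq_along(membership), membership, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  network$module_of <- stats::setNames(
    as.integer(relabel[as.character(membership)]),
    network$nodes$node
  )
  network
}

#' Export a program network
#'
#' Writes the network as GraphML (with module and layout attributes) and as
#' an edge-list TSV (`node_a`, `node_b`, `r`, `p`, `module_a`, `module_b`).
#'
#' @param network a `program_network`.
#' @param graphml,edges output paths; either may be `NULL` to skip.
#' @return invisibly, the written paths.
#' @export
write_network <- function(network, graphml = NULL, edges = NULL) {
  stopifnot(inherits(network, "program_network"))
  written <- character(0)
  if (!is.null(graphml)) {
    g <- network$graph
    igraph::V(g)$module <- unname(network$module_of[igraph::V(g)$name])
    igraph::V(g)$x <- network$layout[igraph::V(g)$name, 1]
    igraph::V(g)$y <- network$layout[igraph::V(g)$name, 2]
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edges)) {
    tab <- data.frame(
      node_a = network$edges$from, node_b = network$edges$to,
      r = network$edges$r, p = network$edges$p,
      module_a = unname(network$module_of[network$edges$from]),
      module_b = unname(network$module_of[network$edges$to])
    )
    utils::write.table(tab, edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edges)
  }
  invisible(written)
}

#' Module gene-set enrichment by network permutation
#'
#' Tests whether a gene set's program-level enrichment concentrates in a
#' module.  The statistic for module `M` and set `g` is the mean over the
#' module's programs of `-log10(max(FDR, 1e-10))`, where the FDRs come from
#' per-program GSEA ([batch_gsea()]).  The null draws `n_perm` random node
#' subsets of size `|M|` from the whole network;
#' `p = (1 + #{T_perm >= T_obs}) / (n_perm + 1)`, BH-adjusted across gene
#' sets within each module.  Modules of size 1 are computed but flagged
#' low-power.
#'
#' @param network a `program_network` with modules assigned.
#' @param gsea_table data.frame with columns `program`, `set`, `fdr` (from
#'   [batch_gsea()]).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param fdr_floor floor applied to FDRs before the log transform.
#' @return data.frame: module, set, statistic, p, p_adj, low_power.
#' @export
module_enrichment <- function(network, gsea_table, n_perm = 1000L, seed = 1L,
                              fdr_floor = 1e-10) {
  stopifnot(inherits(network, "program_network"))
  if (all(is.na(network$module_of))) stop("run detect_modules() first")
  nodes <- network$nodes$node
  sets <- sort(unique(gsea_table$set))
  # node x set matrix of -log10 FDR
  S <- matrix(0, length(nodes), length(sets),
              dimnames = list(nodes, sets))
  idx <- cbind(match(gsea_table$program, nodes),
               match(gsea_table$set, sets))
  ok <- stats::complete.cases(idx)
  S[idx[ok, , drop = FALSE]] <- -log10(pmax(gsea_table$fdr[ok], fdr_floor))
  modules <- sort(unique(network$module_of))
  out <- list()
  with_seed(seed, {
    for (m in modules) {
      members <- names(network$module_of)[network$module_of == m]
      sz <- length(members)
      t_obs <- colMeans(S[members, , drop = FALSE])
      t_perm <- matrix(0, n_perm, length(sets))
      for (b in seq_len(n_perm)) {
        sub <- sample(nodes, sz)
        t_perm[b, ] <- colMeans(S[sub, , drop = FALSE])
      }
      pv <- (1 + colSums(t_perm >= rep(t_obs, each = n_perm))) / (n_perm + 1)
      out[[length(out) + 1]] <- data.frame(
        module = m, set = sets, statistic = t_obs, p = pv,
        p_adj = stats::p.adjust(pv, "BH"), low_power = sz == 1,
        row.names = NULL
      )
    }
  })
  do.call(rbind, out)
}

#' Gene loading similarity between programs of two models
#'
#' Pearson correlation of two programs' gene loadings over the shared gene
#' subset, with a permutation p-value obtained by permuting one vector's
#' gene labels: `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param model_a,model_b `gep_nmf` models (may be the same model).
#' @param pairs data.frame with columns `program_a`, `program_b` (indices or
#'   column names); `NULL` tests all cross pairs.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param min_shared minimal shared-gene count (refuses below).
#' @return data.frame: program_a, program_b, n_genes, r, p.
#' @export
loading_similarity <- function(model_a, model_b, pairs = NULL,
                               n_perm = 999L, seed = 1L, min_shared = 100L) {
  shared <- intersect(rownames(model_a$W), rownames(model_b$W))
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " shared genes between the two models; ",
         "need >= ", min_shared,
         " for a meaningful loading correlation")
  }
  A <- model_a$W[shared, , drop = FALSE]
  B <- model_b$W[shared, , drop = FALSE]
  if (is.null(pairs)) {
    pairs <- expand.grid(program_a = seq_len(ncol(A)),
                         program_b = seq_len(ncol(B)))
  }
  with_seed(seed, {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- A[, pairs$program_a[i]]
      b <- B[, pairs$program_b[i]]
      r_obs <- stats::cor(a, b)
      r_perm <- vapply(seq_len(n_perm), function(s) {
        stats::cor(a[sample.int(length(a))], b)
      }, numeric(1))
      data.frame(program_a = pairs$program_a[i],
                 program_b = pairs$program_b[i],
                 n_genes = length(shared), r = r_obs,
                 p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1))
    })
  })
  do.call(rbind, res)
}

#' Fisher's exact test for top-gene overlap between two programs
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 table of membership
#' of two programs' top-gene sets over a stated gene universe.
#'
#' @param top_genes_a,top_genes_b character vectors, subsets of `universe`.
#' @param universe gene universe (e.g. intersection of the two models' gene
#'   subsets).
#' @return list with `odds_ratio`, `p`, `overlap`, `table`.
#' @export
gene_overlap_fisher <- function(top_genes_a, top_genes_b, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(top_genes_a %in% universe) || !all(top_genes_b %in% universe)) {
    stop("top gene sets must be subsets of the universe")
  }
  a <- unique(top_genes_a)
  b <- unique(top_genes_b)
  k <- length(intersect(a, b))
  tab <- matrix(c(k, length(a) - k,
                  length(b) - k,
                  length(universe) - length(a) - length(b) + k), 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, overlap = k,
       table = tab)
}
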