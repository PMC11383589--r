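make_edge_stats <- function(r, p, n = 30L) {
  ids <- colnames(r)
  nm <- matrix(n, nrow(r), ncol(r), dimnames = dimnames(r))
  structure(list(r = r, p = p, n = nm, n_boot = 1000L),
            class = "edge_stats")
}

test_that("correlation matrix has unit diagonal and symmetric entries", {
  set.seed(1)
  s <- matrix(rnorm(30 * 3), 30,
              dimnames = list(sprintf("S%02d", 1:30),
                              c("CT1_1", "CT1_2", "CT2_1")))
  s <- abs(s)
  es <- correlate_programs(s, n_boot = 200, seed = 1)
  expect_equal(diag(es$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(es$r, t(es$r))
  expect_equal(es$r["CT1_1", "CT1_2"], cor(s[, 1], s[, 2]),
               tolerance = 1e-12)
  expect_true(all(es$p[upper.tri(es$p)] > 0 & es$p[upper.tri(es$p)] <= 1))
})

test_that("anticorrelated pairs get high bootstrap p and no edge", {
  x <- seq_len(30) + 0
  s <- cbind(a = x, b = -x + 31, c = x + rnorm(30, 0, 1e-3))
  rownames(s) <- sprintf("S%02d", 1:30)
  es <- correlate_programs(s, n_boot = 500, seed = 2)
  expect_equal(es$r["a", "b"], -1, tolerance = 1e-12)
  expect_gt(es$p["a", "b"], 0.99)
  net <- build_network(es, alpha = 0.05, seed = 1)
  expect_false(any(net$edges$from == "a" & net$edges$to == "b"))
  expect_true(any(net$edges$from == "a" & net$edges$to == "c"))
})

test_that("constant and sparse-overlap pairs are marked missing", {
  s <- cbind(a = rep(1, 10), b = rnorm(10), c = c(rnorm(3), rep(NA, 7)))
  rownames(s) <- sprintf("S%02d", 1:10)
  es <- correlate_programs(s, n_boot = 100, seed = 1)
  expect_true(is.na(es$r["a", "b"]))   # constant column
  expect_true(is.na(es$r["b", "c"]))   # < 5 common samples
  expect_identical(es$n["b", "c"], 3L)
})

test_that("edges require positivity and significance exactly", {
  ids <- c("A_1", "A_2", "A_3")
  r <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3,
              dimnames = list(ids, ids))
  p <- matrix(c(NA, 0.01, 0.001, 0.01, NA, 0.2, 0.001, 0.2, NA), 3,
              dimnames = list(ids, ids))
  net <- build_network(make_edge_stats(r, p), alpha = 0.05, seed = 1)
  expect_equal(nrow(net$edges), 1)          # only A_1 - A_2 passes both gates
  expect_setequal(c(net$edges$from, net$edges$to), c("A_1", "A_2"))
  expect_true(net$nodes$isolated[net$nodes$node == "A_3"])
})

test_that("module detection separates disjoint cliques and handles degenerates", {
  ids <- paste0("CT1_", 1:8)
  r <- diag(8)
  p <- matrix(1, 8, 8)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    r[i, j] <- 0.9; p[i, j] <- 0.001
    r[i + 4, j + 4] <- 0.9; p[i + 4, j + 4] <- 0.001
  }
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  net <- detect_modules(build_network(make_edge_stats(r, p), seed = 1),
                        seed = 1)
  expect_identical(unname(net$module_of[1:4]), rep(1L, 4))
  expect_identical(unname(net$module_of[5:8]), rep(2L, 4))

  # single node, no edges
  r1 <- matrix(1, 1, 1, dimnames = list("X_1", "X_1"))
  p1 <- matrix(NA_real_, 1, 1, dimnames = list("X_1", "X_1"))
  net1 <- build_network(make_edge_stats(r1, p1), seed = 1)
  expect_warning(net1 <- detect_modules(net1, seed = 1), "edgeless")
  expect_identical(unname(net1$module_of), 1L)
})

test_that("module detection is deterministic given the seed", {
  set.seed(9)
  P <- 9
  truemod <- rep(1:3, each = 3)
  Sig <- outer(truemod, truemod, function(a, b) ifelse(a == b, 0.7, 0))
  diag(Sig) <- 1
  Z <- matrix(rnorm(40 * P), 40) %*% chol(Sig)
  colnames(Z) <- paste0("CT", truemod, "_", 1:P)
  rownames(Z) <- sprintf("S%02d", 1:40)
  s <- gepnet:::softplus(1 + Z)
  es <- correlate_programs(s, n_boot = 200, seed = 4)
  n1 <- detect_modules(build_network(es, seed = 4), seed = 4)
  n2 <- detect_modules(build_network(es, seed = 4), seed = 4)
  expect_identical(n1$module_of, n2$module_of)
})

test_that("networks export to GraphML and an annotated edge list", {
  ids <- paste0("CT1_", 1:4)
  r <- diag(4); p <- matrix(1, 4, 4)
  r[1, 2] <- r[2, 1] <- 0.9; p[1, 2] <- p[2, 1] <- 0.001
  r[3, 4] <- r[4, 3] <- 0.8; p[3, 4] <- p[4, 3] <- 0.01
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  net <- detect_modules(build_network(make_edge_stats(r, p), seed = 1),
                        seed = 1)
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  tsv <- file.path(dir, "edges.tsv")
  write_network(net, graphml = gml, edges = tsv)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_identical(sort(igraph::V(g2)$name), sort(ids))
  expect_equal(igraph::ecount(g2), 2)
  tab <- utils::read.delim(tsv)
  expect_identical(names(tab),
                   c("node_a", "node_b", "r", "p", "module_a", "module_b"))
  expect_equal(nrow(tab), 2)
})

test_that("module enrichment p-values behave at the extremes", {
  ids <- paste0("CT1_", 1:30)
  r <- diag(30); p <- matrix(1, 30, 30)
  r[1, 2] <- r[2, 1] <- 0.9; p[1, 2] <- p[2, 1] <- 0.001
  dimnames(r) <- dimnames(p) <- list(ids, ids)
  net <- build_network(make_edge_stats(r, p), seed = 1)
  net$module_of[] <- c(rep(1L, 5), rep(2L, 25))

  # extreme case: the set hits exactly module 1's five programs; the only
  # permutation subsets reaching the observed statistic are exact redraws
  # of the module, which are vanishingly rare among C(30, 5) subsets, so
  # the p-value sits at the permutation floor 1/(n_perm + 1)
  gt <- data.frame(program = ids, set = "S1",
                   fdr = c(rep(1e-10, 5), rep(1, 25)))
  me <- module_enrichment(net, gt, n_perm = 999, seed = 1)
  expect_equal(me$p[me$module == 1], 1 / 1000, tolerance = 1e-12)

  # identical FDR everywhere: degenerate null, p = 1
  gt2 <- data.frame(program = ids, set = "S1", fdr = rep(0.2, 30))
  me2 <- module_enrichment(net, gt2, n_perm = 99, seed = 1)
  expect_equal(me2$p, rep(1, nrow(me2)))
})

test_that("loading similarity is exact on identical vectors and refuses tiny overlap", {
  set.seed(3)
  W <- matrix(abs(rnorm(150)), 150, 1,
              dimnames = list(sprintf("g%03d", 1:150), "p1"))
  m <- list(W = W)
  res <- loading_similarity(m, m, n_perm = 999, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 1000)

  # oracle equivalence of the correlation itself
  W2 <- matrix(abs(rnorm(150)), 150, 1,
               dimnames = list(sprintf("g%03d", 1:150), "p1"))
  res2 <- loading_similarity(m, list(W = W2), n_perm = 99, seed = 1)
  expect_equal(res2$r, cor(W[, 1], W2[, 1]), tolerance = 1e-12)

  small <- list(W = W[1:50, , drop = FALSE])
  expect_error(loading_similarity(small, small), "shared genes")
})

test_that("Fisher overlap p equals direct hypergeometric summation", {
  universe <- sprintf("g%04d", 1:1000)
  a <- universe[1:50]
  expect_equal(gene_overlap_fisher(a, a, universe)$p,
               brute_hyper_tail(50, 50, 1000, 50), tolerance = 1e-12)
  b <- universe[51:100]
  expect_gte(gene_overlap_fisher(a, b, universe)$p, 0.5)
  # the (10, 5, 5, 80) table
  u2 <- sprintf("u%03d", 1:100)
  x <- u2[1:15]
  y <- u2[c(1:10, 16:20)]
  expect_equal(gene_overlap_fisher(x, y, u2)$p,
               brute_hyper_tail(10, 15, 100, 15), tolerance = 1e-12)
  expect_error(gene_overlap_fisher(a, b, character(0)), "empty")
})
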