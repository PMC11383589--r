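write_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT parsing handles toy files, warnings and error paths", {
  p <- write_gmt(c("SET_A\tdesc\tTP53\tmyc\tBRCA1",
                   "SET_B\tdesc\tCD19"))
  expect_warning(gs <- read_gmt(p), "fewer than")
  expect_length(gs$sets, 2)
  expect_setequal(gs$sets$SET_A, c("TP53", "MYC", "BRCA1"))
  expect_identical(gs$sets$SET_B, "CD19")

  expect_error(read_gmt(write_gmt(c("A\td\tG1\tG2", "A\td\tG3\tG4"))),
               "duplicate")
  expect_error(read_gmt(write_gmt("JUSTNAME\tdesc")), "line 1")
  expect_error(read_gmt("/nonexistent/file.gmt"), "no such file")
})

test_that("the enrichment score matches brute-force running sums exactly", {
  # spec-style toy: 10 genes, set = the top 3
  scores <- setNames(seq(10, 1), paste0("G", sprintf("%02d", 1:10)))
  res <- preranked_gsea(scores, names(scores)[1:3], n_perm = 99, seed = 1)
  expect_equal(res$ES, brute_es(unname(scores), 1:3), tolerance = 1e-12)
  expect_setequal(res$leading_edge, names(scores)[1:3])

  # exhaustive: every subset of an 8-gene ranking
  set.seed(4)
  sc8 <- setNames(sort(rnorm(8), decreasing = TRUE), paste0("H", 1:8))
  for (mask in 1:254) {
    hit <- which(bitwAnd(mask, 2^(0:7)) > 0)
    res <- preranked_gsea(sc8, names(sc8)[hit], n_perm = 0, seed = 1)
    expect_equal(res$ES, brute_es(unname(sc8), hit), tolerance = 1e-12)
  }
})

test_that("degenerate sets are flagged with zero enrichment", {
  scores <- setNames(5:1, paste0("G", 1:5))
  all_set <- preranked_gsea(scores, names(scores), n_perm = 9, seed = 1)
  expect_identical(all_set$flag, "degenerate_all_genes")
  expect_identical(all_set$ES, 0)
  none <- preranked_gsea(scores, c("X1", "X2"), n_perm = 9, seed = 1)
  expect_identical(none$flag, "empty_intersection")
  expect_identical(none$p, 1)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(1)
  ps <- replicate(300, {
    r <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    preranked_gsea(r, sample(names(r), 15), n_perm = 199,
                   seed = sample.int(1e6, 1))$p
  })
  expect_true(all(ps > 0))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("enrichment agrees with fgsea on sign and significance", {
  skip_if_not_installed("fgsea")
  set.seed(2)
  r <- setNames(sort(rnorm(200, sd = 2), decreasing = TRUE),
                sprintf("g%03d", 1:200))
  strong <- names(r)[1:15]
  ours <- preranked_gsea(r, strong, n_perm = 500, seed = 3)
  ref <- suppressWarnings(
    fgsea::fgsea(list(S = strong), r, nperm = 500)
  )
  expect_gt(ours$ES, 0.8)
  expect_equal(sign(ours$ES), sign(ref$ES))
  expect_lt(ours$p, 0.01)
  expect_lt(ref$pval, 0.01)
})

test_that("batch GSEA applies BH within program and flags planted sets", {
  # single set: FDR equals p
  set.seed(5)
  rank1 <- list(pA = setNames(rnorm(50), sprintf("g%03d", 1:50)))
  coll <- structure(list(
    sets = list(ONE = sprintf("G%03d", 1:8)),
    description = c(ONE = "")
  ), class = "gene_set_collection")
  names(coll$sets$ONE) <- NULL
  coll$sets$ONE <- toupper(sprintf("g%03d", 1:8))
  tab <- batch_gsea(rank1, coll, n_perm = 99, seed = 1)
  expect_equal(tab$fdr, tab$p)

  # planted: anchor set of a program is significant for that program only
  co <- simulate_cohort(synthetic_config(
    n_cell_types = 1L, genes_per_type = 1000L, programs_per_type = 5L,
    cells_per_sample_per_type = 60L, usage_concentration = 2, seed = 7
  ))
  X <- prepare_matrix(co$counts$CT1, 1000)
  fit <- consensus_gep(X, 5, n_restarts = 4, seed = 7, cell_type = "CT1")
  mk <- marker_scores(fit)
  C <- cor(fit$W, co$truth$true_loadings$CT1[rownames(fit$W), ])
  mp <- apply(C, 2, which.max)   # planted j -> fitted column
  anch <- co$truth$anchor_genes$CT1
  coll2 <- structure(list(
    sets = setNames(lapply(anch, toupper), paste0("ANCH", 1:5)),
    description = setNames(rep("", 5), paste0("ANCH", 1:5))
  ), class = "gene_set_collection")
  res <- batch_gsea(mk, coll2, n_perm = 999, seed = 2)
  for (j in 1:5) {
    row <- res[res$program == paste0("p", mp[j]) &
                 res$set == paste0("ANCH", j), ]
    expect_true(row$significant)
    expect_gt(row$ES, 0.9)
  }
  off <- res[mapply(function(pr, st) {
    j <- as.integer(sub("ANCH", "", st))
    pr != paste0("p", mp[j])
  }, res$program, res$set), ]
  expect_gte(mean(!off$significant), 0.9)
})

test_that("hypergeometric overrepresentation matches its oracles", {
  universe <- sprintf("g%04d", 1:500)
  hits <- universe[1:20]
  gene_set <- universe[11:40]
  res <- ora_hypergeometric(hits, gene_set, universe)
  expect_equal(res$p, brute_hyper_tail(10, 30, 500, 20), tolerance = 1e-12)
  # equivalence with the one-sided Fisher test on the same table
  expect_equal(res$p, gene_overlap_fisher(hits, gene_set, universe)$p,
               tolerance = 1e-12)
  # hits identical to the set: minimal possible p
  res2 <- ora_hypergeometric(hits, hits, universe)
  expect_equal(res2$p, brute_hyper_tail(20, 20, 500, 20), tolerance = 1e-15)
  # overlap exactly at expectation: fold = 1
  res3 <- ora_hypergeometric(universe[1:50], universe[seq(1, 500, 10)],
                             universe)
  expect_equal(res3$fold, 1)
  expect_error(ora_hypergeometric(character(0), gene_set, universe),
               "empty hit list")
})
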