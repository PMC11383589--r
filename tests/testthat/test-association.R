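toy_clinical <- function(n = 27) {
  groups <- rep(c("HC", "Inactive", "Active", "TreatmentNaive"),
                c(5, 6, 7, 9))
  data.frame(sample_id = sprintf("S%02d", 1:n),
             donor_id = sprintf("D%02d", 1:n),
             group = groups[1:n],
             vas_global = seq(0, 10, length.out = n),
             on_medication = FALSE)
}

test_that("Kruskal-Wallis and Dunn statistics match rank-based oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  kw <- kruskal.test(x, factor(g))
  expect_equal(unname(kw$statistic), brute_kw(x, g), tolerance = 1e-10)
  expect_equal(brute_kw(x, g), 7.2, tolerance = 1e-10)

  dn <- gepnet:::dunn_test(x, g, list(c("C", "A"), c("C", "B"),
                                      c("B", "A")))
  # mean ranks 2, 5, 8; sd = sqrt((N(N+1)/12) * (2/3)) = sqrt(5)
  expect_equal(dn$z, c(6, 3, 3) / sqrt(5), tolerance = 1e-10)
  expect_equal(dn$p, 2 * pnorm(-abs(dn$z)), tolerance = 1e-12)
})

test_that("composition tests run the stated comparisons and adjustments", {
  clin <- toy_clinical()
  set.seed(2)
  counts <- matrix(rpois(27 * 3, 200), 27, 3,
                   dimnames = list(clin$sample_id, c("B", "T4", "NK")))
  res <- composition_test(counts, clin)
  expect_setequal(unique(res$family),
                  c("composition_kw", "composition_dunn", "composition_vas"))
  dunn <- res[res$family == "composition_dunn" & res$unit == "B", ]
  expect_equal(nrow(dunn), 3)
  expect_setequal(dunn$comparison,
                  c("TreatmentNaive vs HC", "TreatmentNaive vs Inactive",
                    "Inactive vs HC"))
  # Holm within cell type, BH across cell types for the VAS family
  expect_equal(dunn$p_adj, p.adjust(dunn$p, "holm"))
  vas <- res[res$family == "composition_vas", ]
  expect_equal(vas$p_adj, p.adjust(vas$p, "BH"))
  # compositional closure: proportions anticorrelate somewhere
  props <- counts / rowSums(counts)
  expect_lt(min(cor(props)), 0)
})

test_that("null compositions rarely reject", {
  clin <- toy_clinical()
  set.seed(3)
  rej <- replicate(500, {
    counts <- matrix(rpois(27 * 2, 300), 27, 2,
                     dimnames = list(clin$sample_id, c("A", "B")))
    res <- composition_test(counts, clin)
    res$p[res$family == "composition_kw" & res$unit == "A"] < 0.05
  })
  expect_gte(mean(!rej), 0.91)
})

test_that("Welch t-tests match the textbook formulas", {
  clin <- toy_clinical(8)
  clin$group <- rep(c("TreatmentNaive", "HC"), c(3, 5))
  sc <- matrix(c(2, 4, 6, 1, 3, 5, 2, 4), ncol = 1,
               dimnames = list(clin$sample_id, "CT1_1"))
  res <- program_case_control(sc, clin)
  oracle <- brute_welch(sc[1:3, 1], sc[4:8, 1])
  expect_equal(res$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)

  # degenerate equal-constant groups
  sc0 <- matrix(1, 8, 1, dimnames = list(clin$sample_id, "CT1_1"))
  res0 <- program_case_control(sc0, clin)
  expect_identical(res0$p, 1)
  expect_identical(res0$flag, "degenerate_zero_variance")
})

test_that("four-group ANOVA and Tukey match sum-of-squares oracles", {
  clin <- toy_clinical()
  set.seed(4)
  sc <- matrix(rnorm(27), ncol = 1, dimnames = list(clin$sample_id, "P"))
  res <- program_activity_anova(sc, clin)
  an <- res[res$family == "activity_anova", ]
  oracle <- brute_anova(sc[, 1], clin$group)
  expect_equal(an$statistic, oracle$f, tolerance = 1e-10)
  expect_equal(an$p, oracle$p, tolerance = 1e-10)
  tk <- res[res$family == "activity_tukey", ]
  expect_equal(nrow(tk), 6)
  row <- tk[tk$comparison == "TreatmentNaive-HC", ]
  expect_equal(row$p, brute_tukey_p(sc[, 1], clin$group,
                                    "TreatmentNaive", "HC"),
               tolerance = 1e-8)

  clin2 <- clin[clin$group != "Active", ]
  expect_error(program_activity_anova(sc[clin2$sample_id, , drop = FALSE],
                                      clin2), "Active")
})

test_that("a pure treatment-naive shift is flagged only for its pairs", {
  clin <- toy_clinical()
  shift <- ifelse(clin$group == "TreatmentNaive", 4, 0)
  set.seed(5)
  sc <- matrix(rnorm(27, sd = 0.5) + shift, ncol = 1,
               dimnames = list(clin$sample_id, "P"))
  res <- program_activity_anova(sc, clin)
  tk <- res[res$family == "activity_tukey", ]
  tn <- grepl("TreatmentNaive", tk$comparison)
  expect_true(all(tk$p[tn] < 0.05))
  expect_true(all(tk$p[!tn] > 0.05))
})

test_that("ANOVA p-values are uniform under the null", {
  clin <- toy_clinical()
  set.seed(6)
  ps <- replicate(500, {
    sc <- matrix(rnorm(27), ncol = 1, dimnames = list(clin$sample_id, "P"))
    res <- program_activity_anova(sc, clin)
    res$p[res$family == "activity_anova"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("gene modules come from genes shared by cell types, clustered", {
  # two orthogonal expression blocks are split exactly
  genes <- sprintf("g%02d", 1:10)
  de <- list(CT1 = genes, CT2 = genes[1:8], CT3 = "g10")
  avg <- rbind(
    matrix(rep(c(5, 0, 5, 0, 5, 0), each = 5), 5, byrow = FALSE),
    matrix(rep(c(0, 5, 0, 5, 0, 5), each = 5), 5, byrow = FALSE)
  )
  rownames(avg) <- genes
  colnames(avg) <- paste0("s", 1:6)
  mods <- derive_gene_modules(de, avg, n_modules = 2)
  expect_length(mods, 2)
  got <- lapply(mods, `[[`, "genes")
  expect_setequal(got[[1]], genes[1:5])
  # g09 is significant in only one cell type and must be excluded
  expect_setequal(got[[2]], c("g06", "g07", "g08", "g10"))
  expect_false("g09" %in% unlist(got))

  expect_error(derive_gene_modules(list(A = "g1", B = "g2"), avg), "fewer")
})

test_that("gene clustering agrees with a naive complete-linkage oracle", {
  set.seed(7)
  M <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  cl_pkg <- cutree(hclust(dist(M), method = "complete"), k = 4)
  cl_oracle <- brute_complete_linkage(M, 4)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl_pkg, cl_oracle))), 4)
})

test_that("module scores are centered, zero on zero input and exact when degenerate", {
  set.seed(8)
  E <- as.matrix(lognormalize(matrix(rpois(500 * 200, 5), 500, 200,
                              dimnames = list(sprintf("g%03d", 1:500),
                                              sprintf("c%03d", 1:200)))))
  sc <- module_score(E, sample(rownames(E), 30), seed = 1)
  expect_lt(abs(mean(sc)), 0.01)

  E0 <- matrix(0, 10, 5, dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
  expect_equal(unname(module_score(E0, c("g1", "g2"), seed = 1)), rep(0, 5))

  # n_bins = 1 with the full gene pool as controls
  gs <- rownames(E)[1:20]
  direct <- colMeans(E[gs, ]) - colMeans(as.matrix(E))
  expect_equal(module_score(E, gs, n_bins = 1, n_ctrl = nrow(E), seed = 1),
               direct, tolerance = 1e-12)

  expect_error(module_score(E, c("nope1", "nope2")), "absent")
})

test_that("activity correlations recover identity and flag degenerates", {
  clin <- toy_clinical()
  sc <- cbind(ident = clin$vas_global, const = rep(1, 27))
  rownames(sc) <- clin$sample_id
  res <- score_activity_correlation(sc, clin)
  expect_equal(res$statistic[res$unit == "ident"], 1, tolerance = 1e-12)
  expect_identical(res$flag[res$unit == "const"], "constant_scores")

  set.seed(9)
  null_rho <- replicate(200, {
    s <- matrix(rnorm(27), ncol = 1, dimnames = list(clin$sample_id, "x"))
    score_activity_correlation(s, clin)$statistic
  })
  expect_gte(mean(abs(null_rho) < 0.4), 0.95)
})
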