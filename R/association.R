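#' Cell type composition tests
#'
#' Per cell type, computes per-sample cell type proportions and tests them
#' across the healthy-control, inactive and treatment-naive groups with a
#' Kruskal-Wallis test followed by Dunn's post hoc z-tests for the three
#' pairs (TreatmentNaive vs HC, TreatmentNaive vs Inactive, Inactive vs HC),
#' Holm-adjusted within cell type.  Separately, the Spearman correlation of
#' each cell type's proportion with the disease-activity VAS is computed
#' over all samples, BH-adjusted across cell types.
#'
#' @param cell_counts samples x cell types matrix of cell counts (see
#'   [count_cells()]).
#' @param clinical data.frame with `sample_id`, `group`, `vas_global`.
#' @return data.frame with columns unit, family, test, comparison,
#'   statistic, p, p_adj, direction.
#' @export
composition_test <- function(cell_counts, clinical) {
  props <- cell_counts / rowSums(cell_counts)
  grp <- clinical$group[match(rownames(props), clinical$sample_id)]
  vas <- clinical$vas_global[match(rownames(props), clinical$sample_id)]
  tested_groups <- c("HC", "Inactive", "TreatmentNaive")
  pairs <- list(c("TreatmentNaive", "HC"),
                c("TreatmentNaive", "Inactive"),
                c("Inactive", "HC"))
  out <- list()
  for (ct in colnames(props)) {
    x <- props[, ct]
    in_test <- grp %in% tested_groups
    sizes <- table(factor(grp[in_test], levels = tested_groups))
    if (any(sizes < 2)) {
      message("composition_test: skipping ", ct,
              " (group with < 2 samples)")
      next
    }
    kw <- stats::kruskal.test(x[in_test], factor(grp[in_test]))
    out[[length(out) + 1]] <- data.frame(
      unit = ct, family = "composition_kw", test = "kruskal-wallis",
      comparison = paste(tested_groups, collapse = "|"),
      statistic = unname(kw$statistic), p = kw$p.value,
      p_adj = NA_real_, direction = NA_character_
    )
    dn <- dunn_test(x[in_test], grp[in_test], pairs)
    dn$p_adj <- stats::p.adjust(dn$p, "holm")
    out[[length(out) + 1]] <- data.frame(
      unit = ct, family = "composition_dunn", test = "dunn",
      comparison = dn$comparison, statistic = dn$z, p = dn$p,
      p_adj = dn$p_adj,
      direction = ifelse(dn$z > 0, "up", "down")
    )
  }
  sp <- lapply(colnames(props), function(ct) {
    ok <- !is.na(vas)
    ct_test <- suppressWarnings(
      stats::cor.test(props[ok, ct], vas[ok], method = "spearman",
                      exact = FALSE)
    )
    data.frame(
      unit = ct, family = "composition_vas", test = "spearman",
      comparison = "proportion~vas_global",
      statistic = unname(ct_test$estimate), p = ct_test$p.value,
      p_adj = NA_real_,
      direction = ifelse(ct_test$estimate > 0, "up", "down")
    )
  })
  sp <- do.call(rbind, sp)
  sp$p_adj <- stats::p.adjust(sp$p, "BH")
  res <- rbind(do.call(rbind, out), sp)
  rownames(res) <- NULL
  res
}

# Dunn's post hoc z-tests on shared ranks with tie correction.
dunn_test <- function(x, g, pairs) {
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12
  res <- lapply(pairs, function(pr) {
    i <- g == pr[1]
    j <- g == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((v0 - tie_term) * (1 / sum(i) + 1 / sum(j)))
    data.frame(comparison = paste(pr, collapse = " vs "), z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, res)
}

#' Count cells per sample and cell type
#'
#' @param cell_metadata data.frame with `sample_id` and `cell_type`.
#' @return samples x cell types integer matrix.
#' @export
count_cells <- function(cell_metadata) {
  tab <- table(cell_metadata$sample_id, cell_metadata$cell_type)
  matrix(as.integer(tab), nrow(tab), ncol(tab),
         dimnames = dimnames(tab))
}

#' Case-control program tests
#'
#' Welch's two-tailed unequal-variance t-test per program, comparing all
#' disease samples (every non-HC group) against healthy controls.
#'
#' @param scores samples x programs matrix.
#' @param clinical data.frame with `sample_id` and `group`.
#' @return data.frame: unit, family, test, comparison, statistic, p, p_adj
#'   (BH across programs), direction (sign of disease minus control mean),
#'   flag.
#' @export
program_case_control <- function(scores, clinical) {
  grp <- clinical$group[match(rownames(scores), clinical$sample_id)]
  case <- grp != "HC"
  if (sum(case, na.rm = TRUE) < 2 || sum(!case, na.rm = TRUE) < 2) {
    stop("need >= 2 samples per group")
  }
  rows <- lapply(colnames(scores), function(pn) {
    x <- scores[which(case), pn]
    y <- scores[which(!case), pn]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    d <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stat <- if (d == 0) 0 else sign(d) * Inf
      p <- if (d == 0) 1 else 0
      flag <- "degenerate_zero_variance"
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
      flag <- "ok"
    }
    data.frame(unit = pn, family = "case_control", test = "welch_t",
               comparison = "disease vs HC", statistic = stat, p = p,
               p_adj = NA_real_,
               direction = ifelse(d >= 0, "up", "down"), flag = flag)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res
}

#' Four-group disease-activity ANOVA per program
#'
#' One-way ANOVA of each program's per-sample score across the four ordered
#' disease groups, with Tukey HSD post hoc p-values for all six pairs.
#'
#' @param scores samples x programs matrix.
#' @param clinical data.frame with `sample_id` and `group`.
#' @return data.frame with `family` either `activity_anova` (F statistic,
#'   raw p) or `activity_tukey` (pairwise difference as statistic, Tukey
#'   adjusted p in both `p` and `p_adj`).
#' @export
program_activity_anova <- function(scores, clinical) {
  levels4 <- c("HC", "Inactive", "Active", "TreatmentNaive")
  grp <- clinical$group[match(rownames(scores), clinical$sample_id)]
  missing <- setdiff(levels4, unique(grp))
  if (length(missing) > 0) stop("missing group: ", missing[1])
  g <- factor(grp, levels = levels4)
  out <- list()
  for (pn in colnames(scores)) {
    ok <- !is.na(scores[, pn])
    fit <- stats::aov(scores[ok, pn] ~ g[ok])
    an <- summary(fit)[[1]]
    out[[length(out) + 1]] <- data.frame(
      unit = pn, family = "activity_anova", test = "anova_1way",
      comparison = "4 groups", statistic = an[["F value"]][1],
      p = an[["Pr(>F)"]][1], p_adj = NA_real_, direction = NA_character_
    )
    tk <- stats::TukeyHSD(fit)[[1]]
    out[[length(out) + 1]] <- data.frame(
      unit = pn, family = "activity_tukey", test = "tukey_hsd",
      comparison = rownames(tk), statistic = tk[, "diff"],
      p = tk[, "p adj"], p_adj = tk[, "p adj"],
      direction = ifelse(tk[, "diff"] > 0, "up", "down")
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive cross-cell-type gene modules from DE gene lists
#'
#' Keeps genes called differentially expressed in at least two cell types,
#' builds their (sample, cell type) average-expression matrix,
#' row-standardizes it, and clusters the genes hierarchically (Euclidean
#' distance, complete linkage) into `n_modules` modules, returned by
#' decreasing size.
#'
#' @param de_tables named list (per cell type) of significant gene id
#'   vectors; DE testing itself is upstream input.
#' @param avg_expr genes x (sample, cell type) average-expression matrix,
#'   e.g. from [average_expression()].
#' @param n_modules number of modules to cut.
#' @return list of modules, each a list with `label`, `genes`, `source`.
#' @export
derive_gene_modules <- function(de_tables, avg_expr, n_modules = 7L) {
  counts <- table(unlist(lapply(de_tables, unique)))
  keep <- names(counts)[counts >= 2]
  keep <- intersect(keep, rownames(avg_expr))
  if (length(keep) < 2) {
    stop("fewer than 2 genes significant in >= 2 cell types")
  }
  M <- avg_expr[keep, , drop = FALSE]
  mu <- rowMeans(M)
  sd <- apply(M, 1, stats::sd)
  M <- (M - mu) / ifelse(sd > 0, sd, 1)
  hc <- stats::hclust(stats::dist(M), method = "complete")
  cl <- stats::cutree(hc, k = min(n_modules, length(keep)))
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  lapply(seq_along(ord), function(i) {
    id <- as.integer(names(sizes)[ord[i]])
    list(label = paste0("M", i), genes = sort(keep[cl == id]),
         source = "hclust_euclidean_complete")
  })
}

#' Average expression per sample and cell type
#'
#' Mean log-normalized expression (`log1p` of per-10k scaled counts) of each
#' gene over the cells of each (sample, cell type) stratum.
#'
#' @param counts gene x cell count matrix.
#' @param cell_metadata data.frame with `barcode`, `sample_id`, `cell_type`
#'   covering the matrix columns.
#' @return genes x (sample.cell_type) matrix.
#' @export
average_expression <- function(counts, cell_metadata) {
  idx <- match(colnames(counts), cell_metadata$barcode)
  if (anyNA(idx)) stop("cells missing from metadata")
  stratum <- paste(cell_metadata$sample_id[idx],
                   cell_metadata$cell_type[idx], sep = ".")
  X <- lognormalize(counts)
  strata <- sort(unique(stratum))
  out <- vapply(strata, function(s) {
    Matrix::rowMeans(X[, stratum == s, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Log-normalize counts
#'
#' `log1p` of counts scaled to 10,000 per cell.
#'
#' @param counts gene x cell matrix.
#' @return matrix of the same shape.
#' @export
lognormalize <- function(counts) {
  tot <- Matrix::colSums(counts)
  sf <- ifelse(tot > 0, 10000 / tot, 0)
  X <- counts %*% Matrix::Diagonal(x = sf)
  if (inherits(X, "Matrix")) {
    X@x <- log1p(X@x)
  } else {
    X <- log1p(X)
  }
  dimnames(X) <- dimnames(counts)
  X
}

#' Per-cell module score with binned expression-matched controls
#'
#' Scores a gene set per cell as the mean expression of the set genes minus
#' the mean expression of an expression-matched control pool: genes are
#' binned into `n_bins` bins by mean expression and, for every set gene,
#' `n_ctrl` control genes are sampled with replacement from its bin (the
#' whole bin is used, once each, when it has at most `n_ctrl` genes, which
#' also makes `n_bins = 1, n_ctrl >= n_genes` reduce exactly to
#' mean(set) - mean(all genes)).
#'
#' @param expression log-normalized gene x cell matrix (see
#'   [lognormalize()]).
#' @param gene_set character vector; at least one gene must be present.
#' @param n_bins expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(expression, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  present <- intersect(gene_set, rownames(expression))
  if (length(present) == 0) {
    stop("gene set entirely absent from matrix; missing: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  }
  mu <- Matrix::rowMeans(expression)
  nb <- min(n_bins, nrow(expression))
  bin <- ceiling(rank(mu, ties.method = "first") * nb / length(mu))
  ctrl_weight <- numeric(nrow(expression))
  with_seed(seed, {
    for (g in present) {
      pool <- which(bin == bin[match(g, rownames(expression))])
      if (length(pool) <= n_ctrl) {
        ctrl_weight[pool] <- ctrl_weight[pool] + 1
      } else {
        draw <- pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
        tab <- tabulate(draw, nbins = nrow(expression))
        ctrl_weight <- ctrl_weight + tab
      }
    }
  })
  set_mean <- Matrix::colMeans(expression[present, , drop = FALSE])
  wsum <- sum(ctrl_weight)
  ctrl_mean <- as.numeric(ctrl_weight %*% expression) / wsum
  score <- set_mean - ctrl_mean
  stats::setNames(as.numeric(score), colnames(expression))
}

#' Spearman correlation of per-sample scores with disease activity
#'
#' Per scored unit (program, module score or biomarker channel), Spearman
#' correlation with the clinical VAS over samples with both values,
#' BH-adjusted across units.
#'
#' @param scores samples x units matrix (or named vector for one unit).
#' @param clinical data.frame with `sample_id` and `vas_global`.
#' @param family label recorded in the output.
#' @param min_samples minimal paired samples per unit.
#' @return data.frame: unit, family, test, comparison, statistic (rho), p,
#'   p_adj, direction, flag.
#' @export
score_activity_correlation <- function(scores, clinical,
                                       family = "activity_vas",
                                       min_samples = 5L) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, ncol = 1,
                     dimnames = list(names(scores), "score"))
  }
  vas <- clinical$vas_global[match(rownames(scores), clinical$sample_id)]
  rows <- lapply(colnames(scores), function(u) {
    ok <- !is.na(scores[, u]) & !is.na(vas)
    if (sum(ok) < min_samples) {
      return(data.frame(unit = u, family = family, test = "spearman",
                        comparison = "score~vas_global",
                        statistic = NA_real_, p = NA_real_,
                        p_adj = NA_real_, direction = NA_character_,
                        flag = "too_few_samples"))
    }
    if (stats::sd(scores[ok, u]) == 0) {
      return(data.frame(unit = u, family = family, test = "spearman",
                        comparison = "score~vas_global",
                        statistic = NA_real_, p = NA_real_,
                        p_adj = NA_real_, direction = NA_character_,
                        flag = "constant_scores"))
    }
    ct <- suppressWarnings(
      stats::cor.test(scores[ok, u], vas[ok], method = "spearman",
                      exact = FALSE)
    )
    data.frame(unit = u, family = family, test = "spearman",
               comparison = "score~vas_global",
               statistic = unname(ct$estimate), p = ct$p.value,
               p_adj = NA_real_,
               direction = ifelse(ct$estimate > 0, "up", "down"),
               flag = "ok")
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$p)
  res$p_adj[ok] <- stats::p.adjust(res$p[ok], "BH")
  res
}
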