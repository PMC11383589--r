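# Independent brute-force oracles used to check the implementations.

# GSEA enrichment score by walking the full ranking position by position.
brute_es <- function(scores, hit_idx, weight_exponent = 1) {
  n <- length(scores)
  m <- length(hit_idx)
  w <- abs(scores)^weight_exponent
  tot <- sum(w[hit_idx])
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_idx) {
      run <- run + (if (tot > 0) w[i] / tot else 1 / m)
    } else {
      run <- run - 1 / (n - m)
    }
    hi <- max(hi, run)
    lo <- min(lo, run)
  }
  if (hi >= -lo - 1e-12) hi else lo
}

# Upper-tail hypergeometric probability P(X >= k) by direct log-choose
# summation.
brute_hyper_tail <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Kruskal-Wallis H with tie correction, from first principles.
brute_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Welch's t statistic and p-value from the textbook formulas.
brute_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F and p from the sum-of-squares decomposition.
brute_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Tukey HSD adjusted p for one pair, from the studentized range distribution.
brute_tukey_p <- function(values, groups, a, b) {
  groups <- factor(groups)
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  df2 <- length(values) - nlevels(groups)
  s2 <- ssw / df2
  na <- sum(groups == a)
  nb <- sum(groups == b)
  q <- abs(mean(values[groups == a]) - mean(values[groups == b])) /
    sqrt(s2 / 2 * (1 / na + 1 / nb))
  ptukey(q, nlevels(groups), df2, lower.tail = FALSE)
}

# Rank-AUC by explicit construction of the recovery step curve.
brute_rank_auc <- function(expr, set_flags, top_fraction) {
  ord <- order(-expr, seq_along(expr))
  n_top <- ceiling(top_fraction * length(expr))
  m <- sum(set_flags)
  curve <- cumsum(set_flags[ord])[seq_len(n_top)]
  best <- cumsum(rep(1, min(m, n_top)))
  best <- c(best, rep(min(m, n_top), n_top - length(best)))
  sum(curve) / sum(best)
}

# Naive O(n^3) agglomerative complete-linkage clustering into k groups.
brute_complete_linkage <- function(M, k) {
  D <- as.matrix(dist(M))
  clusters <- as.list(seq_len(nrow(M)))
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(j, i)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(nrow(M))
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}
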