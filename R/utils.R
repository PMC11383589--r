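## Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Softplus map used to push Gaussian latents onto a nonnegative scale while
# staying close to linear in the range the latents actually occupy.
softplus <- function(x) {
  # log(1 + exp(x)), numerically stable for large |x|
  ifelse(x > 30, x, log1p(exp(x)))
}

# Derive a reproducible sub-seed from a global seed and a stage label.
# Simple additive counter scheme over a fixed stage table; keeps every
# stochastic stage independently re-runnable from the one global seed.
stage_seed <- function(seed, stage) {
  stages <- c(
    simulate = 1L, factorize = 2L, filter = 3L, network = 4L,
    enrich = 5L, associate = 6L, transfer = 7L, layout = 8L, modules = 9L
  )
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  (as.integer(seed) + 1000L * stages[[stage]]) %% .Machine$integer.max
}

# Column-wise cosine similarity between two matrices with equal rows.
cosine_columns <- function(A, B) {
  An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), .Machine$double.eps), "/")
  Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), .Machine$double.eps), "/")
  crossprod(An, Bn)
}

# Exact linear assignment maximizing the total score for small k
# (exhaustive over permutations up to k = 8, greedy beyond).  Used to match
# recovered program columns to planted ones.
match_columns <- function(score) {
  k <- nrow(score)
  stopifnot(ncol(score) == k)
  if (k <= 8) {
    perms <- permutations_of(k)
    best <- NULL
    best_val <- -Inf
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, ]
      v <- sum(score[cbind(seq_len(k), p)])
      if (v > best_val) {
        best_val <- v
        best <- p
      }
    }
    return(list(assignment = best, total = best_val))
  }
  # greedy fallback: repeatedly take the best remaining pair
  assign <- integer(k)
  rows <- seq_len(k)
  cols <- seq_len(k)
  s <- score
  for (step in seq_len(k)) {
    idx <- which(s == max(s[rows, cols], na.rm = TRUE), arr.ind = TRUE)[1, ]
    assign[idx[1]] <- idx[2]
    s[idx[1], ] <- -Inf
    s[, idx[2]] <- -Inf
    rows <- setdiff(rows, idx[1])
    cols <- setdiff(cols, idx[2])
  }
  list(assignment = assign, total = sum(score[cbind(seq_len(k), assign)]))
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  r <- 1L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      row <- integer(k)
      row[pos] <- k
      row[-pos] <- sub[i, ]
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

# Dense matrix from possibly sparse input, without surprises on vectors.
as_dense <- function(X) {
  if (inherits(X, "Matrix")) as.matrix(X) else X
}

# Format a program identifier from a cell type and program index, e.g. "B_3".
program_id <- function(cell_type, program) paste0(cell_type, "_", program)
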