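#' Read a GMT gene-set collection
#'
#' Parses the standard GMT format (set name, description, then tab-separated
#' gene ids, one set per line).  Gene ids are uppercased so they match
#' expression gene ids normalized the same way; duplicate set names are
#' rejected.
#'
#' @param path GMT file.
#' @param min_size warn (not drop) for sets smaller than this.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of gene id vectors) and `description` (named character).
#' @export
read_gmt <- function(path, min_size = 2L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", i, ": need name, description, >= 1 gene")
    }
    nm <- parts[1]
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set at line ", i, ": ", nm)
    if (length(genes) < min_size) {
      warning("gene set ", nm, " has fewer than ", min_size, " genes")
    }
    sets[[nm]] <- genes
    descr[nm] <- parts[2]
  }
  structure(list(sets = sets, description = descr),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("Gene set collection:", length(x$sets), "sets, sizes",
      min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Preranked gene set enrichment
#'
#' Computes the classic running-sum enrichment score on a ranked gene list:
#' walking down the ranking, the sum increases by `|score|^weight_exponent`
#' (normalized) at set genes and decreases uniformly at non-set genes; the
#' enrichment score ES is the maximum deviation from zero.  Significance
#' comes from `n_perm` gene-label permutations; the p-value is computed
#' against the null ES values of matching sign, so enrichment at either end
#' of the ranking is testable.  NES is ES divided by the mean |null ES| of
#' the same sign.
#'
#' @param ranking named numeric vector of gene scores; internally ordered by
#'   descending score with ties broken by gene id.
#' @param gene_set character vector of gene ids.
#' @param n_perm permutations.
#' @param weight_exponent exponent on |score| for hit increments (0 gives
#'   the unweighted Kolmogorov-Smirnov walk).
#' @param seed integer seed.
#' @return list: `set_size` (genes in both set and ranking), `ES`, `NES`,
#'   `p`, `leading_edge` (gene ids), `flag` (`"ok"`, `"empty_intersection"`
#'   or `"degenerate_all_genes"`).
#' @export
preranked_gsea <- function(ranking, gene_set, n_perm = 1000L,
                           weight_exponent = 1, seed = 1L) {
  stopifnot(!is.null(names(ranking)))
  ord <- order(-ranking, names(ranking))
  scores <- ranking[ord]
  genes <- names(scores)
  n <- length(genes)
  hits <- which(genes %in% toupper_if_needed(gene_set, genes))
  m <- length(hits)
  if (m == 0) {
    return(list(set_size = 0L, ES = 0, NES = NA_real_, p = 1,
                leading_edge = character(0), flag = "empty_intersection"))
  }
  if (m == n) {
    return(list(set_size = m, ES = 0, NES = NA_real_, p = 1,
                leading_edge = character(0), flag = "degenerate_all_genes"))
  }
  w <- abs(scores)^weight_exponent
  es_obs <- running_sum_es(hits, w, n)
  with_seed(seed, {
    es_null <- vapply(seq_len(n_perm), function(b) {
      running_sum_es(sort(sample.int(n, m)), w, n)$ES
    }, numeric(1))
  })
  same <- es_null[sign(es_null) == sign(es_obs$ES)]
  p <- (1 + sum(abs(same) >= abs(es_obs$ES))) / (1 + length(same))
  nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
    es_obs$ES / mean(abs(same))
  } else {
    NA_real_
  }
  leading <- if (es_obs$ES >= 0) {
    genes[hits[hits <= es_obs$arg]]
  } else {
    genes[hits[hits >= es_obs$arg]]
  }
  list(set_size = m, ES = es_obs$ES, NES = nes, p = p,
       leading_edge = leading, flag = "ok")
}

# Maximum deviation of the GSEA running sum, evaluated at the hit positions
# (where the extrema occur).  `hits` must be sorted ascending.
running_sum_es <- function(hits, w, n) {
  m <- length(hits)
  wh <- w[hits]
  tot <- sum(wh)
  inc <- if (tot > 0) cumsum(wh) / tot else cumsum(rep(1 / m, m))
  dec <- 1 / (n - m)
  after <- inc - (hits - seq_len(m)) * dec        # just after each hit
  before <- c(0, inc[-m]) - (hits - seq_len(m)) * dec  # just before each hit
  hi <- max(after)
  lo <- min(before)
  # positive deviation wins unless the negative one is genuinely larger
  if (hi >= -lo - 1e-12) {
    list(ES = hi, arg = hits[which.max(after)])
  } else {
    list(ES = lo, arg = hits[which.min(before)])
  }
}

# Match set ids to the ranking's id case convention.
toupper_if_needed <- function(gene_set, genes) {
  s <- intersect(gene_set, genes)
  if (length(s) > 0) return(gene_set)
  toupper(gene_set)
}

#' Batch GSEA over programs and a gene-set collection
#'
#' Runs [preranked_gsea()] on every program's marker-score ranking against
#' every set of a collection, with BH correction across sets within each
#' program and a significance flag at `fdr < fdr_cutoff`.
#'
#' @param markers a `marker_table` from [marker_scores()], or a named list
#'   of named score vectors (one per program).
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param n_perm permutations per test.
#' @param fdr_cutoff significance cutoff on the BH-adjusted p; only
#'   positively enriched sets (`ES > 0`) are flagged, depleted sets keep
#'   their p/FDR but are never marked significant.
#' @param seed integer seed.
#' @param weight_exponent passed to [preranked_gsea()].
#' @return data.frame: program, set, set_size, ES, NES, p, fdr, significant,
#'   leading_edge (comma-separated).
#' @export
batch_gsea <- function(markers, collection, n_perm = 1000L,
                       fdr_cutoff = 0.01, seed = 1L, weight_exponent = 1) {
  rankings <- if (inherits(markers, "marker_table")) {
    cols <- colnames(markers$score)
    stats::setNames(lapply(cols, function(j) {
      stats::setNames(markers$score[, j], toupper(rownames(markers$score)))
    }), cols)
  } else {
    lapply(markers, function(v) stats::setNames(v, toupper(names(v))))
  }
  out <- list()
  for (pi in seq_along(rankings)) {
    prog <- names(rankings)[pi]
    rows <- lapply(seq_along(collection$sets), function(si) {
      res <- preranked_gsea(rankings[[pi]], collection$sets[[si]],
                            n_perm = n_perm,
                            weight_exponent = weight_exponent,
                            seed = seed + 1000L * pi + si)
      data.frame(program = prog, set = names(collection$sets)[si],
                 set_size = res$set_size, ES = res$ES, NES = res$NES,
                 p = res$p,
                 leading_edge = paste(res$leading_edge, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p, "BH")
    tab$significant <- tab$fdr < fdr_cutoff & tab$ES > 0
    out[[pi]] <- tab
  }
  res <- do.call(rbind, out)
  res[, c("program", "set", "set_size", "ES", "NES", "p", "fdr",
          "significant", "leading_edge")]
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail hypergeometric p-value for the overlap between a hit list and
#' a gene set within a universe, plus the fold enrichment
#' `(overlap/|hits|) / (|set|/|universe|)`.
#'
#' @param hit_genes nonempty character vector, subset of `universe`.
#' @param gene_set character vector, subset of `universe`.
#' @param universe gene universe.
#' @return list with `p`, `fold`, `overlap`, `n_hits`, `n_set`, `n_universe`.
#' @export
ora_hypergeometric <- function(hit_genes, gene_set, universe) {
  hit_genes <- unique(hit_genes)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(hit_genes) == 0) stop("empty hit list")
  if (!all(hit_genes %in% universe) || !all(gene_set %in% universe)) {
    stop("hits and set must be subsets of the universe")
  }
  k <- length(intersect(hit_genes, gene_set))
  N <- length(universe)
  K <- length(gene_set)
  nh <- length(hit_genes)
  p <- stats::phyper(k - 1, K, N - K, nh, lower.tail = FALSE)
  fold <- if (K > 0) (k / nh) / (K / N) else NA_real_
  list(p = p, fold = fold, overlap = k, n_hits = nh, n_set = K,
       n_universe = N)
}
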