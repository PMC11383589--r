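#' Synthetic cohort configuration
#'
#' Builds the configuration object for [simulate_cohort()].  The defaults
#' emulate a pediatric autoimmune CITE-seq cohort: 27 samples split over four
#' disease-activity groups (healthy controls, inactive, active and
#' treatment-naive disease), six major immune cell types, five planted gene
#' expression programs (GEPs) per cell type, cross-cell-type program modules
#' with a designated "activity" module whose per-sample intensity is shifted
#' along the group ordering, and one surface-protein (ADT) channel that is an
#' affine readout of the activity module.
#'
#' @param n_samples total number of samples; must equal `sum(group_sizes)`.
#' @param group_sizes named integer vector over the four groups, ordered
#'   `HC < Inactive < Active < TreatmentNaive` (increasing disease activity).
#' @param n_cell_types number of cell types simulated.
#' @param genes_per_type number of genes per cell type.
#' @param programs_per_type true number of programs (NMF rank) per cell type.
#' @param cells_per_sample_per_type cells drawn per sample for each cell type.
#' @param loading_sparsity fraction of non-anchor loading entries set to zero,
#'   in `[0, 1)`.
#' @param module_spec list of planted modules; each element is a list with
#'   `id`, `members` (data.frame with columns `cell_type`, `program`) and
#'   `rho` (latent intra-module correlation in `[0, 1)`).  `NULL` plants the
#'   default three modules spanning the cell types.
#' @param activity_module id of the module tied to disease activity.
#' @param activity_effect standardized shift `d` applied to the activity
#'   module's latent intensity per ordered group step.
#' @param libsize_mean mean per-cell library size (UMI counts).
#' @param overdispersion negative-binomial dispersion; `0` gives Poisson
#'   counts.
#' @param usage_concentration Dirichlet concentration for per-cell program
#'   usages around the sample-level mixture.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param loading_seed seed for the planted loadings only; defaults to
#'   `seed`.  Fixing `loading_seed` while varying `seed` yields independent
#'   cohorts expressing the same planted programs, as needed for
#'   signature-transfer studies.
#' @return a list of class `gep_sim_config`.
#' @export
synthetic_config <- function(n_samples = 27L,
                             group_sizes = c(HC = 5L, Inactive = 6L,
                                             Active = 7L, TreatmentNaive = 9L),
                             n_cell_types = 6L,
                             genes_per_type = 1000L,
                             programs_per_type = 5L,
                             cells_per_sample_per_type = 100L,
                             loading_sparsity = 0.5,
                             module_spec = NULL,
                             activity_module = 1L,
                             activity_effect = 2,
                             libsize_mean = 2000L,
                             overdispersion = 0.5,
                             usage_concentration = 5,
                             seed = 1L,
                             loading_seed = NULL) {
  groups <- c("HC", "Inactive", "Active", "TreatmentNaive")
  if (!identical(sort(names(group_sizes)), sort(groups))) {
    stop("group_sizes must be named over HC, Inactive, Active, TreatmentNaive")
  }
  group_sizes <- group_sizes[groups]
  if (sum(group_sizes) != n_samples) {
    stop("group sizes must sum to n_samples (", sum(group_sizes),
         " != ", n_samples, ")")
  }
  if (loading_sparsity < 0 || loading_sparsity >= 1) {
    stop("loading_sparsity must be in [0, 1)")
  }
  if (any(c(n_cell_types, genes_per_type, programs_per_type,
            cells_per_sample_per_type, libsize_mean) < 1)) {
    stop("all size parameters must be >= 1")
  }
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  cell_types <- paste0("CT", seq_len(n_cell_types))
  if (is.null(module_spec)) {
    module_spec <- default_module_spec(cell_types, programs_per_type)
  }
  validate_module_spec(module_spec, cell_types, programs_per_type)
  cfg <- list(
    n_samples = as.integer(n_samples),
    group_sizes = group_sizes,
    n_cell_types = as.integer(n_cell_types),
    cell_types = cell_types,
    genes_per_type = as.integer(genes_per_type),
    programs_per_type = as.integer(programs_per_type),
    cells_per_sample_per_type = as.integer(cells_per_sample_per_type),
    loading_sparsity = loading_sparsity,
    module_spec = module_spec,
    activity_module = activity_module,
    activity_effect = activity_effect,
    libsize_mean = libsize_mean,
    overdispersion = overdispersion,
    usage_concentration = usage_concentration,
    seed = as.integer(seed),
    loading_seed = if (is.null(loading_seed)) as.integer(seed) else
      as.integer(loading_seed)
  )
  class(cfg) <- "gep_sim_config"
  cfg
}

# Default planted modules: one activity module spanning program 1 of every
# cell type, and two smaller modules over disjoint cell-type subsets.
default_module_spec <- function(cell_types, k) {
  m1 <- data.frame(cell_type = cell_types, program = 1L)
  spec <- list(list(id = 1L, members = m1, rho = 0.7))
  if (k >= 2 && length(cell_types) >= 2) {
    half <- ceiling(length(cell_types) / 2)
    m2 <- data.frame(cell_type = cell_types[seq_len(half)], program = 2L)
    spec <- c(spec, list(list(id = 2L, members = m2, rho = 0.6)))
    if (half < length(cell_types)) {
      m3 <- data.frame(cell_type = cell_types[(half + 1):length(cell_types)],
                       program = 2L)
      spec <- c(spec, list(list(id = 3L, members = m3, rho = 0.6)))
    }
  }
  spec
}

validate_module_spec <- function(spec, cell_types, k) {
  seen <- character(0)
  for (m in spec) {
    stopifnot(is.list(m), !is.null(m$id), !is.null(m$members), !is.null(m$rho))
    if (m$rho < 0 || m$rho >= 1) stop("module rho must be in [0, 1)")
    ids <- program_id(m$members$cell_type, m$members$program)
    if (any(ids %in% seen)) stop("a program may belong to at most one module")
    if (!all(m$members$cell_type %in% cell_types)) {
      stop("module member cell type not in cohort")
    }
    if (any(m$members$program > k)) stop("module member program exceeds rank")
    seen <- c(seen, ids)
  }
  invisible(TRUE)
}

#' Plant sparse, anchored program loadings
#'
#' Generates a nonnegative gene-by-program loading matrix whose columns sum
#' to one.  Each program receives a disjoint set of high-weight "anchor"
#' genes carrying half the column mass, which makes the programs mutually
#' identifiable; the remaining mass is spread over a random subset of
#' background genes, with a `sparsity` fraction of background entries set to
#' zero.  For `n_genes >= 6 * n_anchor` every anchor weight exceeds three
#' times the column mean.
#'
#' @param n_genes number of genes (rows).
#' @param k number of programs (columns); `k <= n_genes`.
#' @param sparsity fraction of background entries zeroed, in `[0, 1)`.
#' @param seed integer seed.
#' @param n_anchor anchor genes per program (default 5).
#' @return `n_genes x k` matrix; columns sum to 1, rows named `g0001, ...`.
#' @export
plant_loadings <- function(n_genes, k, sparsity, seed, n_anchor = 5L) {
  if (k < 1 || n_genes < k) stop("need n_genes >= k >= 1")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (n_anchor * k > n_genes) stop("too many anchor genes for n_genes")
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    W <- matrix(0, n_genes, k, dimnames = list(gene_ids, paste0("p", seq_len(k))))
    anchors <- matrix(sample.int(n_genes, n_anchor * k), nrow = n_anchor)
    for (j in seq_len(k)) {
      bg <- setdiff(seq_len(n_genes), anchors[, j])
      # flat background weights: program identity is carried by the anchors
      # and the random support, so no background direction is preferred
      w <- rep(0.6, length(bg))
      n_zero <- floor(sparsity * length(bg))
      if (n_zero > 0) w[sample.int(length(bg), n_zero)] <- 0
      col <- numeric(n_genes)
      col[bg] <- w
      bg_total <- sum(w)
      # anchors carry half the column mass (all of it if background is empty)
      anchor_mass <- if (bg_total > 0) bg_total else 1
      col[anchors[, j]] <- anchor_mass / n_anchor
      W[, j] <- col / sum(col)
    }
    attr(W, "anchor_genes") <- lapply(seq_len(k), function(j) {
      sort(gene_ids[anchors[, j]])
    })
    W
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a multi-sample, multi-cell-type single-cell cohort
#'
#' Draws a full synthetic cohort from a [synthetic_config()]: planted
#' loadings per cell type, sample-level program intensities from a Gaussian
#' copula (correlation `rho` inside planted modules, zero across), per-cell
#' Dirichlet usages around the sample intensity, negative-binomial gene
#' counts, a clinical table with a 0-10 disease-activity VAS derived from an
#' independent latent activity shifted by `activity_effect` per group step,
#' and one ADT channel that reads out the activity module's intensity.
#'
#' @param config a `gep_sim_config` from [synthetic_config()].
#' @return a list of class `gep_cohort` with elements `counts` (named list of
#'   sparse gene-by-cell `dgCMatrix` per cell type), `cell_metadata`
#'   (data.frame: barcode, sample_id, donor_id, cell_type, group, vas_global,
#'   on_medication), `clinical` (per-sample table), `adt` (1 x cells matrix),
#'   `truth` (planted loadings, sample usages, module map, activity score)
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "gep_sim_config"))
  cfg <- config
  if (cfg$cells_per_sample_per_type < 1) stop("each cell type needs >= 1 cell")
  with_seed(cfg$seed, {
    groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
    sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
    donor_ids <- sprintf("D%02d", seq_len(cfg$n_samples))
    group_step <- match(groups, c("HC", "Inactive", "Active", "TreatmentNaive")) - 1L

    ## planted loadings per cell type
    loadings <- lapply(seq_along(cfg$cell_types), function(t) {
      plant_loadings(cfg$genes_per_type, cfg$programs_per_type,
                     cfg$loading_sparsity, seed = cfg$loading_seed + 17L * t)
    })
    names(loadings) <- cfg$cell_types

    ## latent sample intensities over all (cell type, program) pairs
    prog_tab <- expand.grid(program = seq_len(cfg$programs_per_type),
                            cell_type = cfg$cell_types,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)[, c("cell_type", "program")]
    prog_ids <- program_id(prog_tab$cell_type, prog_tab$program)
    P <- nrow(prog_tab)
    Sigma <- diag(P)
    module_of <- rep(NA_integer_, P)
    names(module_of) <- prog_ids
    for (m in cfg$module_spec) {
      idx <- match(program_id(m$members$cell_type, m$members$program), prog_ids)
      Sigma[idx, idx] <- m$rho
      diag(Sigma)[idx] <- 1
      module_of[idx] <- m$id
    }
    Z <- rmvnorm_chol(cfg$n_samples, Sigma)
    act_idx <- which(module_of == cfg$activity_module)
    if (length(act_idx) > 0) {
      Z[, act_idx] <- Z[, act_idx] + cfg$activity_effect * group_step
    }
    intensity <- softplus(1 + Z)
    dimnames(intensity) <- list(sample_ids, prog_ids)

    ## clinical activity: independent latent shifted with the group ordering,
    ## rank-mapped to the 0-10 VAS scale
    activity_raw <- cfg$activity_effect * group_step + stats::rnorm(cfg$n_samples)
    vas <- round(10 * (rank(activity_raw) - 0.5) / cfg$n_samples, 2)
    clinical <- data.frame(
      sample_id = sample_ids, donor_id = donor_ids, group = groups,
      vas_global = vas,
      on_medication = groups %in% c("Inactive", "Active"),
      stringsAsFactors = FALSE
    )

    ## per-cell draws
    n_ct_cells <- cfg$n_samples * cfg$cells_per_sample_per_type
    counts <- list()
    meta_list <- list()
    cell_usage <- list()
    gene_ids <- sprintf("g%04d", seq_len(cfg$genes_per_type))
    for (t in seq_along(cfg$cell_types)) {
      ct <- cfg$cell_types[t]
      W <- loadings[[t]]
      cols <- match(program_id(ct, seq_len(cfg$programs_per_type)), prog_ids)
      H <- matrix(0, cfg$programs_per_type, n_ct_cells)
      cell_sample <- rep(seq_len(cfg$n_samples),
                         each = cfg$cells_per_sample_per_type)
      for (s in seq_len(cfg$n_samples)) {
        p <- intensity[s, cols]
        probs <- p / sum(p)
        cells <- which(cell_sample == s)
        H[, cells] <- t(rdirichlet(length(cells),
                                   cfg$usage_concentration * probs))
      }
      libsize <- stats::rlnorm(n_ct_cells,
                               meanlog = log(cfg$libsize_mean) - 0.3^2 / 2,
                               sdlog = 0.3)
      mu <- (W %*% H) * rep(libsize, each = cfg$genes_per_type)
      X <- draw_counts(mu, cfg$overdispersion)
      barcodes <- sprintf("%s-%s-%04d", ct, sample_ids[cell_sample],
                          seq_len(n_ct_cells))
      dimnames(X) <- list(gene_ids, barcodes)
      dimnames(H) <- list(paste0("p", seq_len(cfg$programs_per_type)),
                          barcodes)
      cell_usage[[ct]] <- H
      counts[[ct]] <- methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix")
      meta_list[[ct]] <- data.frame(
        barcode = barcodes, sample_id = sample_ids[cell_sample],
        donor_id = donor_ids[cell_sample], cell_type = ct,
        group = groups[cell_sample], vas_global = vas[cell_sample],
        on_medication = clinical$on_medication[cell_sample],
        stringsAsFactors = FALSE
      )
    }
    cell_metadata <- do.call(rbind, meta_list)
    rownames(cell_metadata) <- NULL

    ## ADT biomarker channel: affine in the activity module's mean intensity
    act_signal <- if (length(act_idx) > 0) {
      rowMeans(intensity[, act_idx, drop = FALSE])
    } else {
      rep(0, cfg$n_samples)
    }
    adt_sample <- 1 + 2 * act_signal + stats::rnorm(cfg$n_samples, sd = 0.3)
    names(adt_sample) <- sample_ids
    adt_cell <- adt_sample[cell_metadata$sample_id] +
      stats::rnorm(nrow(cell_metadata), sd = 0.5)
    adt <- matrix(adt_cell, nrow = 1,
                  dimnames = list("ADT_activity", cell_metadata$barcode))

    truth <- list(
      true_loadings = loadings,
      true_sample_usage = intensity,
      true_modules = module_of[!is.na(module_of)],
      true_activity_score = stats::setNames(vas, sample_ids),
      true_cell_usage = cell_usage,
      activity_module = cfg$activity_module,
      anchor_genes = lapply(loadings, attr, "anchor_genes"),
      adt_sample_level = adt_sample
    )
    out <- list(counts = counts, cell_metadata = cell_metadata,
                clinical = clinical, adt = adt, truth = truth, config = cfg)
    class(out) <- "gep_cohort"
    out
  })
}

#' @export
print.gep_cohort <- function(x, ...) {
  cat("Synthetic single-cell cohort\n")
  cat("  samples:   ", x$config$n_samples, " (",
      paste(names(x$config$group_sizes), x$config$group_sizes,
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  cell types:", length(x$counts), "x",
      x$config$cells_per_sample_per_type, "cells/sample,",
      x$config$genes_per_type, "genes\n")
  cat("  programs:  ", x$config$programs_per_type, "per cell type;",
      length(x$config$module_spec), "planted modules\n")
  invisible(x)
}

# Multivariate normal via Cholesky (Sigma must be positive definite).
rmvnorm_chol <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% L
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1
  x / rowSums(x)
}

draw_counts <- function(mu, overdispersion) {
  n <- length(mu)
  x <- if (overdispersion <= 0) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
  }
  matrix(x, nrow = nrow(mu))
}
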