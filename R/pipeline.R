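#' Default pipeline parameters
#'
#' @return named list of stage parameters with the package defaults:
#'   2,000 overdispersed genes, rank grid 5-20 with 5 restarts, 1,000
#'   bootstrap resamples and permutations, edge significance 0.05,
#'   enrichment FDR cutoff 0.01, 5% marker and ranking fractions, and a
#'   10-cell minimum per sample and cell type.
#' @export
default_params <- function() {
  list(n_top_genes = 2000L, k_grid = 5:20, restarts = 5L,
       n_boot = 1000L, n_perm = 1000L, alpha = 0.05, fdr = 0.01,
       top_fraction = 0.05, marker_fraction = 0.05, min_cells = 10L,
       max_sample_share = 0.5, min_active_samples = 3L)
}

#' Assemble and validate a pipeline configuration
#'
#' @param counts fixture directory readable by [read_counts()].
#' @param out output directory for stage tables and the manifest.
#' @param gene_sets optional GMT file enabling the enrichment stage.
#' @param validation_counts optional second fixture directory; enables the
#'   proxy-transfer stage.
#' @param params overrides merged over [default_params()].
#' @param seed global seed, expanded into per-stage sub-seeds.
#' @return validated config list of class `gep_config`.
#' @export
pipeline_config <- function(counts, out, gene_sets = NULL,
                            validation_counts = NULL, params = list(),
                            seed = 1L) {
  if (!dir.exists(counts)) stop("counts directory not found: ", counts)
  if (!is.null(gene_sets) && !file.exists(gene_sets)) {
    stop("gene set file not found: ", gene_sets)
  }
  if (!is.null(validation_counts) && !dir.exists(validation_counts)) {
    stop("validation counts directory not found: ", validation_counts)
  }
  p <- utils::modifyList(default_params(), params)
  if (is.character(p$k_grid)) {
    rng <- as.integer(strsplit(p$k_grid, ":")[[1]])
    p$k_grid <- seq(rng[1], rng[2])
  }
  for (nm in c("k_grid", "restarts", "n_boot", "n_perm", "min_cells",
               "n_top_genes", "min_active_samples")) {
    p[[nm]] <- as.integer(p[[nm]])
  }
  structure(list(counts = counts, out = out, gene_sets = gene_sets,
                 validation_counts = validation_counts, params = p,
                 seed = as.integer(seed)),
            class = "gep_config")
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level keys `counts`, `out` and optionally `gene_sets`,
#' `validation_counts`, `params` (a map of overrides) and `seed`.
#'
#' @param path YAML file.
#' @return a `gep_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(counts = y$counts, out = y$out,
                  gene_sets = y$gene_sets,
                  validation_counts = y$validation_counts,
                  params = if (is.null(y$params)) list() else y$params,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Run the full program-network pipeline
#'
#' Executes the stages factorize (per-cell-type rank selection and
#' consensus NMF) -> filter (outlier programs) -> network (bootstrap
#' correlations, edges, modules) -> enrich (per-program GSEA and module
#' enrichment; only when a gene-set collection is configured) -> associate
#' (composition, case-control, activity ANOVA, VAS correlations) ->
#' transfer (rank-AUC proxy validation; only when a validation cohort is
#' configured), writing every stage table as TSV plus a JSON manifest of
#' parameters, sub-seeds and input checksums.  Rerunning with the same
#' configuration and seed reproduces all tables exactly.
#'
#' @param config a `gep_config` from [pipeline_config()] or [read_config()].
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gep_config"))
  p <- config$params
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  collection <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
  data <- read_counts(config$counts)
  written <- character(0)
  stage <- "factorize"
  result <- tryCatch({
    ## -- factorize -------------------------------------------------------
    models <- list()
    ranks <- list()
    markers <- list()
    scores <- list()
    fseed <- stage_seed(config$seed, "factorize")
    for (ti in seq_along(data$counts)) {
      ct <- names(data$counts)[ti]
      X <- prepare_matrix(data$counts[[ct]], p$n_top_genes)
      grid <- p$k_grid[p$k_grid <= min(dim(X))]
      sel <- select_rank(X, k_grid = grid, n_restarts = p$restarts,
                         seed = fseed + 10000L * ti)
      fit <- consensus_gep(X, sel$chosen_k, n_restarts = p$restarts,
                           seed = fseed + 10000L * ti + 5000L,
                           cell_type = ct)
      models[[ct]] <- fit
      ranks[[ct]] <- sel
      markers[[ct]] <- marker_scores(fit)
      sc <- sample_program_scores(fit, data$cell_metadata,
                                  min_cells = p$min_cells)
      scores[[ct]] <- sc
      written <- c(written,
                   write_stage_table(elbow_table(sel, ct), config$out,
                                     paste0("rank_selection_", ct)),
                   write_stage_table(matrix_table(fit$W, "gene"), config$out,
                                     paste0("loadings_", ct)),
                   write_stage_table(matrix_table(sc, "sample"), config$out,
                                     paste0("sample_scores_", ct)))
    }
    ## -- filter ----------------------------------------------------------
    stage <- "filter"
    combined <- combine_scores(scores)
    filt <- filter_outlier_programs(combined,
                                    max_sample_share = p$max_sample_share,
                                    min_active_samples = p$min_active_samples)
    retained <- combined[, filt$retained, drop = FALSE]
    written <- c(written,
                 write_stage_table(filt$report, config$out, "program_filter"))
    ## -- network ---------------------------------------------------------
    stage <- "network"
    nseed <- stage_seed(config$seed, "network")
    es <- correlate_programs(retained, n_boot = p$n_boot, seed = nseed)
    net <- build_network(es, alpha = p$alpha, seed = nseed)
    net <- detect_modules(net, seed = nseed)
    module_tab <- data.frame(node = names(net$module_of),
                             module = unname(net$module_of))
    edge_tab <- net$edges
    edge_tab$module_from <- net$module_of[edge_tab$from]
    edge_tab$module_to <- net$module_of[edge_tab$to]
    written <- c(written,
                 write_stage_table(edge_tab, config$out, "network_edges"),
                 write_stage_table(module_tab, config$out, "network_modules"))
    write_network(net, graphml = file.path(config$out, "network.graphml"))
    written <- c(written, file.path(config$out, "network.graphml"))
    ## -- enrich ----------------------------------------------------------
    gsea_tab <- NULL
    mod_enrich <- NULL
    if (!is.null(collection)) {
      stage <- "enrich"
      eseed <- stage_seed(config$seed, "enrich")
      per_ct <- lapply(seq_along(models), function(ti) {
        mk <- markers[[ti]]
        rk <- stats::setNames(
          lapply(seq_len(ncol(mk$score)), function(j) mk$score[, j]),
          program_id(names(models)[ti], seq_len(ncol(mk$score)))
        )
        batch_gsea(rk, collection, n_perm = p$n_perm,
                   fdr_cutoff = p$fdr, seed = eseed + 100000L * ti)
      })
      gsea_tab <- do.call(rbind, per_ct)
      mod_enrich <- module_enrichment(net, gsea_tab, n_perm = p$n_perm,
                                      seed = eseed)
      written <- c(written,
                   write_stage_table(gsea_tab[, names(gsea_tab) !=
                                                "leading_edge"],
                                     config$out, "gsea"),
                   write_stage_table(mod_enrich, config$out,
                                     "module_enrichment"))
    }
    ## -- associate -------------------------------------------------------
    stage <- "associate"
    comp <- composition_test(count_cells(data$cell_metadata), data$clinical)
    cc <- program_case_control(retained, data$clinical)
    an <- program_activity_anova(retained, data$clinical)
    vas <- score_activity_correlation(retained, data$clinical)
    assoc <- rbind(comp,
                   cc[, names(comp)],
                   an[, names(comp)],
                   vas[, names(comp)])
    if (!is.null(data$adt)) {
      adt_sample <- pseudobulk(t(data$adt), data$cell_metadata)
      assoc <- rbind(assoc,
                     score_activity_correlation(adt_sample, data$clinical,
                                                family = "adt_vas")[, names(comp)])
    }
    written <- c(written,
                 write_stage_table(assoc, config$out, "associations"))
    ## -- transfer --------------------------------------------------------
    transfer <- NULL
    if (!is.null(config$validation_counts)) {
      stage <- "transfer"
      vdata <- read_counts(config$validation_counts)
      per_ct <- lapply(names(models), function(ct) {
        if (!ct %in% names(vdata$counts)) return(NULL)
        px <- proxy_scores(markers[[ct]], vdata$counts[[ct]],
                           vdata$cell_metadata,
                           marker_fraction = p$marker_fraction,
                           top_fraction = p$top_fraction)
        colnames(px$sample_scores) <- program_id(
          ct, seq_len(ncol(px$sample_scores)))
        px$sample_scores
      })
      proxy <- combine_scores(Filter(Negate(is.null), per_ct))
      transfer <- transfer_validation(proxy, vdata$clinical)
      written <- c(written,
                   write_stage_table(matrix_table(proxy, "sample"),
                                     config$out, "proxy_scores"),
                   write_stage_table(transfer, config$out,
                                     "transfer_validation"))
    }
    list(models = models, ranks = ranks, markers = markers,
         scores = combined, filter = filt, network = net,
         gsea = gsea_tab, module_enrichment = mod_enrich,
         associations = assoc, transfer = transfer)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(
    package = as.character(utils::packageVersion("gepnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = lapply(
      stats::setNames(nm = c("factorize", "network", "enrich", "transfer")),
      function(s) stage_seed(config$seed, s)
    ),
    params = config$params,
    inputs = input_checksums(config),
    tables = basename(written)
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(result, list(manifest = manifest)))
}

elbow_table <- function(sel, cell_type) {
  data.frame(cell_type = cell_type, k = sel$k_grid, metric = sel$metric,
             chosen = sel$k_grid == sel$chosen_k)
}

matrix_table <- function(m, id_col) {
  out <- data.frame(rownames(m), as.data.frame(as.matrix(m)),
                    check.names = FALSE)
  names(out)[1] <- id_col
  out
}

# TSV with stable column order and 12-significant-digit floats.
write_stage_table <- function(tab, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, 12))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

input_checksums <- function(config) {
  files <- c(
    file.path(config$counts, c("metadata.csv", "clinical.csv")),
    config$gene_sets
  )
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}
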