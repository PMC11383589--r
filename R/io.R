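#' Write a cohort to a plain-text fixture directory
#'
#' Serializes a simulated (or otherwise assembled) cohort in the standard
#' exchange layout: one subdirectory per cell type holding `matrix.mtx`
#' (genes x cells, Matrix Market), `features.tsv` (gene id, gene name) and
#' `barcodes.tsv`, plus top-level `metadata.csv`, `clinical.csv`, `adt.csv`
#' and a `truth.json` ground-truth record when present.  A round trip through
#' [read_counts()] reproduces the counts exactly.
#'
#' @param dataset a `gep_cohort` (or compatible list).
#' @param directory output directory; created if absent.
#' @return invisibly, the directory path.
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  for (ct in names(dataset$counts)) {
    sub <- file.path(directory, ct)
    dir.create(sub, showWarnings = FALSE)
    X <- dataset$counts[[ct]]
    Matrix::writeMM(X, file.path(sub, "matrix.mtx"))
    utils::write.table(
      data.frame(gene_id = rownames(X), gene_name = rownames(X)),
      file.path(sub, "features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    writeLines(colnames(X), file.path(sub, "barcodes.tsv"))
  }
  utils::write.csv(dataset$cell_metadata, file.path(directory, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$clinical, file.path(directory, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$adt)) {
    adt <- data.frame(barcode = colnames(dataset$adt),
                      t(dataset$adt), check.names = FALSE)
    utils::write.csv(adt, file.path(directory, "adt.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    out <- list(
      true_modules = as.list(truth$true_modules),
      true_activity_score = as.list(truth$true_activity_score),
      activity_module = truth$activity_module,
      true_sample_usage = list(
        sample_ids = rownames(truth$true_sample_usage),
        program_ids = colnames(truth$true_sample_usage),
        values = unname(apply(truth$true_sample_usage, 1, as.numeric,
                              simplify = FALSE))
      ),
      anchor_genes = truth$anchor_genes
    )
    jsonlite::write_json(out, file.path(directory, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(directory)
}

#' Read a cohort fixture directory
#'
#' Reads per-cell-type Matrix Market counts with their feature/barcode
#' sidecars and the cohort-level metadata tables written by
#' [write_fixture()] (or any tool using the same layout).  Gzip-compressed
#' `matrix.mtx.gz` files are accepted.  Counts must be nonnegative integers;
#' matrix dimensions must match the sidecar lengths; every barcode must
#' appear in the metadata table.
#'
#' @param directory fixture directory.
#' @return list with `counts` (named list of `dgCMatrix` per cell type),
#'   `cell_metadata`, `clinical` (or `NULL`), `adt` (or `NULL`) and `truth`
#'   (reparsed `truth.json`, or `NULL`).
#' @export
read_counts <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  meta_path <- file.path(directory, "metadata.csv")
  if (!file.exists(meta_path)) stop("missing metadata.csv in ", directory)
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  subdirs <- list.dirs(directory, recursive = FALSE)
  counts <- list()
  for (sub in subdirs) {
    ct <- basename(sub)
    mtx <- file.path(sub, "matrix.mtx")
    if (!file.exists(mtx)) mtx <- file.path(sub, "matrix.mtx.gz")
    if (!file.exists(mtx)) next
    X <- read_mtx(mtx)
    feat <- utils::read.table(file.path(sub, "features.tsv"), sep = "\t",
                              stringsAsFactors = FALSE)
    barcodes <- readLines(file.path(sub, "barcodes.tsv"))
    if (nrow(X) != nrow(feat) || ncol(X) != length(barcodes)) {
      stop(sprintf(
        "dimension mismatch in %s: matrix %d x %d vs %d features, %d barcodes",
        ct, nrow(X), ncol(X), nrow(feat), length(barcodes)
      ))
    }
    if (any(X@x != round(X@x)) || any(X@x < 0)) {
      stop("non-integer or negative values in counts for ", ct)
    }
    missing <- setdiff(barcodes, metadata$barcode)
    if (length(missing) > 0) {
      stop("barcode absent from metadata: ", missing[1])
    }
    dimnames(X) <- list(feat[[1]], barcodes)
    counts[[ct]] <- X
  }
  if (length(counts) == 0) stop("no count matrices found in ", directory)
  clin_path <- file.path(directory, "clinical.csv")
  clinical <- if (file.exists(clin_path)) {
    utils::read.csv(clin_path, stringsAsFactors = FALSE)
  }
  adt_path <- file.path(directory, "adt.csv")
  adt <- NULL
  if (file.exists(adt_path)) {
    tab <- utils::read.csv(adt_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    adt <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(adt) <- tab$barcode
  }
  truth_path <- file.path(directory, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    raw <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    usage <- NULL
    if (!is.null(raw$true_sample_usage)) {
      v <- raw$true_sample_usage$values
      usage <- if (is.matrix(v)) v else do.call(rbind, v)
      dimnames(usage) <- list(raw$true_sample_usage$sample_ids,
                              raw$true_sample_usage$program_ids)
    }
    truth <- list(
      true_modules = unlist(raw$true_modules),
      true_activity_score = unlist(raw$true_activity_score),
      activity_module = raw$activity_module,
      true_sample_usage = usage,
      anchor_genes = raw$anchor_genes
    )
  }
  list(counts = counts, cell_metadata = metadata, clinical = clinical,
       adt = adt, truth = truth)
}

read_mtx <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  X <- Matrix::readMM(con)
  methods::as(methods::as(X, "CsparseMatrix"), "generalMatrix")
}
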