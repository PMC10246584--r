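# Readers and writers: dense CSV/TSV and MatrixMarket count matrices,
# labels, embeddings, training logs and the run manifest.

#' Read a raw count matrix
#'
#' Dense CSV/TSV files are read with cells in rows and genes in columns
#' (first column = cell identifiers, header = gene identifiers); set
#' `transpose = TRUE` for genes-in-rows files. MatrixMarket input expects
#' `path` to name the `.mtx` file with 10x-style sidecar files
#' `<prefix>_barcodes.tsv` and `<prefix>_genes.tsv` next to it (genes in
#' rows, cells in columns, as written by [write_counts()]).
#'
#' @param path File path.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"` (default: guessed from
#'   the extension).
#' @param transpose Set when the dense file stores genes in rows.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "tsv", "mtx")) stop("unsupported format: ", format)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    prefix <- sub("\\.mtx$", "", path)
    genes <- readLines(paste0(prefix, "_genes.tsv"))
    cells <- readLines(paste0(prefix, "_barcodes.tsv"))
    counts <- t(as.matrix(m)) # stored genes x cells
    dimnames(counts) <- list(cells, genes)
    return(count_matrix(counts))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric entries in ", path)
  if (transpose) mat <- t(mat)
  count_matrix(mat)
}

#' Write a count matrix
#'
#' `format = "csv"`/`"tsv"` writes the dense cells x genes table;
#' `format = "mtx"` writes a MatrixMarket triplet file (genes x cells,
#' 10x-style) plus `<prefix>_barcodes.tsv` and `<prefix>_genes.tsv`.
#'
#' @param cm A [count_matrix()] or raw matrix.
#' @param path Output path (extension selects the format unless given).
#' @param format Optional explicit format.
#' @return The paths written, invisibly.
#' @export
write_counts <- function(cm, path, format = NULL) {
  if (!inherits(cm, "count_matrix")) cm <- count_matrix(cm)
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "mtx") {
    prefix <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(t(cm$counts), sparse = TRUE), path)
    writeLines(cm$cell_ids, paste0(prefix, "_barcodes.tsv"))
    writeLines(cm$gene_ids, paste0(prefix, "_genes.tsv"))
    return(invisible(c(path, paste0(prefix, "_barcodes.tsv"),
                       paste0(prefix, "_genes.tsv"))))
  }
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(cm$counts, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write fit results to a directory
#'
#' Deterministic layout: `labels.csv` (cell_id, cluster),
#' `embeddings.csv`, `training_log.csv` and `manifest.yaml` (resolved
#' config, seed, sizes, per-phase epoch counts).
#'
#' @param fit A `scgpcl_fit`.
#' @param outdir Output directory (created if needed).
#' @param force Overwrite existing files.
#' @return Named vector of paths written, invisibly.
#' @export
write_results <- function(fit, outdir, force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(outdir, "labels.csv"),
             embeddings = file.path(outdir, "embeddings.csv"),
             log = file.path(outdir, "training_log.csv"),
             manifest = file.path(outdir, "manifest.yaml"))
  if (!force && any(file.exists(paths))) {
    stop("output files exist in ", outdir, "; use force = TRUE to overwrite")
  }
  utils::write.csv(data.frame(cell_id = names(fit$labels),
                              cluster = unname(fit$labels)),
                   paths["labels"], row.names = FALSE, quote = FALSE)
  emb <- as.data.frame(fit$embeddings)
  names(emb) <- paste0("dim", seq_along(emb))
  utils::write.csv(cbind(cell_id = names(fit$labels), emb),
                   paths["embeddings"], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(fit$log), paths["log"], row.names = FALSE)
  manifest <- list(
    seed = fit$seed, K = fit$K, graph = fit$graph_type,
    n_cells = length(fit$labels),
    pretrain_epochs = sum(fit$log$phase == "pretrain"),
    finetune_epochs = sum(fit$log$phase == "finetune"),
    config = unclass(fit$config))
  yaml::write_yaml(manifest, paths["manifest"])
  invisible(paths)
}

#' Read a labels CSV written by [write_results()]
#'
#' @param path Path to a two-column (cell_id, cluster) CSV.
#' @return Named integer vector of cluster labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.integer(df$cluster), df$cell_id)
}
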