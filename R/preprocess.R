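# Preprocessing: size factors, log-normalization, feature scaling, and
# construction of the bipartite cell-gene graph (plus the cell-cell kNN
# ablation graph).

#' Construct a count matrix object
#'
#' Wraps a raw read-count matrix (cells in rows, genes in columns) together
#' with cell/gene identifiers, per-cell library sizes and size factors.
#'
#' @param counts Non-negative integer matrix, cells x genes. A sparse
#'   `Matrix` is accepted and densified.
#' @param cell_ids,gene_ids Optional character identifiers; taken from
#'   `dimnames(counts)` or synthesized when absent.
#' @return An object of class `count_matrix` with fields `counts`,
#'   `cell_ids`, `gene_ids`, `library_sizes`, `size_factors`.
#' @examples
#' cm <- count_matrix(matrix(c(0, 5, 2, 3), 2, 2))
#' cm$size_factors
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at cell ", bad[1], ", gene ", bad[2])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count at cell ", bad[1], ", gene ", bad[2])
  }
  cell_ids <- cell_ids %||% rownames(counts) %||% paste0("cell", seq_len(nrow(counts)))
  gene_ids <- gene_ids %||% colnames(counts) %||% paste0("gene", seq_len(ncol(counts)))
  stopifnot(length(cell_ids) == nrow(counts), length(gene_ids) == ncol(counts))
  dimnames(counts) <- list(cell_ids, gene_ids)
  sf <- compute_size_factors(counts)
  structure(
    list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
         library_sizes = sf$library_sizes, size_factors = sf$size_factors),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes; median library size ", stats::median(x$library_sizes), "\n", sep = "")
  invisible(x)
}

#' Per-cell library sizes and size factors
#'
#' The library size of cell i is its total read count; its size factor is
#' the library size divided by the median library size across cells (median
#' of an even number of cells is the mean of the two middle values).
#'
#' @param counts Non-negative count matrix, cells x genes.
#' @return List with `library_sizes` and `size_factors`, each length-Nc.
#' @examples
#' compute_size_factors(rbind(rep(1, 100), rep(2, 100), rep(3, 100)))$size_factors
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    stop("cell(s) with zero total count: ",
         paste(head(ids[lib == 0], 5), collapse = ", "))
  }
  list(library_sizes = lib, size_factors = lib / stats::median(lib))
}

#' Size-factor normalization followed by log transform
#'
#' Divides each cell's counts by its size factor and applies `log(x + 1)`;
#' zeros map to zeros and the transform is monotone per cell.
#'
#' @param counts Count matrix, cells x genes.
#' @param size_factors Positive per-cell scaling factors.
#' @return Matrix of the same shape.
#' @export
normalize_log <- function(counts, size_factors) {
  stopifnot(all(size_factors > 0), length(size_factors) == nrow(counts))
  log1p(as.matrix(counts) / size_factors)
}

#' Per-gene standard scaling
#'
#' Centers and scales each gene (column) to zero mean and unit variance
#' across cells, using the population standard deviation. Constant genes
#' become all-zero columns rather than dividing by zero.
#'
#' @param x Numeric matrix, cells x genes.
#' @return Scaled matrix `Xc`.
#' @export
scale_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(x^2) - mu^2)
  sdp[sdp < 1e-12] <- Inf # constant gene -> zero column
  sweep(sweep(x, 2, mu, "-"), 2, sdp, "/")
}

#' Build the bipartite cell-gene graph
#'
#' Connects a cell node to a gene node for every nonzero count, with the raw
#' count as edge weight. Cell node features are the normalized, log
#' transformed and scaled expression matrix; gene node features are randomly
#' initialized learnable embeddings, drawn uniformly from
#' \eqn{[-1/\sqrt{F}, 1/\sqrt{F}]}.
#'
#' @param counts Raw count matrix (cells x genes), after gene filtering.
#' @param Xc Cell feature matrix (same shape as `counts`).
#' @param n_gene_features Dimension F of the learnable gene features.
#' @param seed Seed for the gene-feature initializer.
#' @param size_factors Per-cell size factors carried for the ZINB loss.
#' @return `cell_gene_graph` object: sparse weighted adjacency `A`
#'   (cells x genes), `Xc`, `Xg`, size factors and identifiers.
#' @export
build_cell_gene_graph <- function(counts, Xc, n_gene_features = 256, seed = 0,
                                  size_factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == dim(Xc)))
  if (all(counts == 0)) stop("all-zero count matrix yields an empty graph")
  A <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  f <- n_gene_features
  Xg <- withr::with_seed(seed, matrix(
    runif(ncol(counts) * f, -1 / sqrt(f), 1 / sqrt(f)), ncol(counts), f))
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)$size_factors
  structure(
    list(type = "cell_gene", n_cells = nrow(counts), n_genes = ncol(counts),
         A = A, Xc = unname(as.matrix(Xc)), Xg = Xg, n_gene_features = f,
         size_factors = size_factors,
         cell_ids = rownames(counts) %||% paste0("cell", seq_len(nrow(counts))),
         gene_ids = colnames(counts) %||% paste0("gene", seq_len(ncol(counts)))),
    class = "cell_gene_graph"
  )
}

#' @export
print.cell_gene_graph <- function(x, ...) {
  cat("<", x$type, " graph> ", x$n_cells, " cells, ", x$n_genes, " genes, ",
      length(x$A@x), " edges\n", sep = "")
  invisible(x)
}

#' Build the cell-cell k-nearest-neighbor graph (ablation variant)
#'
#' Connects each cell to its `k` most similar cells by Pearson correlation
#' of the scaled feature rows (directed edges). A constant feature row has
#' undefined correlation and is treated as correlation -1 to every other
#' cell. Ties are broken by lowest cell index.
#'
#' @param Xc Cell feature matrix (cells x genes).
#' @param k Number of neighbors, `k < Nc`.
#' @param counts,size_factors Raw counts and size factors carried for the
#'   ZINB reconstruction loss.
#' @return `cell_gene_graph` object of type `"cell_cell"` whose adjacency
#'   `A` is the binary directed kNN matrix (cells x cells).
#' @export
build_cell_cell_knn_graph <- function(Xc, k = 10, counts = NULL,
                                      size_factors = NULL) {
  Xc <- as.matrix(Xc)
  nc <- nrow(Xc)
  stopifnot(k >= 1, k < nc)
  sds <- apply(Xc, 1, stats::sd)
  C <- matrix(-1, nc, nc)
  ok <- sds > 0
  if (any(ok)) C[ok, ok] <- suppressWarnings(stats::cor(t(Xc[ok, , drop = FALSE])))
  diag(C) <- -Inf
  idx <- lapply(seq_len(nc), function(i) {
    # order() is stable: ties go to the lowest index
    order(C[i, ], decreasing = TRUE)[seq_len(k)]
  })
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(nc), each = k), j = unlist(idx), x = 1,
    dims = c(nc, nc))
  if (!is.null(counts) && is.null(size_factors)) {
    size_factors <- compute_size_factors(counts)$size_factors
  }
  structure(
    list(type = "cell_cell", n_cells = nc, n_genes = ncol(Xc),
         A = A, Xc = unname(Xc), Xg = NULL, n_gene_features = 0L,
         counts = if (!is.null(counts)) as.matrix(counts) else NULL,
         size_factors = size_factors,
         cell_ids = rownames(Xc) %||% paste0("cell", seq_len(nc)),
         gene_ids = colnames(Xc) %||% paste0("gene", seq_len(ncol(Xc)))),
    class = "cell_gene_graph"
  )
}

#' Preprocess a count matrix into a model-ready graph
#'
#' Removes all-zero genes (logged via `message()`), computes size factors,
#' log-normalizes, scales per gene, and builds the requested graph.
#'
#' @param cm A [count_matrix()] (or a raw matrix, which is wrapped).
#' @param n_gene_features Gene embedding dimension F.
#' @param graph Either `"cell_gene"` (default) or `"cell_cell"` for the
#'   kNN ablation graph.
#' @param knn_k Neighbors for the cell-cell variant.
#' @param seed Seed for the gene-feature initializer.
#' @return A `cell_gene_graph`.
#' @export
preprocess_counts <- function(cm, n_gene_features = 256,
                              graph = c("cell_gene", "cell_cell"),
                              knn_k = 10, seed = 0) {
  graph <- match.arg(graph)
  if (!inherits(cm, "count_matrix")) cm <- count_matrix(cm)
  keep <- colSums(cm$counts) > 0
  if (!all(keep)) {
    message("removing ", sum(!keep), " all-zero gene(s) before graph construction")
  }
  counts <- cm$counts[, keep, drop = FALSE]
  xn <- normalize_log(counts, cm$size_factors)
  Xc <- scale_features(xn)
  if (graph == "cell_gene") {
    g <- build_cell_gene_graph(counts, Xc, n_gene_features, seed,
                               size_factors = cm$size_factors)
  } else {
    g <- build_cell_cell_knn_graph(Xc, k = knn_k, counts = counts,
                                   size_factors = cm$size_factors)
  }
  g$counts <- unname(counts)
  g
}
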