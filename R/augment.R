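# Stochastic graph augmentation: budgeted type-balanced subgraph sampling
# (HGSampling-style) and feature masking.

#' Sample a subgraph around anchor cells
#'
#' Layer-wise, type-balanced importance sampling. Starting from the anchor
#' cells, `depth` rounds are run; in each round, for each node type, up to
#' `budget` not-yet-selected neighbors of the current frontier are sampled
#' without replacement with probability proportional to the squared
#' per-frontier-node normalized connection weight. The induced subgraph of
#' all selected nodes is returned. Deterministic given `seed`.
#'
#' @param graph A `cell_gene_graph`.
#' @param anchors Cell indices that must appear in the subgraph.
#' @param budget Maximum number of new nodes per type per round.
#' @param depth Number of sampling rounds (0 returns the anchors only).
#' @param seed Integer seed.
#' @return List with `cells`, `genes`: the selected original indices
#'   (anchors first), and `A`: the induced weighted adjacency. For
#'   `cell_cell` graphs `genes` is empty and `A` is cells x cells.
#' @export
sample_subgraph <- function(graph, anchors, budget = 512, depth = 2, seed = 0) {
  if (length(anchors) == 0) stop("`anchors` must be nonempty")
  stopifnot(all(anchors >= 1), all(anchors <= graph$n_cells))
  bipartite <- graph$type == "cell_gene"
  A <- graph$A # cells x genes (or cells x cells)
  withr::with_seed(as.integer(seed), {
    sel_c <- as.integer(anchors)
    sel_g <- integer(0)
    frontier_c <- sel_c
    frontier_g <- integer(0)
    if (depth > 0) for (r in seq_len(depth)) {
      new_g <- integer(0)
      new_c <- integer(0)
      # sample gene-type neighbors of the cell frontier
      if (length(frontier_c) > 0) {
        cand <- if (bipartite) sample_frontier(A, frontier_c, exclude = sel_g, budget = budget)
                else sample_frontier(A, frontier_c, exclude = sel_c, budget = budget)
        if (bipartite) new_g <- cand else new_c <- cand
      }
      # sample cell-type neighbors of the gene frontier (bipartite only)
      if (bipartite && length(frontier_g) > 0) {
        new_c <- sample_frontier(Matrix::t(A), frontier_g, exclude = sel_c,
                                 budget = budget)
      }
      sel_g <- c(sel_g, new_g)
      sel_c <- c(sel_c, new_c)
      frontier_c <- new_c
      frontier_g <- new_g
      if (length(new_c) == 0 && length(new_g) == 0) break
    }
  })
  if (bipartite) {
    Asub <- A[sel_c, sel_g, drop = FALSE]
  } else {
    Asub <- A[sel_c, sel_c, drop = FALSE]
  }
  list(cells = sel_c, genes = sel_g, A = Asub)
}

# Importance-sample up to `budget` new column indices adjacent to `rows`,
# with probability proportional to sum over frontier rows of the squared
# row-normalized edge weight.
sample_frontier <- function(A, rows, exclude, budget) {
  Af <- A[rows, , drop = FALSE]
  rs <- Matrix::rowSums(Af)
  rs[rs == 0] <- 1
  score <- Matrix::colSums((Matrix::Diagonal(x = 1 / rs) %*% Af)^2)
  cand <- which(score > 0)
  cand <- setdiff(cand, exclude)
  if (length(cand) == 0) return(integer(0))
  if (length(cand) <= budget) return(cand)
  cand[sample.int(length(cand), budget, prob = score[cand])]
}

#' Randomly mask feature-matrix entries
#'
#' Zeroes each entry independently with probability `mask_rate`, emulating
#' additional dropout of observed expression. Deterministic given `seed`.
#'
#' @param X Numeric matrix.
#' @param mask_rate Probability in \[0, 1\] of zeroing an entry.
#' @param seed Integer seed.
#' @return Masked matrix with the binary keep-mask in `attr(, "mask")`.
#' @export
mask_features <- function(X, mask_rate, seed = 0) {
  stopifnot(mask_rate >= 0, mask_rate <= 1)
  if (mask_rate == 0) {
    keep <- NULL
    out <- X
  } else {
    keep <- withr::with_seed(as.integer(seed), matrix(
      rbinom(length(X), 1, 1 - mask_rate), nrow(X), ncol(X)))
    out <- X * keep
  }
  attr(out, "mask") <- keep
  out
}

#' Generate two augmented views of the graph
#'
#' Applies `sample_subgraph` then `mask_features` twice with independently
#' derived seeds, yielding the two stochastic views used by the contrastive
#' losses. Anchor cells are guaranteed present in both views.
#'
#' @param graph A `cell_gene_graph`.
#' @param anchors Anchor cell indices (the current batch).
#' @param config A [scgpcl_config()] (uses `mask_rate_cell`, `mask_rate_gene`,
#'   `budget`, `depth`).
#' @param seed Integer seed.
#' @param n_views Number of views (2 for pre-training, 1 for fine-tuning).
#' @return List of views; each view has `cells`, `genes`, `A`, row-normalized
#'   aggregation matrices `Acg`/`Agc`, masked features `Xc`, `Xg`, the gene
#'   keep-mask `mask_g`, and `anchor_pos` (anchor rows within `cells`).
#' @export
make_views <- function(graph, anchors, config = scgpcl_config(), seed = 0,
                       n_views = 2) {
  seeds <- derive_seeds(seed, paste0(c("sub", "mc", "mg"),
                                     rep(seq_len(n_views), each = 3)))
  lapply(seq_len(n_views), function(v) {
    sub <- sample_subgraph(graph, anchors, budget = config$budget,
                           depth = config$depth,
                           seed = seeds[[paste0("sub", v)]])
    Xc <- mask_features(graph$Xc[sub$cells, , drop = FALSE],
                        config$mask_rate_cell, seeds[[paste0("mc", v)]])
    Xg <- NULL; mask_g <- NULL
    if (graph$type == "cell_gene") {
      Xg <- mask_features(graph$Xg[sub$genes, , drop = FALSE],
                          config$mask_rate_gene, seeds[[paste0("mg", v)]])
      mask_g <- attr(Xg, "mask")
    }
    Acg <- row_normalize(sub$A)
    Agc <- row_normalize(Matrix::t(sub$A))
    list(cells = sub$cells, genes = sub$genes, A = sub$A,
         Acg = Acg, Agc = Agc,
         Acg_t = Matrix::t(Acg), Agc_t = Matrix::t(Agc),
         Xc = as.matrix(Xc), Xg = if (!is.null(Xg)) as.matrix(Xg),
         mask_g = mask_g,
         anchor_pos = seq_along(anchors))
  })
}

# Un-augmented "view" of the whole graph: all cells are anchors, no
# sampling, no masking. Used for epoch-level evaluation and final labels.
full_view <- function(graph) {
  list(cells = seq_len(graph$n_cells),
       genes = if (graph$type == "cell_gene") seq_len(graph$n_genes) else integer(0),
       A = graph$A,
       Acg = row_normalize(graph$A),
       Agc = row_normalize(Matrix::t(graph$A)),
       Acg_t = Matrix::t(row_normalize(graph$A)),
       Agc_t = Matrix::t(row_normalize(Matrix::t(graph$A))),
       Xc = graph$Xc, Xg = graph$Xg, mask_g = NULL,
       anchor_pos = seq_len(graph$n_cells))
}
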