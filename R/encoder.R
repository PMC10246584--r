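# Two-layer bipartite GraphSAGE encoder. Each layer updates
#   h_c <- Wc' h_c + Wg Mean_{g in N(c)} h_g
#   h_g <- Wg' h_g + Wc Mean_{c in N(g)} h_c
# with an ELU between the two layers and no activation after the last.
# Neighbor means are unweighted; a node with no neighbors in the sampled
# subgraph aggregates the zero vector, so its self term survives.
#
# The backward pass is hand-derived; see test-gradients.R for the
# finite-difference validation.

#' Initialize encoder and decoder parameters
#'
#' All weight matrices are drawn uniformly from
#' \eqn{[-1/\sqrt{fan_{in}}, 1/\sqrt{fan_{in}}]} (fan-in scaling), seeded
#' and reproducible. Every layer carries a zero-initialized bias (the
#' standard dense-layer convention); the per-gene decoder biases in
#' particular let the ZINB heads express gene base rates without spending
#' bottleneck capacity on them.
#'
#' @param graph A `cell_gene_graph` (provides input dimensions).
#' @param config A [scgpcl_config()] (provides `hidden_dim`, `latent_dim`,
#'   `decoder_hidden`).
#' @param seed Integer seed.
#' @return Named list of parameter matrices (class `scgpcl_params`),
#'   including the learnable gene features `Xg` for cell-gene graphs.
#' @export
init_params <- function(graph, config = scgpcl_config(), seed = 0) {
  ng <- graph$n_genes
  f <- graph$n_gene_features
  d1 <- config$hidden_dim
  d <- config$latent_dim
  dh <- config$decoder_hidden
  stopifnot(d1 > 0, d > 0, dh > 0)
  shapes <- list(
    W1_cs = c(ng, d1), # cell self, layer 1
    W1_gn = c(if (graph$type == "cell_gene") f else ng, d1), # neighbor -> cell
    W2_cs = c(d1, d), W2_gn = c(d1, d),
    Wd = c(d, dh), Wmu = c(dh, ng), Wth = c(dh, ng), Wpi = c(dh, ng)
  )
  if (graph$type == "cell_gene") {
    shapes$W1_gs <- c(f, d1)  # gene self
    shapes$W1_cn <- c(ng, d1) # cell -> gene neighbor
    shapes$W2_gs <- c(d1, d)
    shapes$W2_cn <- c(d1, d)
  }
  seeds <- derive_seeds(seed, names(shapes))
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    a <- 1 / sqrt(sh[1])
    withr::with_seed(seeds[[nm]], matrix(runif(prod(sh), -a, a), sh[1], sh[2]))
  })
  names(params) <- names(shapes)
  # zero-initialized biases (row vectors)
  biases <- list(b1_c = d1, b2_c = d, bd = dh, bmu = ng, bth = ng, bpi = ng)
  if (graph$type == "cell_gene") {
    biases$b1_g <- d1
    biases$b2_g <- d
  }
  for (nm in names(biases)) params[[nm]] <- matrix(0, 1, biases[[nm]])
  if (graph$type == "cell_gene") params$Xg <- graph$Xg
  structure(params, class = "scgpcl_params")
}

# broadcast-add a 1 x k bias row to an n x k matrix (no-op when absent)
add_bias <- function(M, b) {
  if (is.null(b)) return(M)
  M + rep(b, each = nrow(M))
}

# Forward pass over one view. Returns anchor-cell representations and, when
# `keep_cache`, every intermediate needed by encoder_backward().
encode_forward <- function(view, params, keep_cache = FALSE,
                           return_genes = FALSE) {
  bipartite <- !is.null(params$W1_gs)
  Xc <- view$Xc
  if (bipartite) {
    Xg <- params$Xg[view$genes, , drop = FALSE]
    if (!is.null(view$mask_g)) Xg <- Xg * view$mask_g
    Zc1 <- add_bias(Xc %*% params$W1_cs +
                      as.matrix(view$Acg %*% Xg) %*% params$W1_gn, params$b1_c)
    Zg1 <- add_bias(Xg %*% params$W1_gs +
                      as.matrix(view$Agc %*% (Xc %*% params$W1_cn)), params$b1_g)
    Hc1 <- elu(Zc1)
    Hg1 <- elu(Zg1)
    Hc2 <- add_bias(Hc1 %*% params$W2_cs +
                      as.matrix(view$Acg %*% Hg1) %*% params$W2_gn, params$b2_c)
    Hg2 <- if (return_genes) {
      add_bias(Hg1 %*% params$W2_gs +
                 as.matrix(view$Agc %*% Hc1) %*% params$W2_cn, params$b2_g)
    }
  } else {
    # homogeneous cell-cell graph: neighbor aggregation over cells
    Xg <- NULL
    Zc1 <- add_bias(Xc %*% params$W1_cs +
                      as.matrix(view$Acg %*% Xc) %*% params$W1_gn, params$b1_c)
    Hc1 <- elu(Zc1)
    Hg1 <- NULL; Zg1 <- NULL
    Hc2 <- add_bias(Hc1 %*% params$W2_cs +
                      as.matrix(view$Acg %*% Hc1) %*% params$W2_gn, params$b2_c)
    Hg2 <- NULL
  }
  H <- Hc2[view$anchor_pos, , drop = FALSE]
  out <- list(H = H, H_genes = Hg2)
  if (keep_cache) {
    out$cache <- list(view = view, Xc = Xc, Xg = Xg, Zc1 = Zc1, Zg1 = Zg1,
                      Hc1 = Hc1, Hg1 = Hg1, Hc2 = Hc2, bipartite = bipartite)
  }
  out
}

#' Encode a view into cell (and gene) representations
#'
#' @param view A view from [make_views()] (or the full graph).
#' @param params Parameters from [init_params()].
#' @param return_genes Also compute final-layer gene representations.
#' @return List with `H` (anchor cells x latent_dim) and optionally
#'   `H_genes`.
#' @export
encode <- function(view, params, return_genes = FALSE) {
  if (nrow(view$Xc) == 0) stop("empty view")
  encode_forward(view, params, keep_cache = FALSE, return_genes = return_genes)
}

# Backward through the encoder given dH (gradient at the anchor rows of
# Hc2). Accumulates into `grads` (an environment-free named list) and
# returns it. Gradients flow into the weights and, for bipartite graphs,
# into the learnable gene features Xg (respecting the feature mask).
encoder_backward <- function(cache, dH, params, grads) {
  view <- cache$view
  nvc <- nrow(cache$Hc2)
  d <- ncol(cache$Hc2)
  dHc2 <- matrix(0, nvc, d)
  dHc2[view$anchor_pos, ] <- dH
  add <- function(g, nm, val) { g[[nm]] <- (g[[nm]] %||% 0) + val; g }

  if (cache$bipartite) {
    AgHg1 <- as.matrix(view$Acg %*% cache$Hg1)
    grads <- add(grads, "W2_cs", crossprod(cache$Hc1, dHc2))
    grads <- add(grads, "W2_gn", crossprod(AgHg1, dHc2))
    grads <- add(grads, "b2_c", matrix(colSums(dHc2), 1))
    dHc1 <- dHc2 %*% t(params$W2_cs)
    Acg_t <- view$Acg_t %||% Matrix::t(view$Acg)
    dHg1 <- as.matrix(Acg_t %*% (dHc2 %*% t(params$W2_gn)))
    dZc1 <- dHc1 * elu_grad(cache$Zc1)
    dZg1 <- dHg1 * elu_grad(cache$Zg1)
    grads <- add(grads, "b1_c", matrix(colSums(dZc1), 1))
    grads <- add(grads, "b1_g", matrix(colSums(dZg1), 1))
    AcXg <- as.matrix(view$Acg %*% cache$Xg)
    grads <- add(grads, "W1_cs", crossprod(cache$Xc, dZc1))
    grads <- add(grads, "W1_gn", crossprod(AcXg, dZc1))
    grads <- add(grads, "W1_gs", crossprod(cache$Xg, dZg1))
    Agc_t <- view$Agc_t %||% Matrix::t(view$Agc)
    AgXc <- as.matrix(Agc_t %*% dZg1) # nvc x d1
    grads <- add(grads, "W1_cn", crossprod(cache$Xc, AgXc))
    # learnable gene features
    dXg <- as.matrix(Acg_t %*% dZc1) %*% t(params$W1_gn) +
      dZg1 %*% t(params$W1_gs)
    if (!is.null(view$mask_g)) dXg <- dXg * view$mask_g
    dXg_full <- matrix(0, nrow(params$Xg), ncol(params$Xg))
    dXg_full[view$genes, ] <- dXg
    grads <- add(grads, "Xg", dXg_full)
  } else {
    AcHc1 <- as.matrix(view$Acg %*% cache$Hc1)
    grads <- add(grads, "W2_cs", crossprod(cache$Hc1, dHc2))
    grads <- add(grads, "W2_gn", crossprod(AcHc1, dHc2))
    grads <- add(grads, "b2_c", matrix(colSums(dHc2), 1))
    Acg_t <- view$Acg_t %||% Matrix::t(view$Acg)
    dHc1 <- dHc2 %*% t(params$W2_cs) +
      as.matrix(Acg_t %*% (dHc2 %*% t(params$W2_gn)))
    dZc1 <- dHc1 * elu_grad(cache$Zc1)
    grads <- add(grads, "b1_c", matrix(colSums(dZc1), 1))
    AcXc <- as.matrix(view$Acg %*% cache$Xc)
    grads <- add(grads, "W1_cs", crossprod(cache$Xc, dZc1))
    grads <- add(grads, "W1_gn", crossprod(AcXc, dZc1))
  }
  grads
}
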