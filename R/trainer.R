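# Training orchestration: batching, the Adam optimizer, the pre-training
# loop (contrastive + ZINB) with ARI-based convergence, and the DEC-style
# fine-tuning loop with label-change-based convergence.

#' Training configuration
#'
#' All tunable hyperparameters of the method. Defaults follow the method's
#' reference settings; smaller widths/budgets are appropriate for
#' desk-scale data (see the methods vignette).
#'
#' @param n_batch Anchor cells per batch (Nb).
#' @param lambda1,lambda2 Pre-training balance coefficients for the
#'   instance-wise and prototypical losses; `lambda2` defaults to
#'   `lambda1 / 20`.
#' @param lambda3 Fine-tuning ZINB coefficient.
#' @param tau Contrastive temperature.
#' @param Ks Cluster counts for the multi-granularity prototype k-means;
#'   `NULL` means `c(K, 2K, 3K)` for the user-supplied `K`.
#' @param mask_rate_cell,mask_rate_gene Feature masking rates.
#' @param budget,depth Subgraph-sampling budget per node type and rounds.
#' @param hidden_dim,latent_dim Encoder layer widths.
#' @param decoder_hidden Width of the shared decoder hidden layer.
#' @param n_gene_features Learnable gene-feature dimension F.
#' @param alpha Student's-t degrees of freedom for soft assignments.
#' @param r ARI threshold for pre-training convergence.
#' @param tol Label-change fraction threshold for fine-tuning convergence.
#' @param max_pretrain_epochs,max_finetune_epochs Epoch caps.
#' @param lr Adam learning rate.
#' @param knn_k Neighbors for the cell-cell ablation graph.
#' @param preset `"default"` keeps the reference widths (hidden 256,
#'   latent 128, decoder 256, F 256, budget 512); `"desk"` switches to the
#'   smaller single-CPU widths used for the package's scaled-down
#'   benchmark runs (hidden 64, latent 32, decoder 64, F 64, budget 256,
#'   epoch caps 30/20). Explicit arguments override the preset.
#' @return List of class `scgpcl_config`.
#' @export
scgpcl_config <- function(n_batch = 256, lambda1 = 1.0, lambda2 = lambda1 / 20,
                          lambda3 = 1.0, tau = 0.5, Ks = NULL,
                          mask_rate_cell = 0.2, mask_rate_gene = 0.2,
                          budget = 512, depth = 2,
                          hidden_dim = 256, latent_dim = 128,
                          decoder_hidden = 256, n_gene_features = 256,
                          alpha = 1, r = 0.99, tol = 0.001,
                          max_pretrain_epochs = 100,
                          max_finetune_epochs = 100, lr = 1e-3, knn_k = 10,
                          preset = c("default", "desk")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  cfg$preset <- NULL
  if (preset == "desk") {
    desk <- list(hidden_dim = 64, latent_dim = 32, decoder_hidden = 64,
                 n_gene_features = 64, budget = 256,
                 max_pretrain_epochs = 30, max_finetune_epochs = 20)
    supplied <- names(match.call())[-1]
    for (nm in setdiff(names(desk), supplied)) cfg[[nm]] <- desk[[nm]]
  }
  stopifnot(cfg$n_batch >= 2, cfg$lambda1 >= 0, cfg$lambda2 >= 0,
            cfg$lambda3 >= 0, cfg$tau > 0, cfg$r >= 0, cfg$r <= 1,
            cfg$tol >= 0, cfg$lr > 0)
  structure(cfg, class = "scgpcl_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- batching --------------------------------------------------------------

# Shuffle cells into ceiling(Nc / Nb) batches covering every cell once.
make_batches <- function(n_cells, n_batch, seed) {
  idx <- withr::with_seed(as.integer(seed), sample.int(n_cells))
  unname(split(idx, ceiling(seq_along(idx) / n_batch)))
}

# ---- per-batch losses (forward + analytic backward) ------------------------

# Pre-training loss and gradients for one batch given already-built views
# and epoch-level prototypes. Exposed internally so the gradient-check
# tests can finite-difference it.
pretrain_batch_loss <- function(params, graph, anchors, views, protos,
                                config, with_grad = TRUE) {
  counts_b <- graph$counts[anchors, , drop = FALSE]
  sf_b <- graph$size_factors[anchors]
  enc <- lapply(views, encode_forward, params = params, keep_cache = with_grad)
  H1 <- enc[[1]]$H; H2 <- enc[[2]]$H
  ins <- instance_loss(H1, H2, config$tau, with_grad = with_grad)
  pro <- prototype_loss(H1, protos, config$tau, rows = anchors,
                        with_grad = with_grad)
  zinb <- lapply(enc, function(e)
    decode_zinb(e$H, params, sf_b, keep_cache = with_grad))
  l_z <- vapply(zinb, function(z) zinb_nll(counts_b, z), numeric(1))
  l_ins <- if (with_grad) ins$loss else ins
  l_pro <- if (with_grad) pro$loss else pro
  loss <- pretrain_loss(l_ins, l_pro, l_z, config$lambda1, config$lambda2)
  if (!with_grad) {
    return(list(loss = loss, l_ins = l_ins, l_pro = l_pro, l_zinb = mean(l_z)))
  }
  grads <- list()
  dH <- list(config$lambda1 * ins$dH1 + config$lambda2 * pro$dH1,
             config$lambda1 * ins$dH2)
  for (v in 1:2) {
    zg <- zinb_nll_grad(counts_b, zinb[[v]])
    bk <- decode_zinb_backward(zinb[[v]], 0.5 * zg$dM, 0.5 * zg$dTheta,
                               0.5 * zg$dPi, params, grads)
    grads <- bk$grads
    grads <- encoder_backward(enc[[v]]$cache, dH[[v]] + bk$dH, params, grads)
  }
  list(loss = loss, l_ins = l_ins, l_pro = l_pro, l_zinb = mean(l_z),
       grads = grads)
}

# Fine-tuning loss and gradients for one batch: KL clustering loss against
# the fixed epoch-level target rows plus the lambda3-weighted ZINB loss of
# the single augmented view. `params$C` holds the trainable centroids.
finetune_batch_loss <- function(params, graph, anchors, view, P_batch,
                                config, with_grad = TRUE) {
  counts_b <- graph$counts[anchors, , drop = FALSE]
  sf_b <- graph$size_factors[anchors]
  enc <- encode_forward(view, params, keep_cache = with_grad)
  H1 <- enc$H
  Q <- soft_assign(H1, params$C, config$alpha)
  l_clu <- cluster_kl_loss(P_batch, Q)
  zinb <- decode_zinb(H1, params, sf_b, keep_cache = with_grad)
  l_z <- zinb_nll(counts_b, zinb)
  loss <- finetune_loss(l_clu, l_z, config$lambda3)
  if (!with_grad) return(list(loss = loss, l_cluster = l_clu, l_zinb = l_z))
  kg <- cluster_kl_grad(P_batch, Q, H1, params$C, config$alpha)
  grads <- list(C = kg$dC)
  zg <- zinb_nll_grad(counts_b, zinb)
  bk <- decode_zinb_backward(zinb, config$lambda3 * zg$dM,
                             config$lambda3 * zg$dTheta,
                             config$lambda3 * zg$dPi, params, grads)
  grads <- bk$grads
  grads <- encoder_backward(enc$cache, kg$dH + bk$dH, params, grads)
  list(loss = loss, l_cluster = l_clu, l_zinb = l_z, grads = grads)
}

# Feature-masked but otherwise full view of the graph (epoch-level
# augmentation for prototypes / target distributions).
masked_full_view <- function(graph, fullv, config, seed) {
  seeds <- derive_seeds(seed, c("mc", "mg"))
  v <- fullv
  Xc <- mask_features(graph$Xc, config$mask_rate_cell, seeds[["mc"]])
  v$Xc <- as.matrix(Xc)
  if (graph$type == "cell_gene") {
    Xg <- mask_features(graph$Xg, config$mask_rate_gene, seeds[["mg"]])
    v$Xg <- as.matrix(Xg)
    v$mask_g <- attr(Xg, "mask")
  }
  v
}

# ---- pre-training ----------------------------------------------------------

#' Pre-train the encoder and decoder
#'
#' Each epoch shuffles all cells into `ceiling(Nc / Nb)` anchor batches;
#' each batch builds two augmented views, encodes them, and takes one Adam
#' step on the combined pre-training loss. Cluster prototypes are
#' recomputed once per epoch from view-2 representations of all cells.
#' After each epoch, k-means on the un-augmented representations yields
#' labels; training stops when the ARI between consecutive epochs' labels
#' exceeds the threshold `r`, or at the epoch cap.
#'
#' @param graph A preprocessed `cell_gene_graph`.
#' @param K User-supplied number of clusters.
#' @param config A [scgpcl_config()].
#' @param seed Integer seed controlling all randomness.
#' @return List with `params`, the per-epoch `log` (tibble), and the final
#'   epoch's k-means `labels`.
#' @export
pretrain <- function(graph, K, config = scgpcl_config(), seed = 0) {
  stopifnot(K >= 2)
  Ks <- config$Ks %||% c(K, 2 * K, 3 * K)
  if (any(Ks > graph$n_cells)) stop("each prototype K must be <= n_cells")
  top <- derive_seeds(seed, c("params", paste0("ep", seq_len(config$max_pretrain_epochs))))
  params <- init_params(graph, config, top[["params"]])
  state <- adam_init(params)
  fullv <- full_view(graph)
  labels_prev <- NULL
  log <- list()
  final_labels <- NULL
  for (epoch in seq_len(config$max_pretrain_epochs)) {
    es <- derive_seeds(top[[paste0("ep", epoch)]],
                       c("shuffle", "v2mask", "proto", "kmeans", "batch"))
    v2 <- masked_full_view(graph, fullv, config, es[["v2mask"]])
    H2_all <- encode_forward(v2, params)$H
    protos <- compute_prototypes(H2_all, Ks, es[["proto"]])
    batches <- make_batches(graph$n_cells, config$n_batch, es[["shuffle"]])
    bseeds <- derive_seeds(es[["batch"]], paste0("b", seq_along(batches)))
    ep <- c(l_ins = 0, l_pro = 0, l_zinb = 0, loss = 0)
    for (b in seq_along(batches)) {
      anchors <- batches[[b]]
      views <- make_views(graph, anchors, config, bseeds[[b]], n_views = 2)
      res <- pretrain_batch_loss(params, graph, anchors, views, protos, config)
      if (!is.finite(res$loss)) {
        stop("non-finite pre-training loss at epoch ", epoch, ", batch ", b)
      }
      upd <- adam_step(params, res$grads, state, config$lr)
      params <- upd$params; state <- upd$state
      ep <- ep + c(res$l_ins, res$l_pro, res$l_zinb, res$loss)
    }
    ep <- ep / length(batches)
    H_full <- encode_forward(fullv, params)$H
    labels <- seeded_kmeans(H_full, K, es[["kmeans"]])$cluster
    drift <- if (is.null(labels_prev)) NA_real_ else ari(labels_prev, labels)
    log[[epoch]] <- tibble::tibble(phase = "pretrain", epoch = epoch,
                                   l_ins = ep[1], l_pro = ep[2],
                                   l_zinb = ep[3], loss = ep[4],
                                   ari_drift = drift,
                                   label_change = NA_real_)
    final_labels <- labels
    if (!is.na(drift) && drift > config$r) break
    labels_prev <- labels
  }
  list(params = params, log = do.call(rbind, log), labels = final_labels)
}

# ---- fine-tuning -----------------------------------------------------------

#' Fine-tune with DEC-style self-training
#'
#' Cluster centroids are initialized by a single k-means run on the
#' pre-trained un-augmented representations and never re-fit (they are
#' updated only by gradients of the KL clustering loss). Each epoch fixes
#' the sharpened target distribution P computed from all cells on a
#' feature-masked view, then optimizes the fine-tuning loss over the batch
#' schedule. Training stops when the fraction of cells changing hard label
#' between consecutive epochs falls below `tol`.
#'
#' @param graph A preprocessed `cell_gene_graph`.
#' @param pretrained Result of [pretrain()].
#' @param K Number of clusters.
#' @param config A [scgpcl_config()].
#' @param seed Integer seed.
#' @return List with final `labels` (from Q on the un-augmented graph),
#'   `embeddings`, `Q`, `params` (including centroids `C`) and `log`.
#' @export
finetune <- function(graph, pretrained, K, config = scgpcl_config(), seed = 0) {
  stopifnot(K >= 2)
  top <- derive_seeds(seed, c("init", paste0("ep", seq_len(config$max_finetune_epochs))))
  params <- pretrained$params
  fullv <- full_view(graph)
  H_full <- encode_forward(fullv, params)$H
  km <- seeded_kmeans(H_full, K, top[["init"]])
  params$C <- km$centers
  state <- adam_init(params)
  labels_prev <- NULL
  log <- list()
  labels <- NULL
  for (epoch in seq_len(config$max_finetune_epochs)) {
    es <- derive_seeds(top[[paste0("ep", epoch)]],
                       c("shuffle", "vmask", "batch"))
    vt <- masked_full_view(graph, fullv, config, es[["vmask"]])
    H_aug <- encode_forward(vt, params)$H
    Q_all <- soft_assign(H_aug, params$C, config$alpha)
    P_all <- target_distribution(Q_all)
    stopifnot(max(abs(rowSums(Q_all) - 1)) < 1e-8,
              max(abs(rowSums(P_all) - 1)) < 1e-8)
    batches <- make_batches(graph$n_cells, config$n_batch, es[["shuffle"]])
    bseeds <- derive_seeds(es[["batch"]], paste0("b", seq_along(batches)))
    ep <- c(l_cluster = 0, l_zinb = 0, loss = 0)
    for (b in seq_along(batches)) {
      anchors <- batches[[b]]
      view <- make_views(graph, anchors, config, bseeds[[b]], n_views = 1)[[1]]
      res <- finetune_batch_loss(params, graph, anchors, view,
                                 P_all[anchors, , drop = FALSE], config)
      if (!is.finite(res$loss)) {
        stop("non-finite fine-tuning loss at epoch ", epoch, ", batch ", b)
      }
      upd <- adam_step(params, res$grads, state, config$lr)
      params <- upd$params; state <- upd$state
      ep <- ep + c(res$l_cluster, res$l_zinb, res$loss)
    }
    ep <- ep / length(batches)
    H_eval <- encode_forward(fullv, params)$H
    Q_eval <- soft_assign(H_eval, params$C, config$alpha)
    labels <- max.col(Q_eval)
    change <- if (is.null(labels_prev)) NA_real_ else mean(labels_prev != labels)
    log[[epoch]] <- tibble::tibble(phase = "finetune", epoch = epoch,
                                   l_ins = NA_real_, l_pro = NA_real_,
                                   l_zinb = ep[2], loss = ep[3],
                                   ari_drift = NA_real_,
                                   label_change = change)
    log[[epoch]]$l_cluster <- ep[1]
    if (!is.na(change) && change < config$tol) { labels_prev <- labels; break }
    labels_prev <- labels
  }
  H_final <- encode_forward(fullv, params)$H
  Q_final <- soft_assign(H_final, params$C, config$alpha)
  list(labels = max.col(Q_final), embeddings = H_final, Q = Q_final,
       params = params, log = do.call(rbind, log))
}

# ---- end-to-end ------------------------------------------------------------

#' Cluster cells end to end
#'
#' Preprocesses a raw count matrix, pre-trains the graph contrastive
#' encoder, fine-tunes with the clustering loss, and returns hard labels
#' from the soft assignments on the un-augmented graph. Fully
#' deterministic given `seed`.
#'
#' @param counts Raw count matrix (cells x genes) or a [count_matrix()].
#' @param K Number of clusters (>= 2).
#' @param config A [scgpcl_config()].
#' @param seed Integer seed for all randomness.
#' @param graph Graph variant: `"cell_gene"` (default) or the
#'   `"cell_cell"` kNN ablation graph.
#' @return Object of class `scgpcl_fit` with `labels`, `embeddings`, `Q`,
#'   `log`, `config`, `K`, `seed`.
#' @export
fit_scgpcl <- function(counts, K, config = scgpcl_config(), seed = 0,
                       graph = c("cell_gene", "cell_cell")) {
  graph <- match.arg(graph)
  if (K < 2) stop("K must be at least 2")
  seeds <- derive_seeds(seed, c("graph", "pretrain", "finetune"))
  g <- preprocess_counts(counts, n_gene_features = config$n_gene_features,
                         graph = graph, knn_k = config$knn_k,
                         seed = seeds[["graph"]])
  pre <- pretrain(g, K, config, seeds[["pretrain"]])
  fin <- finetune(g, pre, K, config, seeds[["finetune"]])
  structure(
    list(labels = stats::setNames(fin$labels, g$cell_ids),
         embeddings = fin$embeddings, Q = fin$Q,
         log = rbind(fill_cols(pre$log), fill_cols(fin$log)),
         params = fin$params, config = config, K = K, seed = seed,
         graph_type = graph, cell_ids = g$cell_ids),
    class = "scgpcl_fit")
}

fill_cols <- function(df) {
  if (!"l_cluster" %in% names(df)) df$l_cluster <- NA_real_
  df[, c("phase", "epoch", "loss", "l_ins", "l_pro", "l_zinb", "l_cluster",
         "ari_drift", "label_change")]
}

#' @export
print.scgpcl_fit <- function(x, ...) {
  cat("<scgpcl_fit> ", length(x$labels), " cells, K = ", x$K,
      "; epochs: ", sum(x$log$phase == "pretrain"), " pretrain + ",
      sum(x$log$phase == "finetune"), " finetune\n", sep = "")
  cat("cluster sizes:\n")
  print(table(x$labels))
  invisible(x)
}

#' Alias for the end-to-end clustering pipeline
#'
#' @inheritParams fit_scgpcl
#' @return Integer cluster labels (one per cell).
#' @export
fit_predict <- function(counts, K, config = scgpcl_config(), seed = 0,
                        graph = "cell_gene") {
  fit_scgpcl(counts, K, config, seed, graph)$labels
}
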