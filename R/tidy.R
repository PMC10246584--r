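# broom-style accessors and plots for fitted objects.

#' Tidy a fitted clustering
#'
#' @param x A `scgpcl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per cell: `cell_id`, `cluster`, and the
#'   maximum soft-assignment probability `confidence`.
#' @export
tidy.scgpcl_fit <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_ids,
                 cluster = unname(x$labels),
                 confidence = apply(x$Q, 1, max))
}

#' One-row summary of a fitted clustering
#'
#' @param x A `scgpcl_fit`.
#' @param ... Unused.
#' @return Tibble with cell/cluster counts, epochs per phase and final
#'   losses.
#' @export
glance.scgpcl_fit <- function(x, ...) {
  fin <- x$log[x$log$phase == "finetune", ]
  tibble::tibble(
    n_cells = length(x$labels),
    K = x$K,
    n_clusters_used = length(unique(x$labels)),
    pretrain_epochs = sum(x$log$phase == "pretrain"),
    finetune_epochs = nrow(fin),
    final_loss = x$log$loss[nrow(x$log)],
    final_label_change = if (nrow(fin)) fin$label_change[nrow(fin)] else NA_real_
  )
}

#' Training-curve plot
#'
#' Loss components per epoch across the pre-training and fine-tuning
#' phases.
#'
#' @param object A `scgpcl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scgpcl_fit <- function(object, ...) {
  df <- as.data.frame(object$log)
  long <- do.call(rbind, lapply(c("loss", "l_ins", "l_pro", "l_zinb", "l_cluster"),
                                function(nm) {
    data.frame(phase = df$phase, epoch = df$epoch, component = nm,
               value = df[[nm]])
  }))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free") +
    ggplot2::labs(x = "epoch", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Embedding scatter plot
#'
#' First two principal components of the learned cell embeddings, colored
#' by cluster.
#'
#' @param fit A `scgpcl_fit`.
#' @return A ggplot object.
#' @export
plot_embeddings <- function(fit) {
  pc <- stats::prcomp(fit$embeddings, rank. = 2)
  df <- data.frame(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                   cluster = factor(fit$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::theme_minimal()
}
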