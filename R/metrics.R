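# Clustering evaluation: NMI, ARI, Hungarian-matched clustering accuracy,
# macro/micro F1. Labels are arbitrary identifiers; every metric is
# invariant to relabeling of either vector.

contingency <- function(truth, pred) {
  table(factor(truth), factor(pred))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized by default by
#' the arithmetic mean of their entropies; `"geometric"`, `"min"` and
#' `"max"` normalizations are also available.
#'
#' @param truth,pred Label vectors of equal length.
#' @param normalization One of `"arithmetic"`, `"geometric"`, `"min"`,
#'   `"max"`.
#' @return Value in \[0, 1\].
#' @export
nmi <- function(truth, pred,
                normalization = c("arithmetic", "geometric", "min", "max")) {
  assert_same_length(truth, pred)
  normalization <- match.arg(normalization)
  ct <- contingency(truth, pred)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  expected <- outer(pi_, pj_)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / expected[nz]))
  h1 <- entropy_nat(pi_)
  h2 <- entropy_nat(pj_)
  denom <- switch(normalization,
                  arithmetic = (h1 + h2) / 2,
                  geometric = sqrt(h1 * h2),
                  min = min(h1, h2),
                  max = max(h1, h2))
  if (denom == 0) return(if (mi == 0 && h1 == 0 && h2 == 0) 1 else 0)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie pair-counting ARI from the contingency table; 1 for
#' identical partitions, ~0 for independent ones, negative when agreement
#' is below chance.
#'
#' @param truth,pred Label vectors of equal length.
#' @return Value in \[-1, 1\].
#' @export
ari <- function(truth, pred) {
  assert_same_length(truth, pred)
  ct <- contingency(truth, pred)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Minimum-cost assignment (Jonker-Volgenant style O(n^3) with potentials).
# `cost` must have nrow <= ncol; returns the matched column per row.
hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(m)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) match_col[p[j + 1]] <- j
  match_col
}

# Optimal one-to-one matching of predicted clusters to truth classes.
# Returns a list: `map` (pred level index -> truth level index, 0 when the
# pred cluster is matched to a padding class) and the factor levels.
match_clusters <- function(truth, pred) {
  tl <- sort(unique(truth)); pl <- sort(unique(pred))
  ct <- matrix(0, length(pl), length(tl))
  for (i in seq_along(pl)) for (j in seq_along(tl)) {
    ct[i, j] <- sum(pred == pl[i] & truth == tl[j])
  }
  k <- max(dim(ct))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  assign <- hungarian_min(max(sq) - sq)
  map <- assign[seq_along(pl)]
  map[map > length(tl)] <- 0L # matched to a padding (nonexistent) class
  list(map = map, truth_levels = tl, pred_levels = pl, table = ct)
}

#' Hungarian-matched clustering accuracy
#'
#' Maximum fraction of correctly labeled cells over all one-to-one
#' matchings between predicted clusters and true classes.
#'
#' @param truth,pred Label vectors of equal length.
#' @return Value in \[0, 1\].
#' @export
clustering_accuracy <- function(truth, pred) {
  assert_same_length(truth, pred)
  mc <- match_clusters(truth, pred)
  correct <- 0
  for (i in seq_along(mc$pred_levels)) {
    if (mc$map[i] > 0) correct <- correct + mc$table[i, mc$map[i]]
  }
  correct / length(truth)
}

#' Macro- and micro-averaged F1 after cluster matching
#'
#' Predicted clusters are first matched one-to-one to truth classes
#' (Hungarian matching on the confusion matrix); per-class F1 scores are
#' then averaged unweighted (macro) or pooled (micro). For single-label
#' predictions the micro-F1 equals the matched accuracy. Predicted
#' clusters left unmatched (more clusters than classes) contribute
#' zero-F1 classes to the macro average.
#'
#' @param truth,pred Label vectors of equal length.
#' @return Named list with `macro` and `micro`.
#' @export
macro_micro_f1 <- function(truth, pred) {
  assert_same_length(truth, pred)
  mc <- match_clusters(truth, pred)
  # relabel predictions into truth space (0 = unmatched cluster)
  relab <- mc$map[match(pred, mc$pred_levels)]
  truth_idx <- match(truth, mc$truth_levels)
  f1s <- numeric(0)
  tp_tot <- fp_tot <- fn_tot <- 0
  for (j in seq_along(mc$truth_levels)) {
    tp <- sum(relab == j & truth_idx == j)
    fp <- sum(relab == j & truth_idx != j)
    fn <- sum(relab != j & truth_idx == j)
    f1s <- c(f1s, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
    tp_tot <- tp_tot + tp; fp_tot <- fp_tot + fp; fn_tot <- fn_tot + fn
  }
  # predicted clusters matched to no class: zero-F1 classes whose
  # predictions count as false positives (keeps micro-F1 equal to the
  # matched accuracy)
  n_unmatched <- sum(mc$map == 0)
  if (n_unmatched > 0) {
    f1s <- c(f1s, rep(0, n_unmatched))
    fp_tot <- fp_tot + sum(relab == 0)
  }
  list(macro = mean(f1s),
       micro = 2 * tp_tot / (2 * tp_tot + fp_tot + fn_tot))
}

#' Clustering metric report
#'
#' @param truth,pred Label vectors of equal length.
#' @return One-row tibble with `nmi`, `ari`, `ca`, `macro_f1`, `micro_f1`.
#' @examples
#' evaluate_clustering(c(0, 0, 1, 1), c(1, 1, 0, 0))
#' @export
evaluate_clustering <- function(truth, pred) {
  f1 <- macro_micro_f1(truth, pred)
  tibble::tibble(
    nmi = nmi(truth, pred),
    ari = ari(truth, pred),
    ca = clustering_accuracy(truth, pred),
    macro_f1 = f1$macro,
    micro_f1 = f1$micro
  )
}
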