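# Independent brute-force oracles used to validate the package's
# vectorized implementations, plus small fixture builders. These are
# deliberately written as naive loops straight from the definitions.

cos_o <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# InfoNCE instance loss via explicit double loops (symmetrized).
oracle_instance_loss <- function(H1, H2, tau) {
  nb <- nrow(H1)
  term <- function(A, B, i) {
    # anchor A[i,]; same-view negatives A[-i,], other view B (all rows)
    num <- exp(cos_o(A[i, ], B[i, ]) / tau)
    den <- 0
    for (j in seq_len(nb)) {
      if (j != i) den <- den + exp(cos_o(A[i, ], A[j, ]) / tau)
      den <- den + exp(cos_o(A[i, ], B[j, ]) / tau)
    }
    log(num / den)
  }
  tot <- 0
  for (i in seq_len(nb)) tot <- tot + term(H1, H2, i) + term(H2, H1, i)
  -tot / (2 * nb)
}

# Prototypical loss via loops.
oracle_prototype_loss <- function(H1, protos, tau, rows = seq_len(nrow(H1))) {
  nb <- nrow(H1)
  tt <- length(protos$Ks)
  tot <- 0
  for (i in seq_len(nb)) {
    for (t in seq_len(tt)) {
      Z <- protos$prototypes[[t]]
      a <- protos$assign[rows[i], t]
      den <- sum(sapply(seq_len(nrow(Z)), function(s)
        exp(cos_o(H1[i, ], Z[s, ]) / tau)))
      tot <- tot + log(exp(cos_o(H1[i, ], Z[a, ]) / tau) / den)
    }
  }
  -tot / (nb * tt)
}

# ZINB negative log-likelihood via direct pmf evaluation.
oracle_zinb_pmf <- function(x, pi, mu, theta) {
  nb <- exp(lgamma(x + theta) - lgamma(theta) - lgamma(x + 1)) *
    (theta / (theta + mu))^theta * (mu / (theta + mu))^x
  pi * (x == 0) + (1 - pi) * nb
}

oracle_zinb_nll <- function(counts, zinb) {
  tot <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    tot <- tot - log(oracle_zinb_pmf(counts[i, j], zinb$Pi[i, j],
                                     zinb$M[i, j], zinb$Theta[i, j]))
  }
  tot / length(counts)
}

# KL divergence via loops.
oracle_kl <- function(P, Q) {
  tot <- 0
  for (i in seq_len(nrow(P))) for (k in seq_len(ncol(P))) {
    if (P[i, k] > 0) tot <- tot + P[i, k] * log(P[i, k] / Q[i, k])
  }
  tot
}

# NMI via a base-2 contingency computation (base cancels in the ratio).
oracle_nmi <- function(truth, pred) {
  ct <- table(truth, pred)
  n <- sum(ct)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    if (ct[i, j] > 0) {
      mi <- mi + ct[i, j] / n *
        log2(ct[i, j] * n / (sum(ct[i, ]) * sum(ct[, j])))
    }
  }
  h <- function(x) { p <- x / sum(x); p <- p[p > 0]; -sum(p * log2(p)) }
  h1 <- h(rowSums(ct)); h2 <- h(colSums(ct))
  if (h1 + h2 == 0) return(1)
  if (mi == 0 && (h1 == 0 || h2 == 0)) return(0)
  mi / ((h1 + h2) / 2)
}

# ARI from raw pair counts (a different closed form than the package's
# contingency-sum formula).
oracle_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c2 <- d <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) c2 <- c2 + 1
    else if (!st && sp) b <- b + 1
    else d <- d + 1
  }
  num <- 2 * (a * d - b * c2)
  den <- (a + b) * (b + d) + (a + c2) * (c2 + d)
  if (den == 0) return(0)
  num / den
}

# all permutations of 1..n (recursive; n <= 6 in tests)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# clustering accuracy by exhaustive search over one-to-one matchings
oracle_accuracy <- function(truth, pred) {
  tl <- sort(unique(truth)); pl <- sort(unique(pred))
  k <- max(length(tl), length(pl))
  best <- 0
  for (perm in all_perms(k)) {
    correct <- 0
    for (i in seq_along(pl)) {
      if (perm[i] <= length(tl)) {
        correct <- correct + sum(pred == pl[i] & truth == tl[perm[i]])
      }
    }
    best <- max(best, correct)
  }
  best / length(truth)
}

# minimum assignment cost by exhaustive search
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (perm in all_perms(ncol(cost))) {
    s <- sum(cost[cbind(seq_len(n), perm[seq_len(n)])])
    best <- min(best, s)
  }
  best
}

# small random non-degenerate representation matrices
rand_H <- function(n, d, seed) {
  withr::with_seed(seed, matrix(rnorm(n * d), n, d))
}

# tiny preprocessed graph fixture
tiny_graph <- function(n_cells = 12, n_genes = 10, seed = 3, groups = 2,
                       sigma = 0.5) {
  sim <- simulate_counts(sim_config(
    n_cells = n_cells, n_genes = n_genes,
    group_probs = rep(1 / groups, groups), de_fac_scale = sigma,
    lib_loc = 4, seed = seed))
  g <- suppressMessages(preprocess_counts(sim$counts, n_gene_features = 3,
                                          seed = 1))
  list(graph = g, sim = sim)
}

tiny_config <- function(...) {
  defaults <- list(n_batch = 6, hidden_dim = 5, latent_dim = 4,
                   decoder_hidden = 5, n_gene_features = 3, budget = 20)
  do.call(scgpcl_config, utils::modifyList(defaults, list(...)))
}

# generic finite-difference gradient checker over named parameter lists
numeric_grad_check <- function(lossfn, params, grads, n_per = 4, seed = 1,
                               eps = 1e-5) {
  worst <- 0
  withr::with_seed(seed, {
    for (nm in names(grads)) {
      p <- params[[nm]]
      idx <- sample(length(p), min(n_per, length(p)))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
        ana <- grads[[nm]][i]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num), abs(ana)))
      }
    }
  })
  worst
}
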