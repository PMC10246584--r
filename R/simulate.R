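# Splat-style synthetic scRNA-seq count simulation with group structure,
# log-normal differential-expression factors, gamma-Poisson noise and
# logistic dropout, plus the three benchmark regimes (dropout strength,
# signal strength, cluster imbalance).

#' Simulation configuration
#'
#' Parameters of the Splat-style generative recipe. Defaults not fixed by
#' the benchmark regimes follow the published Splat defaults.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param group_probs Probability of each group (sums to 1).
#' @param de_prob Fraction of genes differentially expressed per group.
#' @param de_fac_scale Sigma of the log-normal multiplicative DE factors
#'   (the "signal strength": larger values separate groups more).
#' @param dropout_mid,dropout_shape Midpoint and shape of the logistic
#'   dropout curve on the log mean; `dropout_mid = NA` disables the
#'   dropout stage entirely.
#' @param lib_loc,lib_scale Log-normal library-size parameters.
#' @param mean_shape,mean_rate Gamma parameters of the gene base means.
#' @param bcv Biological coefficient of variation (gamma-Poisson
#'   overdispersion scale).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000, n_genes = 5000,
                       group_probs = rep(1 / 3, 3),
                       de_prob = 0.1, de_fac_scale = 0.3,
                       dropout_mid = NA, dropout_shape = -1,
                       lib_loc = 11, lib_scale = 0.2,
                       mean_shape = 0.6, mean_rate = 0.3,
                       bcv = 0.18, seed = 0) {
  if (any(group_probs < 0) || abs(sum(group_probs) - 1) > 1e-8) {
    stop("`group_probs` must be a probability vector summing to 1")
  }
  stopifnot(n_cells >= 2, n_genes >= 1, de_prob >= 0, de_prob <= 1,
            de_fac_scale >= 0, lib_scale >= 0, mean_shape > 0,
            mean_rate > 0, bcv > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a grouped scRNA-seq count matrix
#'
#' Splat-style recipe: gene base means are Gamma(mean_shape, mean_rate);
#' per group a `de_prob` fraction of genes receives multiplicative DE
#' factors \eqn{\exp(N(0, \sigma))} (symmetric in log space, so up- and
#' down-regulation are equally likely); cell library sizes are log-normal;
#' per-cell expected counts are the library size times the group's
#' normalized expression proportions; counts are gamma-Poisson with
#' dispersion \eqn{1/bcv^2}; finally each entry is zeroed with probability
#' \eqn{1/(1 + e^{-shape(\ln\lambda - mid)})} evaluated at its pre-noise
#' mean \eqn{\lambda} (skipped when `dropout_mid` is `NA`). Deterministic
#' given the seed.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (cells x genes integer matrix), `labels`
#'   (integer group per cell) and the `config`.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  G <- length(cfg$group_probs)
  withr::with_seed(as.integer(cfg$seed), {
    labels <- sample.int(G, cfg$n_cells, replace = TRUE, prob = cfg$group_probs)
    base_mean <- rgamma(cfg$n_genes, shape = cfg$mean_shape, rate = cfg$mean_rate)
    # per-group multiplicative DE factors
    fac <- matrix(1, G, cfg$n_genes)
    for (g in seq_len(G)) {
      de <- runif(cfg$n_genes) < cfg$de_prob
      fac[g, de] <- exp(rnorm(sum(de), 0, cfg$de_fac_scale))
    }
    group_mean <- sweep(fac, 2, base_mean, "*") # G x Ng
    group_prop <- group_mean / rowSums(group_mean)
    lib <- rlnorm(cfg$n_cells, cfg$lib_loc, cfg$lib_scale)
    lambda <- lib * group_prop[labels, , drop = FALSE] # Nc x Ng cell-gene means
    # gamma-Poisson (NB) noise with dispersion 1/bcv^2
    shape <- 1 / cfg$bcv^2
    noisy <- matrix(rgamma(length(lambda), shape = shape,
                           scale = as.vector(lambda) / shape),
                    cfg$n_cells, cfg$n_genes)
    counts <- matrix(rpois(length(noisy), as.vector(noisy)),
                     cfg$n_cells, cfg$n_genes)
    if (!is.na(cfg$dropout_mid)) {
      p_drop <- 1 / (1 + exp(-cfg$dropout_shape *
                               (log(lambda) - cfg$dropout_mid)))
      keep <- matrix(rbinom(length(p_drop), 1, 1 - as.vector(p_drop)),
                     cfg$n_cells, cfg$n_genes)
      counts <- counts * keep
    }
  })
  dimnames(counts) <- list(paste0("cell", seq_len(cfg$n_cells)),
                           paste0("gene", seq_len(cfg$n_genes)))
  list(counts = counts, labels = labels, config = cfg)
}

#' Group probabilities from a minimum retention rate
#'
#' Geometric interpolation from the majority to the minority cluster so
#' that the minority/majority probability ratio equals `rate`, normalized
#' to sum to 1 and sorted descending. `rate = 1` gives balanced groups.
#'
#' @param G Number of groups (>= 2).
#' @param rate Minimum retention rate in (0, 1].
#' @return Probability vector of length `G`.
#' @examples
#' group_probs_from_retention(2, 0.5) # 2/3, 1/3
#' @export
group_probs_from_retention <- function(G, rate) {
  stopifnot(G >= 2)
  if (!(rate > 0 && rate <= 1)) stop("`rate` must be in (0, 1]")
  p <- rate^((seq_len(G) - 1) / (G - 1))
  p / sum(p)
}

#' Benchmark simulation regimes
#'
#' Three stress regimes for cluster recovery: case 1 varies dropout
#' strength (`level` = dropout midpoint in \[0, 2\]) at 3000 cells, 3
#' balanced groups, 5000 genes, sigma 0.3; case 2 varies signal strength
#' (`level` = de_fac_scale) at the same geometry with dropout midpoint 0;
#' case 3 varies cluster imbalance (`level` = minimum retention rate) at
#' 1500 cells, 6 groups, sigma 0.4. `n_cells`/`n_genes` may be overridden
#' for scaled-down runs.
#'
#' @param case 1, 2 or 3.
#' @param level Regime-specific level (see above).
#' @param seed Integer seed.
#' @param n_cells,n_genes Optional size overrides.
#' @return A [sim_config()].
#' @export
simulation_case <- function(case, level, seed = 0, n_cells = NULL,
                            n_genes = NULL) {
  if (!case %in% 1:3) stop("unknown simulation case: ", case)
  cfg <- switch(as.character(case),
    "1" = sim_config(n_cells = n_cells %||% 3000, n_genes = n_genes %||% 5000,
                     group_probs = rep(1 / 3, 3), de_fac_scale = 0.3,
                     dropout_mid = level, dropout_shape = -1, seed = seed),
    "2" = sim_config(n_cells = n_cells %||% 3000, n_genes = n_genes %||% 5000,
                     group_probs = rep(1 / 3, 3), de_fac_scale = level,
                     dropout_mid = 0, dropout_shape = -1, seed = seed),
    "3" = sim_config(n_cells = n_cells %||% 1500, n_genes = n_genes %||% 5000,
                     group_probs = group_probs_from_retention(6, level),
                     de_fac_scale = 0.4, dropout_mid = 0, dropout_shape = -1,
                     seed = seed)
  )
  cfg
}
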