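# Pre-training losses: instance-wise InfoNCE, prototypical contrastive
# loss over k-means prototypes, and the ZINB reconstruction loss.
# Every *_grad() routine is hand-derived and validated against finite
# differences in the test suite.

cosine_sim <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' InfoNCE term for one anchor cell
#'
#' \eqn{l = \log \frac{e^{sim(h_i, h_i')/\tau}}
#' {\sum_{j \ne i} e^{sim(h_i, \tilde h_j)/\tau} + \sum_j e^{sim(h_i, \tilde h_j')/\tau}}}
#' with cosine similarity. `H_intra` holds the same-view representations of
#' the *other* cells (row i already excluded); `H_inter` holds all
#' other-view representations, including the positive `hi_prime`.
#'
#' @param hi,hi_prime Anchor representations from the two views.
#' @param H_intra Matrix of same-view negatives (may have zero rows).
#' @param H_inter Matrix of other-view representations.
#' @param tau Temperature, > 0.
#' @return Scalar log-ratio (non-positive contribution enters the loss with
#'   a minus sign).
#' @export
infonce_pair <- function(hi, hi_prime, H_intra, H_inter, tau = 0.5) {
  stopifnot(tau > 0)
  if (sum(hi^2) == 0 || sum(hi_prime^2) == 0) {
    stop("cosine similarity undefined for a zero vector")
  }
  num <- exp(cosine_sim(hi, hi_prime) / tau)
  s_intra <- if (NROW(H_intra) > 0) {
    sum(exp(apply(H_intra, 1, cosine_sim, a = hi) / tau))
  } else 0
  s_inter <- sum(exp(apply(H_inter, 1, cosine_sim, a = hi) / tau))
  log(num / (s_intra + s_inter))
}

#' Instance-wise contrastive loss over a batch
#'
#' Symmetrized InfoNCE across the two augmented views:
#' \eqn{L_{Ins} = -\frac{1}{2N_b}\sum_i [l(h_i, h_i') + l(h_i', h_i)]}.
#'
#' @param H1,H2 Anchor-cell representations from views 1 and 2 (Nb x d).
#' @param tau Temperature.
#' @param with_grad Also return gradients `dH1`, `dH2`.
#' @return Scalar loss, or list `(loss, dH1, dH2)` when `with_grad`.
#' @export
instance_loss <- function(H1, H2, tau = 0.5, with_grad = FALSE) {
  stopifnot(all(dim(H1) == dim(H2)), tau > 0)
  nb <- nrow(H1)
  U <- l2_normalize_rows(H1)
  V <- l2_normalize_rows(H2)
  S11 <- tcrossprod(U)
  S22 <- tcrossprod(V)
  S12 <- tcrossprod(U, V)
  E11 <- exp(S11 / tau); diag(E11) <- 0
  E22 <- exp(S22 / tau); diag(E22) <- 0
  E12 <- exp(S12 / tau)
  D1 <- rowSums(E11) + rowSums(E12)
  D2 <- rowSums(E22) + colSums(E12)
  l1 <- diag(S12) / tau - log(D1)
  l2 <- diag(S12) / tau - log(D2)
  loss <- -mean(l1 + l2) / 2
  if (!with_grad) return(loss)

  cc <- 1 / (2 * nb * tau)
  G11 <- cc * E11 / D1
  G22 <- cc * E22 / D2
  G12 <- cc * (E12 / D1 + sweep(E12, 2, D2, "/"))
  diag(G12) <- diag(G12) - 2 * cc
  dU <- (G11 + t(G11)) %*% U + G12 %*% V
  dV <- (G22 + t(G22)) %*% V + t(G12) %*% U
  list(loss = loss,
       dH1 = grad_through_l2norm(H1, U, dU),
       dH2 = grad_through_l2norm(H2, V, dV))
}

# d loss / dH for H -> U = H / ||rows||, given dU.
grad_through_l2norm <- function(H, U, dU) {
  nrm <- sqrt(rowSums(H^2))
  (dU - U * rowSums(U * dU)) / nrm
}

#' Cluster prototypes from multi-granularity k-means
#'
#' Runs k-means `T = length(Ks)` times on the view-2 cell representations
#' with different cluster counts, storing centroids (prototypes) and the
#' cell-to-prototype assignment per clustering. Deterministic given `seed`.
#'
#' @param H2 Cell representations (N x d).
#' @param Ks Integer vector of cluster counts, each `<= N`.
#' @param seed Integer seed.
#' @return `prototype_set`: list with `Ks`, `prototypes` (list of K_t x d
#'   centroid matrices) and `assign` (N x T integer matrix).
#' @export
compute_prototypes <- function(H2, Ks, seed = 0) {
  n <- nrow(H2)
  if (any(Ks > n)) stop("each K_t must be <= the number of cells")
  seeds <- derive_seeds(seed, paste0("km", seq_along(Ks)))
  prot <- vector("list", length(Ks))
  assign <- matrix(0L, n, length(Ks))
  for (t in seq_along(Ks)) {
    km <- seeded_kmeans(H2, Ks[t], seeds[[t]])
    prot[[t]] <- km$centers
    assign[, t] <- km$cluster
  }
  structure(list(Ks = Ks, prototypes = prot, assign = assign),
            class = "prototype_set")
}

# stats::kmeans behind a fixed seed; nstart > 1 for stability. When k
# reaches the number of distinct points, each point is its own center.
seeded_kmeans <- function(X, k, seed, nstart = 10) {
  X <- as.matrix(X)
  distinct <- unique(X)
  if (k >= nrow(distinct)) {
    # every distinct point is its own center
    cl <- match(apply(X, 1, paste, collapse = "\r"),
                apply(distinct, 1, paste, collapse = "\r"))
    return(list(cluster = cl, centers = distinct))
  }
  withr::with_seed(as.integer(seed),
                   suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart,
                                                  iter.max = 100)))
}

#' Prototypical contrastive loss
#'
#' For each cell and each clustering granularity t, a softmax
#' cross-entropy over cosine similarities to the K_t prototypes, with the
#' assigned prototype as the positive:
#' \eqn{L_{Pro} = -\frac{1}{N_b}\sum_i \frac{1}{T}\sum_t
#' \log \frac{e^{sim(h_i, z_{a(i)}^t)/\tau}}{\sum_s e^{sim(h_i, z_s^t)/\tau}}}.
#' Prototypes are treated as constants (no gradient flows into them).
#'
#' @param H1 View-1 anchor representations (Nb x d).
#' @param protos A [compute_prototypes()] result.
#' @param tau Temperature.
#' @param rows Row indices of the anchors within the prototype assignment
#'   (defaults to `1:Nb` for epoch-level prototype sets of the same cells).
#' @param with_grad Also return `dH1`.
#' @return Scalar loss, or list `(loss, dH1)`.
#' @export
prototype_loss <- function(H1, protos, tau = 0.5, rows = NULL,
                           with_grad = FALSE) {
  if (length(protos$prototypes) == 0) stop("empty prototype set")
  nb <- nrow(H1)
  rows <- rows %||% seq_len(nb)
  U <- l2_normalize_rows(H1)
  total <- 0
  dU <- if (with_grad) matrix(0, nrow(U), ncol(U))
  tt <- length(protos$Ks)
  for (t in seq_len(tt)) {
    Z <- l2_normalize_rows(protos$prototypes[[t]])
    a <- protos$assign[rows, t]
    logits <- tcrossprod(U, Z) / tau
    m <- apply(logits, 1, max)
    lse <- m + log(rowSums(exp(logits - m)))
    pos <- logits[cbind(seq_len(nb), a)]
    total <- total - sum(pos - lse) / (nb * tt)
    if (with_grad) {
      P <- exp(logits - lse)
      P[cbind(seq_len(nb), a)] <- P[cbind(seq_len(nb), a)] - 1
      dU <- dU + (P %*% Z) / (nb * tt * tau)
    }
  }
  if (!with_grad) return(total)
  list(loss = total, dH1 = grad_through_l2norm(H1, U, dU))
}

#' ZINB parameter heads of the decoder
#'
#' A shared hidden layer `D = ELU(H Wd)` feeds three linear heads:
#' mean \eqn{M = S \exp(D W_\mu)} (size-factor scaled), dispersion
#' \eqn{\Theta = \exp(D W_\theta)}, dropout probability
#' \eqn{\Pi = sigmoid(D W_\pi)}. Mean and dispersion are clamped to
#' `[1e-4, 1e6]` and \eqn{\Pi} to `[1e-6, 1 - 1e-6]` for numerical safety.
#'
#' @param H Cell representations (Nb x d).
#' @param params `scgpcl_params` (uses `Wd`, `Wmu`, `Wth`, `Wpi`).
#' @param size_factors Per-cell size factors (length Nb).
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `M`, `Theta`, `Pi` (each Nb x Ng) and optionally
#'   `cache`.
#' @export
decode_zinb <- function(H, params, size_factors, keep_cache = FALSE) {
  stopifnot(length(size_factors) == nrow(H))
  Zd <- add_bias(H %*% params$Wd, params$bd)
  Dh <- elu(Zd)
  Omu <- add_bias(Dh %*% params$Wmu, params$bmu)
  Oth <- add_bias(Dh %*% params$Wth, params$bth)
  Opi <- add_bias(Dh %*% params$Wpi, params$bpi)
  M0 <- size_factors * exp(Omu)
  M <- clamp(M0, 1e-4, 1e6)
  Th0 <- exp(Oth)
  Theta <- clamp(Th0, 1e-4, 1e6)
  Pi0 <- sigmoid(Opi)
  Pi <- clamp(Pi0, 1e-6, 1 - 1e-6)
  if (any(!is.finite(M)) || any(!is.finite(Theta)) || any(!is.finite(Pi))) {
    stop("non-finite ZINB parameters in the decoder output")
  }
  out <- list(M = M, Theta = Theta, Pi = Pi)
  if (keep_cache) {
    out$cache <- list(H = H, Zd = Zd, Dh = Dh,
                      pass_M = (M0 > 1e-4 & M0 < 1e6),
                      pass_Th = (Th0 > 1e-4 & Th0 < 1e6),
                      pass_Pi = (Pi0 > 1e-6 & Pi0 < 1 - 1e-6))
  }
  out
}

# log NB(x | mu, theta) via log-gamma
nb_log_pmf <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' ZINB negative log-likelihood
#'
#' Mean over all entries of \eqn{-\log ZINB(x \mid \pi, \mu, \theta)} with
#' \eqn{ZINB = \pi \delta_0(x) + (1 - \pi) NB(x \mid \mu, \theta)}. Zero
#' counts are evaluated with a log-sum-exp of \eqn{\log\pi} and
#' \eqn{\log(1-\pi) + \log NB(0)} to avoid underflow.
#'
#' @param counts Non-negative integer matrix (Nb x Ng).
#' @param zinb A [decode_zinb()] result (or list with `M`, `Theta`, `Pi`).
#' @return Scalar mean NLL.
#' @export
zinb_nll <- function(counts, zinb) {
  x <- as.matrix(counts)
  if (any(x < 0)) stop("negative counts")
  mu <- zinb$M; theta <- zinb$Theta; pi <- zinb$Pi
  iz <- x == 0
  ll <- x # container
  # zero entries: logsumexp(log pi, log(1-pi) + log NB(0))
  thz <- theta[iz]; muz <- mu[iz]; piz <- pi[iz]
  a <- log(piz)
  b <- log1p(-piz) + thz * (log(thz) - log(thz + muz))
  m <- pmax(a, b)
  ll[iz] <- m + log(exp(a - m) + exp(b - m))
  ip <- !iz
  ll[ip] <- log1p(-pi[ip]) + nb_log_pmf(x[ip], mu[ip], theta[ip])
  -mean(ll)
}

# Per-entry gradients of the mean ZINB NLL wrt (M, Theta, Pi), already
# scaled by 1/(Nb*Ng).
zinb_nll_grad <- function(counts, zinb) {
  x <- as.matrix(counts)
  mu <- zinb$M; theta <- zinb$Theta; pi <- zinb$Pi
  n <- length(x)
  iz <- x == 0
  ip <- !iz
  dM <- x; dTheta <- x; dPi <- x # containers
  # positive-count branch
  xp <- x[ip]; mup <- mu[ip]; thp <- theta[ip]; pip <- pi[ip]
  tmp <- thp + mup
  dM[ip] <- -(xp / mup - (xp + thp) / tmp)
  dTheta[ip] <- -(digamma(xp + thp) - digamma(thp) +
                    log(thp) + 1 - log(tmp) - (xp + thp) / tmp)
  dPi[ip] <- 1 / (1 - pip)
  # zero-count branch
  muz <- mu[iz]; thz <- theta[iz]; piz <- pi[iz]
  tmz <- thz + muz
  e0 <- exp(thz * (log(thz) - log(tmz))) # NB(0)
  B <- (1 - piz) * e0
  Z <- piz + B
  w <- B / Z
  dM[iz] <- w * thz / tmz
  dTheta[iz] <- -w * (log(thz) + 1 - log(tmz) - thz / tmz)
  dPi[iz] <- -(1 - e0) / Z
  list(dM = dM / n, dTheta = dTheta / n, dPi = dPi / n)
}

# Backward through the decoder heads; accumulates into `grads` and returns
# list(grads = ..., dH = ...).
decode_zinb_backward <- function(zinb, dM, dTheta, dPi, params, grads) {
  ch <- zinb$cache
  dOmu <- dM * zinb$M * ch$pass_M
  dOth <- dTheta * zinb$Theta * ch$pass_Th
  dOpi <- dPi * zinb$Pi * (1 - zinb$Pi) * ch$pass_Pi
  add <- function(g, nm, val) { g[[nm]] <- (g[[nm]] %||% 0) + val; g }
  grads <- add(grads, "Wmu", crossprod(ch$Dh, dOmu))
  grads <- add(grads, "Wth", crossprod(ch$Dh, dOth))
  grads <- add(grads, "Wpi", crossprod(ch$Dh, dOpi))
  grads <- add(grads, "bmu", matrix(colSums(dOmu), 1))
  grads <- add(grads, "bth", matrix(colSums(dOth), 1))
  grads <- add(grads, "bpi", matrix(colSums(dOpi), 1))
  dDh <- tcrossprod(dOmu, params$Wmu) + tcrossprod(dOth, params$Wth) +
    tcrossprod(dOpi, params$Wpi)
  dZd <- dDh * elu_grad(ch$Zd)
  grads <- add(grads, "Wd", crossprod(ch$H, dZd))
  grads <- add(grads, "bd", matrix(colSums(dZd), 1))
  list(grads = grads, dH = tcrossprod(dZd, params$Wd))
}

#' Combined pre-training objective
#'
#' \eqn{L_{Pre} = \lambda_1 L_{Ins} + \lambda_2 L_{Pro} + L_{ZINB}^{Pre}}
#' where \eqn{L_{ZINB}^{Pre}} is the average of the per-view ZINB losses.
#'
#' @param l_ins,l_pro Scalar contrastive losses.
#' @param l_zinb_views Numeric vector of per-view ZINB losses (averaged).
#' @param lambda1,lambda2 Balance coefficients (defaults 1.0 and 0.05;
#'   the prototypical weight is kept 20x smaller to limit confirmation
#'   bias from early mis-assigned prototypes).
#' @return Scalar loss.
#' @export
pretrain_loss <- function(l_ins, l_pro, l_zinb_views, lambda1 = 1.0,
                          lambda2 = 0.05) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  lambda1 * l_ins + lambda2 * l_pro + mean(l_zinb_views)
}
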