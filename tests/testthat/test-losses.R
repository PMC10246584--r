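test_that("InfoNCE matches hand-computed values and degenerate cases", {
  # single pair: denominator equals numerator
  expect_equal(infonce_pair(c(1, 2), c(1, 2), matrix(0, 0, 2),
                            matrix(c(1, 2), 1)), 0)
  # two orthogonal cells, identical views, tau = 1
  H <- rbind(c(1, 0), c(0, 1))
  l <- infonce_pair(H[1, ], H[1, ], H[2, , drop = FALSE], H, tau = 1)
  expect_equal(l, 1 - log(exp(1) + 2), tolerance = 1e-12)
  expect_equal(instance_loss(H, H, tau = 1), log(exp(1) + 2) - 1,
               tolerance = 1e-12)
  # cosine scale invariance
  expect_equal(instance_loss(5 * H, 5 * H, tau = 1),
               instance_loss(H, H, tau = 1))
  # Nb = 1
  expect_equal(instance_loss(matrix(c(1, 1), 1), matrix(c(1, 1), 1), 0.5), 0)
  expect_error(instance_loss(matrix(0, 2, 2), matrix(1, 2, 2), 0.5), "zero")
  expect_error(instance_loss(matrix(1, 2, 2), matrix(1, 3, 2), 0.5))
})

test_that("instance loss equals the brute-force oracle and is rotation invariant", {
  for (seed in 1:4) {
    H1 <- rand_H(8, 4, seed)
    H2 <- rand_H(8, 4, seed + 100)
    tau <- c(0.2, 0.5, 1, 2)[seed]
    l <- instance_loss(H1, H2, tau)
    expect_equal(l, oracle_instance_loss(H1, H2, tau), tolerance = 1e-6)
    expect_gte(l, 0)
    # invariance under a global rotation of all vectors
    R <- qr.Q(qr(rand_H(4, 4, seed + 50)))
    expect_equal(instance_loss(H1 %*% R, H2 %*% R, tau), l, tolerance = 1e-8)
  }
})

test_that("prototype computation covers the degenerate K cases", {
  H <- rand_H(10, 3, 1)
  p1 <- compute_prototypes(H, Ks = 1, seed = 2)
  expect_equal(p1$prototypes[[1]], t(colMeans(H)), ignore_attr = TRUE,
               tolerance = 1e-12)
  # two well-separated clouds: centroids equal the cloud means
  H2 <- rbind(rand_H(5, 3, 3) * 0.01, rand_H(5, 3, 4) * 0.01 + 50)
  p2 <- compute_prototypes(H2, Ks = 2, seed = 2)
  ctr <- p2$prototypes[[1]][order(p2$prototypes[[1]][, 1]), ]
  expect_equal(ctr, rbind(colMeans(H2[1:5, ]), colMeans(H2[6:10, ])),
               tolerance = 1e-6, ignore_attr = TRUE)
  # K = N: every cell its own prototype
  pn <- compute_prototypes(H, Ks = 10, seed = 1)
  expect_equal(sort(pn$assign[, 1]), 1:10)
  expect_error(compute_prototypes(H, Ks = 11, seed = 1), "<=")
})

test_that("prototype loss matches hand example and brute-force oracle", {
  # lone prototype: loss is 0
  protos1 <- structure(list(Ks = 1, prototypes = list(matrix(c(1, 1), 1)),
                            assign = matrix(1L, 1, 1)),
                       class = "prototype_set")
  expect_equal(prototype_loss(matrix(c(2, 0), 1), protos1, tau = 1), 0)
  # one cell at (1,0) against prototypes (1,0) and (0,1), tau = 1
  protos2 <- structure(list(Ks = 2,
                            prototypes = list(rbind(c(1, 0), c(0, 1))),
                            assign = matrix(1L, 1, 1)),
                       class = "prototype_set")
  expect_equal(prototype_loss(matrix(c(1, 0), 1), protos2, tau = 1),
               log(exp(1) + 1) - 1, tolerance = 1e-12)
  # oracle equivalence on random instances with T up to 3
  for (seed in 1:4) {
    H <- rand_H(6, 4, seed)
    Hp <- rand_H(6, 4, seed + 10)
    protos <- compute_prototypes(Hp, Ks = c(2, 3, 4), seed = seed)
    l <- prototype_loss(H, protos, tau = 0.7)
    expect_equal(l, oracle_prototype_loss(H, protos, tau = 0.7),
                 tolerance = 1e-8)
    expect_gte(l, 0)
  }
  expect_error(prototype_loss(rand_H(2, 2, 1),
                              structure(list(Ks = integer(0),
                                             prototypes = list(),
                                             assign = matrix(0, 2, 0)),
                                        class = "prototype_set"), 0.5),
               "empty")
})

test_that("ZINB decoder heads have the right ranges and identities", {
  H <- rand_H(4, 3, 2)
  params <- list(Wd = matrix(0, 3, 2), Wmu = matrix(0, 2, 5),
                 Wth = matrix(0, 2, 5), Wpi = matrix(0, 2, 5))
  z <- decode_zinb(H, params, size_factors = rep(2, 4))
  # all-zero decoder: M = s_i * exp(0), Pi = sigmoid(0)
  expect_equal(z$M, matrix(2, 4, 5))
  expect_equal(z$Theta, matrix(1, 4, 5))
  expect_equal(z$Pi, matrix(0.5, 4, 5))
  # random weights: ranges
  params2 <- lapply(list(Wd = c(3, 2), Wmu = c(2, 5), Wth = c(2, 5),
                         Wpi = c(2, 5)),
                    function(s) rand_H(s[1], s[2], sum(s)))
  z2 <- decode_zinb(H, params2, runif(4, 0.5, 2))
  expect_true(all(z2$M > 0) && all(z2$Theta > 0))
  expect_true(all(z2$Pi > 0 & z2$Pi < 1))
})

test_that("ZINB NLL reproduces closed-form values and the NB limit", {
  zp <- function(pi, mu, th) list(Pi = matrix(pi), M = matrix(mu),
                                  Theta = matrix(th))
  # x = 0 with pure zero inflation
  expect_equal(zinb_nll(matrix(0), zp(1 - 1e-6, 1, 1)), 0, tolerance = 1e-5)
  # x = 0, pi = 0.5, mu = theta = 1: ZINB = 0.75
  expect_equal(zinb_nll(matrix(0), zp(0.5, 1, 1)), -log(0.75),
               tolerance = 1e-12)
  # x = 2, pi = 0, mu = 2, theta = 1: NB = 4/27
  expect_equal(zinb_nll(matrix(2), zp(1e-12, 2, 1)), -log(4 / 27),
               tolerance = 1e-6)
  # pi -> 0 converges to the pure NB NLL
  x <- matrix(0:5, 1)
  mu <- matrix(1.7, 1, 6); th <- matrix(2.3, 1, 6)
  nb_nll <- -mean(scgpcl:::nb_log_pmf(x, mu, th))
  expect_equal(zinb_nll(x, list(Pi = matrix(1e-12, 1, 6), M = mu, Theta = th)),
               nb_nll, tolerance = 1e-9)
  expect_error(zinb_nll(matrix(-1), zp(0.5, 1, 1)), "negative")
})

test_that("ZINB pmf normalizes to 1 over a truncated support", {
  grid <- expand.grid(pi = c(0.01, 0.3, 0.7), mu = c(0.5, 5, 50),
                      theta = c(0.5, 2, 20))
  xs <- 0:2000
  for (r in seq_len(nrow(grid))) {
    total <- sum(oracle_zinb_pmf(xs, grid$pi[r], grid$mu[r], grid$theta[r]))
    expect_gte(total, 1 - 1e-6)
    expect_lte(total, 1 + 1e-9)
    # the package NLL agrees with the oracle pmf on this grid
    x <- matrix(c(0, 1, 7), 1)
    z <- list(Pi = matrix(grid$pi[r], 1, 3), M = matrix(grid$mu[r], 1, 3),
              Theta = matrix(grid$theta[r], 1, 3))
    expect_equal(zinb_nll(x, z), oracle_zinb_nll(x, z), tolerance = 1e-9)
  }
})

test_that("pre-training objective combines components with the balance weights", {
  expect_equal(pretrain_loss(1.0, 2.0, c(0.4, 0.6)), 1.6)
  expect_equal(pretrain_loss(3, 7, c(0.9, 0.1), lambda1 = 0, lambda2 = 0), 0.5)
  expect_equal(pretrain_loss(1, 1, c(0.8, 0.8)), 1 + 0.05 + 0.8)
  expect_error(pretrain_loss(1, 1, c(1, 1), lambda1 = -1), "lambda1")
})
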