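test_that("batch schedule partitions all cells with ceiling arithmetic", {
  b <- scgpcl:::make_batches(10, 4, seed = 1)
  expect_length(b, 3)
  expect_equal(sort(lengths(b), decreasing = TRUE), c(4, 4, 2))
  expect_setequal(unlist(b), 1:10)
  # every cell in exactly one batch across several seeds/sizes
  for (s in 1:5) {
    b2 <- scgpcl:::make_batches(23, 7, seed = s)
    expect_length(b2, ceiling(23 / 7))
    expect_equal(sort(unlist(b2)), 1:23)
  }
})

test_that("label-change fraction equals the brute-force Hamming count", {
  withr::with_seed(2, {
    a <- sample(1:3, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
  })
  frac <- mean(a != b)
  hand <- sum(sapply(seq_along(a), function(i) a[i] != b[i])) / length(a)
  expect_equal(frac, hand)
})

test_that("pre-training runs, logs finite losses, and stops on stable ARI", {
  tg <- tiny_graph(n_cells = 24, n_genes = 15, seed = 8, groups = 2,
                   sigma = 1.0)
  cfg <- tiny_config(n_batch = 8, max_pretrain_epochs = 6, r = 0.99)
  pre <- pretrain(tg$graph, K = 2, cfg, seed = 3)
  expect_true(all(is.finite(pre$log$loss)))
  expect_true(all(is.finite(pre$log$l_ins)))
  expect_lte(nrow(pre$log), 6)
  expect_length(pre$labels, 24)
  # r = 1 never stops early
  cfg2 <- tiny_config(n_batch = 8, max_pretrain_epochs = 3, r = 1)
  pre2 <- pretrain(tg$graph, K = 2, cfg2, seed = 3)
  expect_equal(nrow(pre2$log), 3)
})

test_that("fine-tuning stops when labels stabilize and keeps rows stochastic", {
  tg <- tiny_graph(n_cells = 24, n_genes = 15, seed = 8, groups = 2,
                   sigma = 1.0)
  cfg <- tiny_config(n_batch = 8, max_pretrain_epochs = 2,
                     max_finetune_epochs = 10, tol = 1.0)
  pre <- pretrain(tg$graph, K = 2, cfg, seed = 3)
  fin <- finetune(tg$graph, pre, K = 2, cfg, seed = 4)
  # tol = 1 stops at the second epoch at the latest
  expect_lte(nrow(fin$log), 2)
  expect_equal(rowSums(fin$Q), rep(1, 24), tolerance = 1e-8)
  expect_equal(fin$labels, max.col(fin$Q))
})

test_that("centroids are initialized once and then moved only by gradients", {
  tg <- tiny_graph(n_cells = 20, n_genes = 12, seed = 5, groups = 2,
                   sigma = 1.0)
  cfg <- tiny_config(n_batch = 10, max_pretrain_epochs = 2,
                     max_finetune_epochs = 4, tol = 0, lr = 1e-12)
  pre <- pretrain(tg$graph, K = 2, cfg, seed = 3)
  # with a vanishing learning rate the gradient updates are no-ops, so the
  # centroids after fine-tuning must equal the single k-means
  # initialization: they are never re-fit
  fin <- finetune(tg$graph, pre, K = 2, cfg, seed = 4)
  H0 <- scgpcl:::encode_forward(scgpcl:::full_view(tg$graph), pre$params)$H
  km <- scgpcl:::seeded_kmeans(H0, 2, scgpcl:::derive_seeds(4, c("init"))[[1]])
  expect_equal(fin$params$C, km$centers, tolerance = 1e-6)
})

test_that("the full pipeline recovers well-separated groups deterministically", {
  sim <- simulate_counts(sim_config(n_cells = 80, n_genes = 120,
                                    group_probs = rep(1 / 2, 2),
                                    de_fac_scale = 1.2, lib_loc = 8,
                                    seed = 12))
  cfg <- tiny_config(n_batch = 32, hidden_dim = 16, latent_dim = 8,
                     decoder_hidden = 16, budget = 64,
                     max_pretrain_epochs = 8, max_finetune_epochs = 4)
  fit <- fit_scgpcl(sim$counts, K = 2, cfg, seed = 2)
  expect_equal(nmi(sim$labels, fit$labels), 1)
  # determinism: same seed, same labels
  fit2 <- fit_scgpcl(sim$counts, K = 2, cfg, seed = 2)
  expect_identical(fit$labels, fit2$labels)
  expect_error(fit_scgpcl(sim$counts, K = 1, cfg, seed = 1), "K must be")
})

test_that("tidy/glance/autoplot expose the fit in tabular form", {
  sim <- simulate_counts(sim_config(n_cells = 40, n_genes = 60,
                                    group_probs = c(0.5, 0.5),
                                    de_fac_scale = 1.2, lib_loc = 5,
                                    seed = 3))
  cfg <- tiny_config(n_batch = 20, max_pretrain_epochs = 2,
                     max_finetune_epochs = 2)
  fit <- fit_scgpcl(sim$counts, K = 2, cfg, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cell_id", "cluster", "confidence"))
  expect_equal(nrow(td), 40)
  expect_true(all(td$confidence >= 0.5 / 2 & td$confidence <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_cells, 40)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_embeddings(fit), "ggplot")
})
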