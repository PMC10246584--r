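test_that("size factors follow library size / median library size", {
  counts <- rbind(rep(1, 100), rep(2, 100), rep(3, 100))
  sf <- compute_size_factors(counts)
  expect_equal(sf$library_sizes, c(100, 200, 300))
  expect_equal(sf$size_factors, c(0.5, 1.0, 1.5))

  # equal library sizes -> all ones
  expect_equal(compute_size_factors(matrix(2, 4, 5))$size_factors, rep(1, 4))

  # even number of cells: median is the mean of the middle two
  counts4 <- matrix(0, 4, 10)
  counts4[cbind(1:4, 1)] <- c(50, 150, 250, 350)
  expect_equal(compute_size_factors(counts4)$size_factors,
               c(0.25, 0.75, 1.25, 1.75))

  expect_error(compute_size_factors(rbind(c(1, 2), c(0, 0))), "zero total")
})

test_that("log-normalization divides by size factor and is monotone", {
  expect_equal(normalize_log(matrix(10), size_factors = 0.5),
               matrix(log(21)), tolerance = 1e-12)
  expect_equal(normalize_log(matrix(0), 2), matrix(0))
  x <- matrix(c(0, 1, 5, 9), 1)
  expect_equal(normalize_log(x, 1), log1p(x))
  # monotone in counts for fixed size factor
  out <- normalize_log(matrix(0:20, 1), 1.7)
  expect_true(all(diff(as.vector(out)) > 0))
})

test_that("feature scaling gives zero-mean unit-variance columns (population sd)", {
  expect_equal(scale_features(matrix(c(1, 2, 3), 3))[, 1],
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(scale_features(matrix(5, 4, 2)), matrix(0, 4, 2))
  z <- matrix(c(-1, 1, -1, 1), 4) * sqrt(1)
  expect_equal(scale_features(z), z)
  # random matrix: all columns standardized
  x <- rand_H(20, 6, seed = 4)^2
  sc <- scale_features(x)
  expect_equal(colMeans(sc), rep(0, 6), tolerance = 1e-10)
  expect_equal(colMeans(sc^2), rep(1, 6), tolerance = 1e-10)
})

test_that("cell-gene graph has one weighted edge per nonzero count", {
  counts <- rbind(c(0, 5, 0), c(2, 0, 1))
  g <- build_cell_gene_graph(counts, scale_features(log1p(counts)),
                             n_gene_features = 4, seed = 1)
  expect_equal(length(g$A@x), 3)
  expect_equal(as.matrix(g$A), counts, ignore_attr = TRUE)
  expect_true(all(g$A@x > 0))
  expect_equal(dim(g$Xg), c(3, 4))
  expect_true(all(abs(g$Xg) <= 1 / sqrt(4)))

  dense <- matrix(1, 2, 2)
  g2 <- build_cell_gene_graph(dense, dense, 2, 1)
  expect_equal(length(g2$A@x), 4)

  # edge count equals an independent nonzero scan on a random fixture
  sim <- simulate_counts(sim_config(n_cells = 15, n_genes = 12,
                                    group_probs = c(1), lib_loc = 3,
                                    dropout_mid = 1, seed = 5))
  cm <- sim$counts[, colSums(sim$counts) > 0, drop = FALSE]
  g3 <- build_cell_gene_graph(cm, log1p(cm), 2, 1)
  expect_equal(length(g3$A@x), sum(cm != 0))

  expect_error(build_cell_gene_graph(matrix(0, 2, 2), matrix(0, 2, 2), 2),
               "empty graph")
})

test_that("graph edges are invariant to cell reordering up to relabeling", {
  withr::with_seed(7, {
    counts <- matrix(rpois(25, 1.5), 5, 5)
  })
  counts[1, ] <- counts[1, ] + 1 # no all-zero rows
  perm <- c(3, 1, 5, 2, 4)
  g1 <- build_cell_gene_graph(counts, log1p(counts), 2, 1)
  g2 <- build_cell_gene_graph(counts[perm, ], log1p(counts[perm, ]), 2, 1)
  m1 <- as.matrix(g1$A)
  m2 <- as.matrix(g2$A)
  expect_equal(m1[perm, ], m2, ignore_attr = TRUE)
})

test_that("cell-cell kNN graph follows Pearson correlation with tie/constant rules", {
  Xc <- rbind(c(1, 0, 2), c(1, 0.1, 2.1), c(0, 1, -1))
  g <- build_cell_cell_knn_graph(Xc, k = 1)
  A <- as.matrix(g$A)
  expect_equal(which(A[1, ] == 1), 2) # cell 1's neighbor is cell 2
  # cell 3 is anticorrelated with both but slightly less so with cell 2
  expect_equal(which(A[3, ] == 1), 2)

  # identical rows: tie broken by lowest index
  Xi <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  gi <- build_cell_cell_knn_graph(Xi, k = 1)
  expect_equal(which(as.matrix(gi$A)[2, ] == 1), 1)

  # k = Nc - 1 -> complete graph without self loops
  gc <- build_cell_cell_knn_graph(rand_H(6, 4, 2), k = 5)
  Ac <- as.matrix(gc$A)
  expect_equal(diag(Ac), rep(0, 6))
  expect_true(all(Ac[row(Ac) != col(Ac)] == 1))

  # constant row treated as correlation -1 to everyone: picked last
  Xk <- rbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5), c(1.1, 2, 2.9))
  gk <- build_cell_cell_knn_graph(Xk, k = 2)
  expect_equal(sum(as.matrix(gk$A)[1, 3]), 0)
})

test_that("preprocessing removes all-zero genes and reports it", {
  counts <- cbind(c(3, 1, 2), 0, c(0, 2, 5))
  expect_message(g <- preprocess_counts(counts, n_gene_features = 2),
                 "all-zero gene")
  expect_equal(g$n_genes, 2)
  expect_equal(colMeans(g$Xc), rep(0, 2), tolerance = 1e-10)
})

test_that("count_matrix rejects negative and non-integer input", {
  expect_error(count_matrix(matrix(c(1, -2, 3, 4), 2)), "negative count")
  expect_error(count_matrix(matrix(c(1, 2.5, 3, 4), 2)), "non-integer")
})
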