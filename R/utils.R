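# Internal numerical helpers and the seed-derivation scheme.

elu <- function(x) ifelse(x > 0, x, expm1(x))

elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# All randomness flows from one top-level seed: `derive_seeds()` expands it
# into a named vector of independent stream seeds (drawn below 2^31 so they
# are valid R integer seeds). Callers use withr::with_seed(stream, ...) so
# the global RNG state is never left modified.
derive_seeds <- function(seed, names) {
  stopifnot(length(seed) == 1, is.finite(seed))
  s <- withr::with_seed(as.integer(seed),
                        sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(s, names)
}

# Row-normalized sparse aggregation matrix over the *binary* edge pattern:
# neighbor aggregation is an unweighted mean (edge weights only steer the
# subgraph sampling). All-zero rows stay all-zero so a node without
# neighbors aggregates the zero vector.
row_normalize <- function(A) {
  B <- methods::as(methods::as(A != 0, "dMatrix"), "CsparseMatrix")
  rs <- Matrix::rowSums(B)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% B
}

# L2-normalize matrix rows (cosine-similarity preparation); zero rows are
# rejected upstream where cosine similarity is required.
l2_normalize_rows <- function(H) {
  nrm <- sqrt(rowSums(H^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for a zero vector")
  H / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_same_length <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have the same length (",
         length(truth), " vs ", length(pred), ")")
  }
  if (length(truth) == 0) stop("label vectors must be nonempty")
}
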