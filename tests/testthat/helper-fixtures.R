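# Shared fixtures, generated in code. Keep logging quiet during tests.
options(distnorm.log_level = "quiet")

# A skewed log-intensity-like pool, the typical fitting input.
skew_pool <- function(n = 5000, loc = 6, scale = 1.5, alpha = 3, seed = 1) {
  set.seed(seed)
  value_pool(loc + scale * rskewnorm(n, alpha))
}

# Trapezoid integral of the stored density of a model over its support grid.
model_mass <- function(m, n_grid = 10000) {
  x <- seq(m$support[1], m$support[2], length.out = n_grid)
  y <- density(m, x)
  sum((y[-1] + y[-n_grid]) / 2 * diff(x))
}

# Small expression matrix with reproducible values.
toy_matrix <- function(P = 6, S = 3, seed = 1, source_id = NULL) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(P * S, 6, 1.5), P, S), source_id = source_id)
}

# Independent quantile-normalization oracle: per-rank mean of sorted columns,
# ties receiving the mean of the reference values across their tied ranks.
qn_oracle <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}
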