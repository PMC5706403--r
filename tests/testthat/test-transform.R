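test_that("cdf hits its boundary and symmetry values", {
  m <- fit_density(build_histogram(skew_pool(3000, seed = 4)), "fourier")
  expect_equal(cdf(m, m$support[1]), 0)
  expect_lt(abs(cdf(m, m$support[2]) - 1), 1e-6)
  expect_equal(cdf(m, m$support[1] - 10), 0)   # below support
  expect_equal(cdf(m, m$support[2] + 10), 1)   # above support
  std <- make_analytic_model("gaussian", c(0, 1))
  expect_lt(abs(cdf(std, 0) - 0.5), 1e-6)
  expect_error(cdf(std, NA_real_), class = "distnorm_validation_error")
  # non-decreasing in x
  x <- seq(-6, 6, length.out = 500)
  expect_true(all(diff(cdf(std, x)) >= 0))
})

test_that("inverse_cdf inverts the CDF on the support interior", {
  std <- make_analytic_model("gaussian", c(0, 1))
  expect_equal(inverse_cdf(std, 0), -6)
  expect_equal(inverse_cdf(std, 1), 6)
  expect_lt(abs(inverse_cdf(std, 0.5)), 1e-4)
  expect_error(inverse_cdf(std, 1.5), class = "distnorm_validation_error")
  expect_error(inverse_cdf(std, -0.1), class = "distnorm_validation_error")

  # round trip against a fitted model with strictly positive density
  m <- fit_density(build_histogram(skew_pool(5000, seed = 8)), "gaussian")
  x <- seq(m$support[1] + 0.05 * diff(m$support),
           m$support[2] - 0.05 * diff(m$support), length.out = 100)
  expect_lt(max(abs(inverse_cdf(m, cdf(m, x)) - x)), 1e-4)
  # monotone in p
  p <- seq(0, 1, length.out = 200)
  expect_true(all(diff(inverse_cdf(m, p)) >= 0))
})

test_that("mapping through identical models is the identity", {
  m <- fit_density(build_histogram(skew_pool(5000, seed = 2)), "fourier")
  pool <- as.numeric(skew_pool(5000, seed = 2))
  vals <- quantile(pool, seq(0.02, 0.98, length.out = 300), names = FALSE)
  res <- dbnorm_map(vals, m, m)
  expect_lt(max(abs(res$mapped_values - vals)), 1e-4)
  expect_lte(res$max_probability_gap, 1e-6)
})

test_that("gaussian-to-gaussian mapping follows the affine closed form", {
  src <- make_analytic_model("gaussian", c(0, 1))
  tgt <- make_analytic_model("gaussian", c(5, 2))
  res <- dbnorm_map(c(-1, 0, 1), src, tgt)
  expect_lt(max(abs(res$mapped_values - c(3, 5, 7))), 1e-3)
})

test_that("ties map to ties and order is preserved", {
  src <- fit_density(build_histogram(skew_pool(2000, seed = 3)), "gaussian")
  tgt <- make_analytic_model("gaussian", c(5, 2))
  res <- dbnorm_map(c(2, 2, 3), src, tgt)
  expect_identical(res$mapped_values[1], res$mapped_values[2])
  expect_gt(res$mapped_values[3], res$mapped_values[2])
  expect_error(dbnorm_map(numeric(0), src, tgt), class = "distnorm_validation_error")
  expect_error(dbnorm_map(c(1, NA), src, tgt), class = "distnorm_validation_error")
})

test_that("probability gap stays within tolerance for mapped pools", {
  src <- fit_density(build_histogram(skew_pool(5000, seed = 6)), "fourier")
  tgt <- fit_density(build_histogram(skew_pool(5000, loc = 7, scale = 2, seed = 7)), "fourier")
  res <- dbnorm_map(as.numeric(skew_pool(5000, seed = 6)), src, tgt)
  expect_lte(res$max_probability_gap, 1e-6)
  expect_true(all(res$mapped_values >= tgt$support[1] &
                  res$mapped_values <= tgt$support[2]))
})

test_that("normalize_matrix maps quantiles onto the target distribution", {
  # all entries at the source median land on the target median
  src <- make_analytic_model("gaussian", c(6.5, 2))
  tgt <- make_analytic_model("gaussian", c(5, 1))
  m <- expression_matrix(matrix(6.5, 4, 3))
  out <- normalize_matrix(m, src, tgt)
  expect_lt(max(abs(unclass(out) - 5)), 1e-3)

  # identity model pair leaves a matrix unchanged
  m2 <- toy_matrix(P = 2, S = 2, seed = 10)
  fit <- fit_density(build_histogram(skew_pool(2000, seed = 10)), "gaussian")
  expect_lt(max(abs(unclass(normalize_matrix(m2, fit, fit)) - unclass(m2))), 1e-4)

  # rescaling a N(6.5, 2) matrix onto an analytic N(6.5, 1) halves the spread
  set.seed(12)
  big <- expression_matrix(matrix(rnorm(5000, 6.5, 2), 1000, 5))
  src2 <- fit_density(build_histogram(value_pool(as.vector(big))), "gaussian")
  tgt2 <- make_analytic_model("gaussian", c(6.5, 1))
  out2 <- normalize_matrix(big, src2, tgt2)
  expect_true(sd(as.vector(out2)) > 0.9 && sd(as.vector(out2)) < 1.1)
  expect_identical(dimnames(out2), dimnames(big))

  # declared source must match the model's source
  m3 <- toy_matrix(source_id = "A")
  modelB <- fit_density(build_histogram(value_pool(rnorm(500, 6, 1), source_id = "B")),
                        "gaussian")
  expect_error(normalize_matrix(m3, modelB, tgt),
               class = "distnorm_validation_error")
})

test_that("renormalizing already-mapped data changes values only within fit noise", {
  pool <- as.numeric(skew_pool(5000, seed = 13))
  h_src <- build_histogram(pool)
  src <- fit_density(h_src, "fourier")
  tgt <- fit_density(build_histogram(skew_pool(5000, loc = 7.2, scale = 2.1, seed = 14)),
                     "fourier")
  once <- dbnorm_map(pool, src, tgt)$mapped_values
  refit <- fit_density(build_histogram(value_pool(once)), "fourier")
  twice <- dbnorm_map(once, refit, tgt)$mapped_values
  bin_w <- diff(build_histogram(value_pool(once))$edges)[1]
  expect_lt(max(abs(twice - once)), 2 * bin_w)
})

test_that("the largest source is chosen as target", {
  mats <- list(a = toy_matrix(P = 5, S = 2), b = toy_matrix(P = 5, S = 6),
               c = toy_matrix(P = 5, S = 4))
  expect_identical(choose_target(mats), "b")
  mats2 <- list(a = toy_matrix(P = 9, S = 2), b = toy_matrix(P = 5, S = 2))
  expect_identical(choose_target(mats2, by = "probes"), "a")
})

test_that("the pipeline normalizes all sources onto the chosen target", {
  sim <- simulate_platforms(300, westmead_like_preset(5), seed = 5)
  res <- dbnorm_normalize(sim$matrices, target = "U133Plus2")
  expect_identical(res$target_name, "U133Plus2")
  expect_identical(res$normalized$U133Plus2, sim$matrices$U133Plus2)
  for (nm in c("U133A", "U133A2", "HG1ST")) {
    kb <- kl_divergence(as.vector(sim$matrices[[nm]]), as.vector(sim$matrices$U133Plus2))
    ka <- kl_divergence(as.vector(res$normalized[[nm]]), as.vector(sim$matrices$U133Plus2))
    expect_lt(ka, kb)
  }
  # analytic target
  res2 <- dbnorm_normalize(sim$matrices[c("U133A", "HG1ST")],
                           target = make_analytic_model("gaussian", c(6.5, 1)))
  expect_true(is.na(res2$target_name))
  expect_lt(abs(sd(as.vector(res2$normalized$U133A)) - 1), 0.15)
})
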