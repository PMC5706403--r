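test_that("z-score standardizes every sample column", {
  m <- expression_matrix(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  z <- zscore_normalize(m)
  expect_equal(unclass(z)[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # idempotent on standardized input
  expect_lt(max(abs(unclass(zscore_normalize(z)) - unclass(z))), 1e-12)
  # constant column is degenerate, error names the sample
  bad <- expression_matrix(cbind(ok = c(1, 2, 3), flat = c(5, 5, 5)))
  err <- tryCatch(zscore_normalize(bad), error = identity)
  expect_s3_class(err, "distnorm_validation_error")
  expect_match(conditionMessage(err), "flat")
})

test_that("avgdiff scales every source to the common grand mean", {
  m1 <- expression_matrix(matrix(4, 3, 2) + 0)     # global mean 4
  m2 <- expression_matrix(matrix(8, 3, 2) + 0)     # global mean 8
  out <- avgdiff_normalize(list(m1, m2))
  expect_lt(abs(mean(unclass(out[[1]])) - 6), 1e-9)
  expect_lt(abs(mean(unclass(out[[2]])) - 6), 1e-9)

  # a single matrix is already at its own grand mean
  m3 <- toy_matrix(seed = 21)
  expect_lt(max(abs(unclass(avgdiff_normalize(list(m3))[[1]]) - unclass(m3))), 1e-12)

  # multiplicative: within-matrix ratios unchanged
  m4 <- toy_matrix(seed = 22); m5 <- toy_matrix(seed = 23)
  out2 <- avgdiff_normalize(list(m4, m5))
  r_before <- unclass(m4)[1, 1] / unclass(m4)[2, 1]
  r_after <- unclass(out2[[1]])[1, 1] / unclass(out2[[1]])[2, 1]
  expect_lt(abs(r_after - r_before), 1e-12)

  # all outputs share one global mean
  means <- vapply(out2, function(m) mean(unclass(m)), numeric(1))
  expect_lt(diff(range(means)), 1e-9)

  neg <- expression_matrix(matrix(c(-5, -4, 1, 0), 2, 2))
  expect_error(avgdiff_normalize(list(m4, neg)), class = "distnorm_validation_error")
})

test_that("quantile normalization equalizes sorted columns", {
  m1 <- expression_matrix(matrix(c(2, 4, 6), 3, 1))
  m2 <- expression_matrix(matrix(c(1, 3, 5), 3, 1))
  out <- quantile_normalize(list(m1, m2))
  expect_equal(sort(as.vector(out[[1]])), c(1.5, 3.5, 5.5), ignore_attr = TRUE)
  expect_equal(sort(as.vector(out[[2]])), c(1.5, 3.5, 5.5), ignore_attr = TRUE)

  # identical columns pass through unchanged
  same <- expression_matrix(matrix(c(1, 2, 3, 1, 2, 3), 3, 2))
  expect_lt(max(abs(unclass(quantile_normalize(list(same))[[1]]) - unclass(same))), 1e-12)

  # tied entries receive the mean of the reference values at their tied ranks
  t1 <- expression_matrix(matrix(c(1, 1, 9), 3, 1))
  t2 <- expression_matrix(matrix(c(2, 4, 6), 3, 1))
  out2 <- quantile_normalize(list(t1, t2))
  expect_equal(as.vector(out2[[1]]), c(2, 2, 7.5), ignore_attr = TRUE)

  expect_error(quantile_normalize(list(m1, toy_matrix(P = 5))),
               class = "distnorm_validation_error")
})

test_that("quantile normalization matches an independent rank-mean oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(rnorm(300, 6, 2), 50, 6)
    vals[sample(300, 30)] <- sample(vals[1:5], 30, replace = TRUE)  # inject ties
    m <- expression_matrix(vals)
    ours <- unclass(quantile_normalize(list(m))[[1]])
    expect_lt(max(abs(ours - qn_oracle(vals))), 1e-12)
  }
  # on tie-free columns the sorted vectors become exactly identical
  set.seed(99)
  tf <- expression_matrix(matrix(rnorm(300, 6, 2), 50, 6))
  sorted <- apply(unclass(quantile_normalize(list(tf))[[1]]), 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
})

test_that("all baseline normalizers preserve within-column rank order", {
  set.seed(33)
  m1 <- expression_matrix(matrix(runif(200, 2, 14), 50, 4))
  m2 <- expression_matrix(matrix(runif(150, 1, 12), 50, 3))
  results <- list(zscore = list(zscore_normalize(m1)),
                  avgdiff = avgdiff_normalize(list(m1, m2)),
                  quantile = quantile_normalize(list(m1, m2)))
  for (res in results) {
    for (m in res) {
      for (j in seq_len(ncol(m))) {
        orig <- if (ncol(m) == 4) m1 else m2
        expect_identical(rank(unclass(m)[, j]), rank(unclass(orig)[, j]))
      }
    }
  }
})
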