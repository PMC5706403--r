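test_that("value pools validate their contents", {
  expect_error(value_pool(c(1, 1, 1)), class = "distnorm_validation_error")
  expect_error(value_pool(c(1, NA, 2), nonfinite = "reject"),
               class = "distnorm_validation_error")
  p <- value_pool(c(1, NA, 2, Inf, 3), nonfinite = "drop")
  expect_equal(as.numeric(p), c(1, 2, 3))
  expect_identical(attr(value_pool(1:3, source_id = "x"), "source_id"), "x")
})

test_that("histograms are normalized and span the pool range exactly", {
  h <- build_histogram(value_pool(c(1, 1, 2, 2)), n_bins = 2)
  expect_equal(h$masses, c(0.5, 0.5))

  h <- build_histogram(value_pool(0:9), n_bins = 5)
  expect_equal(h$masses, rep(0.2, 5))  # right-closed last bin catches the max
  expect_equal(range(h$edges), c(0, 9))

  set.seed(42)
  h <- build_histogram(value_pool(rnorm(1000)), n_bins = 20)
  expect_lt(abs(sum(h$masses) - 1), 1e-9)
  expect_true(all(diff(h$edges) > 0))

  # auto rule respects floor and cap
  expect_gte(length(build_histogram(skew_pool(100))$masses), 20)
  expect_lte(length(build_histogram(skew_pool(1e5, seed = 3))$masses), 200)
})

test_that("gaussian family recovers simulated location and scale", {
  for (seed in 1:3) {
    set.seed(seed)
    h <- build_histogram(value_pool(rnorm(5000, 6.5, 2)))
    m <- fit_density(h, family = "gaussian")
    expect_lt(abs(m$coefficients[2] - 6.5), 0.1)
    expect_lt(abs(m$coefficients[3] - 2.0), 0.1)
  }
})

test_that("degree-zero polynomial on uniform data is flat at 1/width", {
  set.seed(7)
  h <- build_histogram(value_pool(runif(5000)))
  m <- fit_density(h, family = "polynomial", order = 0)
  width <- diff(m$support)
  at <- seq(m$support[1] + 0.01, m$support[2] - 0.01, length.out = 50)
  expect_true(all(abs(density(m, at) * width - 1) < 0.05))
})

test_that("every fitted model is a valid density with a monotone CDF", {
  h <- build_histogram(skew_pool(5000, seed = 11))
  models <- list(
    fit_density(h, "polynomial"),
    fit_density(h, "fourier"),
    fit_density(h, "gaussian"),
    fit_custom_density(h, function(x, p) p[1] * exp(-((x - p[2])^2) / (2 * p[3]^2)),
                       c(0.3, 6, 1.5)),
    make_analytic_model("gaussian", c(0, 1)),
    make_analytic_model("uniform", c(0, 1)))
  for (m in models) {
    expect_lt(abs(model_mass(m) - 1), 1e-6)
    grid <- seq(m$support[1], m$support[2], length.out = 10000)
    expect_true(all(density(m, grid) >= 0))
    expect_true(all(diff(m$cdf_grid) >= 0))
    expect_equal(m$cdf_grid[1], 0)
    expect_lt(abs(m$cdf_grid[length(m$cdf_grid)] - 1), 1e-6)
  }
})

test_that("a gaussian-shaped custom fit matches the built-in gaussian family", {
  h <- build_histogram(skew_pool(5000, loc = 6.5, scale = 2, alpha = 0, seed = 2))
  builtin <- fit_density(h, "gaussian", order = 1)
  custom <- fit_custom_density(h, function(x, p) p[1] * exp(-((x - p[2])^2) / (2 * p[3]^2)),
                               param_init = c(0.1, 5, 3))
  expect_true(all(abs(custom$coefficients - builtin$coefficients) < 1e-3))
})

test_that("fit failures and meaningless fits raise typed errors", {
  h <- build_histogram(skew_pool(500, seed = 5), n_bins = 20)
  expect_error(fit_density(h, "polynomial", order = 25),
               class = "distnorm_validation_error")  # degree > B - 1
  expect_error(fit_density(h, "fourier", order = 0),
               class = "distnorm_validation_error")
  expect_error(fit_density(h, "fourier", order = 12),
               class = "distnorm_fit_error")  # 2K+1 coefficients > bins
  expect_error(
    fit_custom_density(h, function(x, p) -abs(p[1]) - x^0, c(1)),
    class = "distnorm_fit_error")  # non-positive density everywhere
  # clipping that removes more than half the absolute mass is rejected
  expect_error(
    distnorm:::finalize_model("custom", 1, c(0, 1), 4097, rss = 0,
                              custom_fn = function(x, p) sin(4 * pi * x) - 0.2),
    class = "distnorm_fit_error")
})

test_that("analytic models expose closed-form probabilities", {
  std <- make_analytic_model("gaussian", c(0, 1), support = c(-6, 6))
  expect_lt(abs(cdf(std, 0) - 0.5), 1e-6)
  expect_lt(abs(cdf(std, 1) - 0.8413447), 1e-3)
  u <- make_analytic_model("uniform", c(0, 1))
  expect_lt(abs(cdf(u, 0.25) - 0.25), 1e-6)
  expect_error(make_analytic_model("gaussian", c(0, -1)),
               class = "distnorm_validation_error")
  expect_error(make_analytic_model("uniform", c(1, 0)),
               class = "distnorm_validation_error")
})

test_that("models serialize to JSON and round-trip their CDF exactly", {
  h <- build_histogram(skew_pool(3000, seed = 9))
  models <- list(fourier = fit_density(h, "fourier"),
                 polynomial = fit_density(h, "polynomial"),
                 gaussian = fit_density(h, "gaussian"),
                 custom = fit_custom_density(
                   h, function(x, p) p[1] * exp(-((x - p[2])^2) / (2 * p[3]^2)),
                   c(0.3, 6, 1.5)),
                 analytic = make_analytic_model("gaussian", c(6.5, 2)))
  for (nm in names(models)) {
    f <- withr::local_tempfile(fileext = ".json")
    write_density_model(models[[nm]], f)
    back <- read_density_model(f)
    expect_lt(max(abs(back$cdf_grid - models[[nm]]$cdf_grid)), 1e-12)
    expect_identical(back$family, models[[nm]]$family)
  }
})
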