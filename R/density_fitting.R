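#' @importFrom stats approx predict coef IQR quantile median rnorm runif setNames
NULL

family_default_order <- c(polynomial = 9L, fourier = 8L, gaussian = 1L)

# Evaluate the raw (unclipped, unnormalized) fitted curve of a built-in family.
# Polynomial coefficients live in the scaled basis u = 2*(x-lo)/(hi-lo) - 1 for
# conditioning; Fourier uses the fixed fundamental period hi - lo.
raw_family_density <- function(family, coefficients, support, x, custom_fn = NULL) {
  lo <- support[1]; hi <- support[2]
  switch(family,
    polynomial = {
      u <- 2 * (x - lo) / (hi - lo) - 1
      drop(outer(u, seq_along(coefficients) - 1L, `^`) %*% coefficients)
    },
    fourier = {
      K <- (length(coefficients) - 1L) %/% 2L
      w <- 2 * pi / (hi - lo)
      out <- rep(coefficients[1L], length(x))
      for (k in seq_len(K)) {
        out <- out + coefficients[2L * k] * cos(k * w * (x - lo)) +
                     coefficients[2L * k + 1L] * sin(k * w * (x - lo))
      }
      out
    },
    gaussian = {
      K <- length(coefficients) %/% 3L
      out <- numeric(length(x))
      for (k in seq_len(K)) {
        a <- coefficients[3L * k - 2L]; b <- coefficients[3L * k - 1L]
        s <- coefficients[3L * k]
        out <- out + a * exp(-((x - b)^2) / (2 * s^2))
      }
      out
    },
    custom = custom_fn(x, coefficients),
    abort_validation(sprintf("unknown density family '%s'", family))
  )
}

# Poisson-motivated variance stabilization: bins with small expected counts get
# small absolute noise, so near-uniform relative weighting with a floor keeps
# the fitted tails pinned near zero instead of wandering.
fit_weights <- function(densities) 1 / (densities + max(densities) / 20)

padded_support <- function(hist) {
  lo <- hist$edges[1L]; hi <- hist$edges[length(hist$edges)]
  pad <- 0.01 * (hi - lo)
  c(lo - pad, hi + pad)
}

# Clip negatives, renormalize to unit mass by composite trapezoid on the
# support grid, build the monotone CDF lookup. Rejects fits whose negative
# excursions carry more than half the absolute mass.
finalize_model <- function(family, coefficients, support, n_grid, rss,
                           order = NA_integer_, custom_fn = NULL, source_id = NULL) {
  grid_x <- seq(support[1], support[2], length.out = n_grid)
  raw <- raw_family_density(family, coefficients, support, grid_x, custom_fn)
  if (any(!is.finite(raw))) {
    abort_fit(sprintf("fit failure: family '%s' produced non-finite densities", family))
  }
  w <- diff(grid_x)
  trap <- function(y) sum((y[-1L] + y[-length(y)]) / 2 * w)
  pos_mass <- trap(pmax(raw, 0))
  neg_mass <- trap(pmax(-raw, 0))
  if (pos_mass <= 0) {
    abort_fit(sprintf("fit rejected: family '%s' density is non-positive over the whole support",
                      family))
  }
  clipped_frac <- neg_mass / (pos_mass + neg_mass)
  if (clipped_frac > 0.5) {
    abort_fit(sprintf(
      "fit rejected: clipping negative density removes %.1f%% of mass (family '%s', order %s)",
      100 * clipped_frac, family, order))
  }
  pdf <- pmax(raw, 0) / pos_mass
  cdf <- c(0, cumsum((pdf[-1L] + pdf[-n_grid]) / 2 * w))
  cdf <- cdf / cdf[n_grid]
  structure(list(family = family, coefficients = coefficients, support = support,
                 order = order, n_grid = n_grid, grid_x = grid_x, pdf_grid = pdf,
                 cdf_grid = cdf, norm_const = pos_mass, rss = rss,
                 clipped_mass = clipped_frac, custom_fn = custom_fn,
                 source_id = source_id),
            class = "density_model")
}

#' Fit a parametric density to a binned distribution
#'
#' Fits one of the built-in families to the (bin midpoint, density height)
#' pairs of a histogram by weighted least squares, then clips the fitted curve
#' at zero, renormalizes it to integrate to one over the support, and
#' precomputes a dense monotone CDF lookup. The support is the histogram range
#' padded by 1% on each side so that boundary values keep interior cumulative
#' probabilities.
#'
#' Weighted least squares uses weights `1 / (density + max(density)/20)`, the
#' variance stabilization suggested by Poisson bin counts: without it the
#' fitted curve can wander in the sparse tails, which translates directly into
#' cumulative-probability error where it hurts the value mapping most.
#'
#' @param hist A [build_histogram()] result.
#' @param family `"polynomial"`, `"fourier"` or `"gaussian"`.
#' @param order Polynomial degree (default 9), number of Fourier harmonics
#'   (default 8), or number of Gaussian components (default 1).
#' @param n_grid Resolution of the support grid backing the CDF lookup
#'   (default 8193).
#' @return A `density_model` with fields `family`, `coefficients`, `support`,
#'   `grid_x`/`pdf_grid`/`cdf_grid`, `rss` (residual sum of squares of the raw
#'   fit) and `clipped_mass` (fraction of absolute mass removed by clipping).
#' @seealso [fit_custom_density()], [make_analytic_model()], [cdf()],
#'   [dbnorm_map()]
#' @examples
#' pool <- value_pool(rnorm(5000, 6.5, 2))
#' m <- fit_density(build_histogram(pool), family = "gaussian")
#' m$coefficients
#' @export
fit_density <- function(hist, family = c("polynomial", "fourier", "gaussian"),
                        order = NULL, n_grid = 8193L) {
  family <- match.arg(family)
  if (!inherits(hist, "binned_distribution")) {
    abort_validation("fit_density expects a binned_distribution (see build_histogram)")
  }
  B <- length(hist$masses)
  if (is.null(order)) order <- family_default_order[[family]]
  order <- as.integer(order)
  if (family == "polynomial" && (order < 0L || order > B - 1L)) {
    abort_validation(sprintf("polynomial degree must be in [0, %d] for %d bins", B - 1L, B))
  }
  if (family %in% c("fourier", "gaussian") && order < 1L) {
    abort_validation(sprintf("%s order must be >= 1", family))
  }
  support <- padded_support(hist)
  mids <- hist$mids; dens <- hist$densities
  sw <- sqrt(fit_weights(dens))

  if (family == "polynomial" || family == "fourier") {
    X <- if (family == "polynomial") {
      u <- 2 * (mids - support[1]) / (support[2] - support[1]) - 1
      outer(u, 0:order, `^`)
    } else {
      w <- 2 * pi / (support[2] - support[1])
      Xf <- matrix(1, B, 1L + 2L * order)
      for (k in seq_len(order)) {
        Xf[, 2L * k] <- cos(k * w * (mids - support[1]))
        Xf[, 2L * k + 1L] <- sin(k * w * (mids - support[1]))
      }
      Xf
    }
    if (ncol(X) > B) {
      abort_fit(sprintf("fit failure: family '%s' order %d needs more bins than available (%d)",
                        family, order, B))
    }
    cf <- tryCatch(qr.solve(X * sw, dens * sw),
                   error = function(e) abort_fit(sprintf(
                     "fit failure: singular least-squares system (family '%s', order %d): %s",
                     family, order, conditionMessage(e))))
    rss <- sum((dens - drop(X %*% cf))^2)
    return(finalize_model(family, as.numeric(cf), support, n_grid, rss,
                          order = order, source_id = hist$source_id))
  }

  # gaussian mixture of `order` components via Levenberg-Marquardt
  mu0 <- sum(mids * hist$masses)
  s0 <- sqrt(max(sum((mids - mu0)^2 * hist$masses), 1e-12))
  if (order == 1L) {
    starts <- list(a = c(max(dens)), b = c(mu0), s = c(s0))
  } else {
    qs <- seq(0.2, 0.8, length.out = order)
    starts <- list(a = rep(max(dens) / order, order),
                   b = mu0 + s0 * stats::qnorm(qs),
                   s = rep(s0 / sqrt(order), order))
  }
  par0 <- as.numeric(rbind(starts$a, starts$b, starts$s))
  residual <- function(par) {
    sw * (dens - raw_family_density("gaussian", par, support, mids))
  }
  fit <- minpack.lm::nls.lm(par0, fn = residual,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    abort_fit(sprintf("fit failure: gaussian fit (order %d) did not converge: %s",
                      order, fit$message))
  }
  cf <- fit$par
  # canonical form: positive widths, components ordered by location
  K <- order
  sgn <- sign(cf[seq(3, 3 * K, by = 3)]); sgn[sgn == 0] <- 1
  cf[seq(3, 3 * K, by = 3)] <- cf[seq(3, 3 * K, by = 3)] * sgn
  ord <- order(cf[seq(2, 3 * K, by = 3)])
  cf <- as.numeric(sapply(ord, function(k) cf[(3 * k - 2):(3 * k)]))
  rss <- sum((dens - raw_family_density("gaussian", cf, support, mids))^2)
  finalize_model("gaussian", cf, support, n_grid, rss, order = order,
                 source_id = hist$source_id)
}

#' Fit a user-defined density to a binned distribution
#'
#' Same contract as [fit_density()] but for an arbitrary density shape:
#' `density_fn(x, params)` must return a non-negative (up to fit error)
#' density value for each `x`. Parameters are estimated by weighted nonlinear
#' least squares against the histogram, then the curve is clipped,
#' renormalized and equipped with a CDF lookup exactly as for the built-in
#' families.
#'
#' @param hist A [build_histogram()] result.
#' @param density_fn `function(x, params)` evaluating the unnormalized density.
#' @param param_init Numeric vector of starting parameter values.
#' @param n_grid CDF grid resolution (default 8193).
#' @return A `density_model` with `family = "custom"`.
#' @examples
#' pool <- value_pool(rnorm(2000, 3, 1))
#' gauss <- function(x, p) exp(-((x - p[1])^2) / (2 * p[2]^2))
#' m <- fit_custom_density(build_histogram(pool), gauss, c(0, 2))
#' @export
fit_custom_density <- function(hist, density_fn, param_init, n_grid = 8193L) {
  if (!inherits(hist, "binned_distribution")) {
    abort_validation("fit_custom_density expects a binned_distribution")
  }
  if (!is.function(density_fn)) abort_validation("density_fn must be a function(x, params)")
  support <- padded_support(hist)
  mids <- hist$mids; dens <- hist$densities
  init_vals <- density_fn(mids, param_init)
  if (!is.numeric(init_vals) || length(init_vals) != length(mids) || any(!is.finite(init_vals))) {
    abort_validation("density_fn must return finite numeric values over the support for param_init")
  }
  if (all(init_vals <= 0)) {
    abort_fit("fit rejected: density_fn is non-positive over the whole support at param_init")
  }
  sw <- sqrt(fit_weights(dens))
  residual <- function(par) sw * (dens - density_fn(mids, par))
  fit <- minpack.lm::nls.lm(par = param_init, fn = residual,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4) {
    abort_fit(sprintf("fit failure: custom density fit did not converge (info %d): %s",
                      fit$info, fit$message))
  }
  rss <- sum((dens - density_fn(mids, fit$par))^2)
  finalize_model("custom", as.numeric(fit$par), support, n_grid, rss,
                 custom_fn = density_fn, source_id = hist$source_id)
}

#' Build an analytic density model (no fitting)
#'
#' Wraps a standard probability density, truncated and renormalized to a
#' finite support, in the same `density_model` container the fitted families
#' use, so a data source can be rescaled to a chosen reference distribution.
#' Cumulative probabilities use the closed-form CDF rather than quadrature.
#'
#' @param family `"gaussian"` (params `c(mean, sd)`, `sd > 0`) or `"uniform"`
#'   (params `c(min, max)`).
#' @param params Numeric parameter vector for the family.
#' @param support `c(lo, hi)` truncation interval. Defaults to mean +/- 6 sd
#'   for the Gaussian and to `params` for the uniform.
#' @param n_grid Grid resolution for the stored density/CDF tables.
#' @return A `density_model` with family `"analytic_gaussian"` or
#'   `"analytic_uniform"`.
#' @examples
#' std <- make_analytic_model("gaussian", c(0, 1))
#' cdf(std, 0)  # 0.5
#' @export
make_analytic_model <- function(family = c("gaussian", "uniform"), params,
                                support = NULL, n_grid = 8193L) {
  family <- match.arg(family)
  if (!is.numeric(params) || length(params) != 2L || any(!is.finite(params))) {
    abort_validation("params must be two finite numbers")
  }
  if (family == "gaussian") {
    if (params[2] <= 0) abort_validation("gaussian sd must be > 0")
    if (is.null(support)) support <- params[1] + c(-6, 6) * params[2]
  } else {
    if (params[1] >= params[2]) abort_validation("uniform requires min < max")
    if (is.null(support)) support <- params
  }
  if (!is.numeric(support) || length(support) != 2L || support[1] >= support[2]) {
    abort_validation("support must be an interval c(lo, hi) with lo < hi")
  }
  fam <- paste0("analytic_", family)
  grid_x <- seq(support[1], support[2], length.out = n_grid)
  cdf_fun <- analytic_cdf_fun(fam, params, support)
  pdf <- analytic_pdf(fam, params, support, grid_x)
  structure(list(family = fam, coefficients = as.numeric(params), support = support,
                 order = NA_integer_, n_grid = as.integer(n_grid), grid_x = grid_x,
                 pdf_grid = pdf, cdf_grid = cdf_fun(grid_x), norm_const = 1,
                 rss = 0, clipped_mass = 0, custom_fn = NULL, source_id = NULL),
            class = "density_model")
}

analytic_cdf_fun <- function(family, params, support) {
  lo <- support[1]; hi <- support[2]
  if (family == "analytic_gaussian") {
    plo <- stats::pnorm(lo, params[1], params[2])
    phi <- stats::pnorm(hi, params[1], params[2])
    function(x) (stats::pnorm(pmin(pmax(x, lo), hi), params[1], params[2]) - plo) / (phi - plo)
  } else {
    plo <- stats::punif(lo, params[1], params[2])
    phi <- stats::punif(hi, params[1], params[2])
    function(x) (stats::punif(pmin(pmax(x, lo), hi), params[1], params[2]) - plo) / (phi - plo)
  }
}

analytic_pdf <- function(family, params, support, x) {
  lo <- support[1]; hi <- support[2]
  if (family == "analytic_gaussian") {
    Z <- stats::pnorm(hi, params[1], params[2]) - stats::pnorm(lo, params[1], params[2])
    stats::dnorm(x, params[1], params[2]) / Z
  } else {
    Z <- stats::punif(hi, params[1], params[2]) - stats::punif(lo, params[1], params[2])
    stats::dunif(x, params[1], params[2]) / Z
  }
}

is_analytic <- function(model) startsWith(model$family, "analytic_")

#' Evaluate a fitted density
#'
#' @param x A `density_model`.
#' @param at Numeric vector of evaluation points.
#' @param ... Unused.
#' @return Density values (zero outside the support).
#' @export
density.density_model <- function(x, at, ...) {
  model <- x
  if (!is.numeric(at) || any(!is.finite(at))) abort_validation("evaluation points must be finite")
  out <- numeric(length(at))
  inside <- at >= model$support[1] & at <= model$support[2]
  if (any(inside)) {
    out[inside] <- if (is_analytic(model)) {
      analytic_pdf(model$family, model$coefficients, model$support, at[inside])
    } else {
      pmax(raw_family_density(model$family, model$coefficients, model$support,
                              at[inside], model$custom_fn), 0) / model$norm_const
    }
  }
  out
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("density_model: family %s%s, support [%.4g, %.4g], grid %d\n",
              x$family,
              if (is.na(x$order)) "" else sprintf(" (order %d)", x$order),
              x$support[1], x$support[2], x$n_grid))
  if (!is_analytic(x)) {
    cat(sprintf("  rss %.4g, clipped mass %.3g%%\n", x$rss, 100 * x$clipped_mass))
  }
  invisible(x)
}
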