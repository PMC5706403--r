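# Plain-text (JSON) serialization of density models. Built-in and analytic
# families round-trip exactly: the density is re-evaluated from the stored
# coefficients on the same support grid, so the reconstructed CDF is
# bit-identical. Custom models store the density grid itself, since an
# arbitrary closure cannot be serialized portably.

#' Write a density model to a JSON document
#'
#' @param model A `density_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_density_model()]
#' @export
write_density_model <- function(model, path) {
  check_model(model)
  doc <- list(format = "distnorm-density-model", version = 1L,
              family = model$family,
              coefficients = model$coefficients,
              support = model$support,
              n_grid = model$n_grid,
              order = if (is.na(model$order)) NULL else model$order,
              rss = model$rss,
              clipped_mass = model$clipped_mass,
              source_id = model$source_id)
  if (model$family == "custom") doc$pdf_grid <- model$pdf_grid
  ok <- tryCatch(jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                                      null = "null", pretty = TRUE),
                 error = function(e) abort_io(sprintf("cannot write model to %s: %s",
                                                      path, conditionMessage(e))))
  invisible(path)
}

#' Read a density model from a JSON document
#'
#' Rebuilds the model from family, coefficients, support and grid resolution;
#' `read_density_model(write_density_model(m, f))` reproduces the CDF grid of
#' `m` exactly for built-in and analytic families.
#'
#' @param path Path written by [write_density_model()].
#' @return A `density_model`.
#' @export
read_density_model <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_io(sprintf("cannot parse %s: %s",
                                                       path, conditionMessage(e))))
  if (!identical(doc$format, "distnorm-density-model")) {
    abort_validation(sprintf("%s is not a distnorm density model document", path))
  }
  support <- as.numeric(doc$support)
  n_grid <- as.integer(doc$n_grid)
  src <- if (is.null(doc$source_id)) NULL else doc$source_id
  ord <- if (is.null(doc$order) || is.na(doc$order)) NA_integer_ else as.integer(doc$order)
  if (startsWith(doc$family, "analytic_")) {
    m <- make_analytic_model(sub("^analytic_", "", doc$family),
                             as.numeric(doc$coefficients), support, n_grid)
    m$source_id <- src
    return(m)
  }
  if (doc$family == "custom") {
    grid_x <- seq(support[1], support[2], length.out = n_grid)
    pdf <- as.numeric(doc$pdf_grid)
    w <- diff(grid_x)
    cdfg <- c(0, cumsum((pdf[-1L] + pdf[-n_grid]) / 2 * w))
    cdfg <- cdfg / cdfg[n_grid]
    return(structure(list(family = "custom", coefficients = as.numeric(doc$coefficients),
                          support = support, order = ord, n_grid = n_grid,
                          grid_x = grid_x, pdf_grid = pdf, cdf_grid = cdfg,
                          norm_const = 1, rss = as.numeric(doc$rss),
                          clipped_mass = as.numeric(doc$clipped_mass),
                          custom_fn = function(x, params) {
                            approx(grid_x, pdf, x, yleft = 0, yright = 0)$y
                          },
                          source_id = src),
                     class = "density_model"))
  }
  m <- finalize_model(doc$family, as.numeric(doc$coefficients), support, n_grid,
                      rss = as.numeric(doc$rss), order = ord, source_id = src)
  m$clipped_mass <- as.numeric(doc$clipped_mass)
  m
}
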