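#' Run configuration with validated defaults
#'
#' Central place for the tunable parameters shared by the CLI and the
#' pipeline functions. Unknown keys are rejected so a typo in a config file
#' cannot silently fall back to a default.
#'
#' Defaults: tab delimiter; automatic (Freedman-Diaconis, 20-200) bin count;
#' Fourier family at its default order; 8193-point CDF grid; interior
#' probability clamp 1e-9; non-finite input policy `"drop"`; `info` logging.
#'
#' @param ... Named overrides of the defaults listed above (`delimiter`,
#'   `bins`, `family`, `order`, `grid_resolution`, `epsilon_clamp`,
#'   `nonfinite_policy`, `seed`, `log_level`).
#' @return A named list of class `run_config`.
#' @examples
#' run_config(family = "polynomial", bins = 50)
#' @export
run_config <- function(...) {
  defaults <- list(delimiter = "\t", bins = NULL, family = "fourier", order = NULL,
                   grid_resolution = 8193L, epsilon_clamp = 1e-9,
                   nonfinite_policy = "drop", seed = NULL, log_level = "info")
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) && is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort_validation(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  if (!cfg$family %in% c("polynomial", "fourier", "gaussian")) {
    abort_validation(sprintf("unknown family '%s'", cfg$family))
  }
  if (!cfg$nonfinite_policy %in% c("drop", "reject")) {
    abort_validation("nonfinite_policy must be 'drop' or 'reject'")
  }
  if (!cfg$log_level %in% c("debug", "info", "warn", "quiet")) {
    abort_validation("log_level must be debug/info/warn/quiet")
  }
  if (!is.null(cfg$bins) && (!is.numeric(cfg$bins) || cfg$bins < 5)) {
    abort_validation("bins must be >= 5")
  }
  if (cfg$grid_resolution < 64) abort_validation("grid_resolution must be >= 64")
  if (cfg$epsilon_clamp <= 0 || cfg$epsilon_clamp >= 0.5) {
    abort_validation("epsilon_clamp must be in (0, 0.5)")
  }
  structure(cfg, class = "run_config")
}
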