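# Condition classes shared across the package. Exit-code mapping in the CLI:
# validation -> 2, fit failure -> 3, I/O -> 4.

abort_validation <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("distnorm_validation_error", "distnorm_error")))
}

abort_fit <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("distnorm_fit_error", "distnorm_error")))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("distnorm_io_error", "distnorm_error")))
}

#' Package logging
#'
#' Emits a timestamped message when `level` is at or above the threshold in
#' `options(distnorm.log_level =)` (one of `"debug"`, `"info"`, `"warn"`,
#' `"quiet"`; default `"info"`).
#'
#' @param level Message level, `"debug"`, `"info"` or `"warn"`.
#' @param ... Passed to [sprintf()] (first element the format string).
#' @return Invisibly, the formatted message.
#' @export
dn_log <- function(level = "info", ...) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  threshold <- getOption("distnorm.log_level", "info")
  msg <- sprintf(...)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), toupper(level), msg))
  }
  invisible(msg)
}
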