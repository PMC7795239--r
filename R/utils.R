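# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed. Levels, from chattiest to
#' quietest: `"debug"`, `"info"`, `"warn"`, `"error"`.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
gw_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("gwgendrug.log_level", "info")
  options(gwgendrug.log_level = level)
  invisible(old)
}

gw_log <- function(level, fmt, ...) {
  threshold <- getOption("gwgendrug.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
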