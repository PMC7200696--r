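# minimal leveled logging to stderr; level set via option or nn_log_level()
.nn_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set or query the package log level
#'
#' Messages below the active level are suppressed. Logs go to stderr.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`; missing to
#'   query.
#' @return the active level, invisibly when setting.
#' @export
nn_log_level <- function(level) {
  if (missing(level)) return(getOption("nervenano.log_level", "warn"))
  level <- match.arg(level, names(.nn_levels))
  options(nervenano.log_level = level)
  invisible(level)
}

nn_log <- function(level, ...) {
  lv <- .nn_levels[[match.arg(level, names(.nn_levels))]]
  if (lv >= .nn_levels[[nn_log_level()]])
    message(sprintf("[nervenano %s] %s", toupper(level),
                    paste0(..., collapse = "")))
  invisible(NULL)
}
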