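.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Set the package log level
#'
#' Messages at or above `level` are emitted via [message()]. The default is
#' `"WARN"` so library use stays quiet; the command-line drivers switch to
#' `"INFO"` to record every I/O decision (skipped residues, altloc choices,
#' effective configuration).
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level) {
  level <- match.arg(toupper(level), names(.log_levels))
  old <- getOption("nsalign.log_level", "WARN")
  options(nsalign.log_level = level)
  invisible(old)
}

ns_log <- function(level, fmt, ...) {
  current <- getOption("nsalign.log_level", "WARN")
  if (.log_levels[[level]] >= .log_levels[[current]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
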