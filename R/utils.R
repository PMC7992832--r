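#' @importFrom utils packageVersion head tail modifyList
NULL

# Lightweight leveled logger. Messages go to stderr via message(); when
# `asiteIP.log_file` option is set they are appended there as well.
.log_levels <- c(DEBUG = 10L, INFO = 20L, WARNING = 30L, ERROR = 40L)

asite_log <- function(level, ...) {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("asiteIP.log_level", "INFO")
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ",
                paste0(..., collapse = ""))
  logfile <- getOption("asiteIP.log_file", NULL)
  if (!is.null(logfile)) cat(msg, "\n", sep = "", file = logfile, append = TRUE)
  if (.log_levels[[level]] >= .log_levels[[threshold]]) message(msg)
  invisible(msg)
}

# stop() wrapper that also records the failing stage in the log
asite_stop <- function(...) {
  msg <- paste0(...)
  asite_log("ERROR", msg)
  stop(msg, call. = FALSE)
}

asite_warn <- function(...) {
  msg <- paste0(...)
  asite_log("WARNING", msg)
  warning(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
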