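# Internal helpers shared across modules.

#' @importFrom stats runif rbinom plogis setNames cor.test chisq.test
#' @importFrom utils head read.delim write.table packageVersion
NULL

## Structured logging to stderr. Levels: DEBUG < INFO < WARN.
.log_level <- new.env(parent = emptyenv())
.log_level$level <- "INFO"

#' Set the package log level
#'
#' @param level one of "DEBUG", "INFO", "WARN".
#' @return the previous level, invisibly.
#' @export
cncLogLevel <- function(level = c("INFO", "DEBUG", "WARN")) {
  level <- match.arg(level)
  old <- .log_level$level
  .log_level$level <- level
  invisible(old)
}

cnc_log <- function(level, fmt, ...) {
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  if (ranks[[level]] < ranks[[.log_level$level]]) return(invisible(NULL))
  msg <- sprintf(fmt, ...)
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"), msg))
  invisible(NULL)
}

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. All stochastic entry points funnel through
## this so that a seed argument fully determines the result.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and a stream label, keeping the
## result inside the 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1103L + stream * 7919L) %% 2147483647
}

## Grouped row sums where the grouping vector is 1..n with every group
## non-empty (guaranteed here by self-loops / graph membership): the result
## of rowsum() is then already in group order.
group_rowsum <- function(x, group) {
  rowsum(x, group, reorder = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
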