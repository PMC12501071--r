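#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats cor cutree dist hclust median p.adjust pchisq prcomp
#'   quantile rbinom rexp rgamma rlnorm rnbinom rnorm runif sd setNames
#'   var wilcox.test pnorm as.dist
#' @importFrom utils read.delim write.table head
NULL

.am_env <- new.env(parent = emptyenv())

#' Direct pipeline log output
#'
#' Messages emitted by the pipeline (removed-cell counts, skipped tumors,
#' clamp counts, ...) go through a single sink. By default they are plain
#' `message()`s; `am_log_file()` additionally appends them to a file.
#'
#' @param path Path of a plain-text log file, or `NULL` to disable.
#' @return Previous path, invisibly.
#' @export
am_log_file <- function(path = NULL) {
  old <- .am_env$log_file
  .am_env$log_file <- path
  invisible(old)
}

am_log <- function(...) {
  txt <- paste0(...)
  if (!is.null(.am_env$log_file)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), txt, "\n",
        file = .am_env$log_file, append = TRUE, sep = "")
  }
  message(txt)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# argmax with deterministic tie-break towards the first (lowest) name
which_max_first <- function(x) which(x == max(x))[1L]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
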