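#' @import data.table
#' @importFrom methods is
#' @importFrom stats median pnorm rnbinom rlnorm runif setNames
#' @importFrom utils combn head tail
NULL

.kiwipan_env <- new.env(parent = emptyenv())

#' Run an expression with a private RNG state
#'
#' Seeds the RNG with `seed`, evaluates `expr`, then restores the caller's
#' `.Random.seed`, so library calls never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# -- logging ------------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set the package log level
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- if (is.null(.kiwipan_env$log_level)) "info" else .kiwipan_env$log_level
  .kiwipan_env$log_level <- level
  invisible(old)
}

kp_log <- function(level, ...) {
  cur <- if (is.null(.kiwipan_env$log_level)) "info" else .kiwipan_env$log_level
  if (.log_levels[[level]] >= .log_levels[[cur]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# -- small helpers ------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest-remainder apportionment of `n` into integer counts
#'
#' @param n total count.
#' @param proportions numeric vector summing to 1.
#' @return integer vector summing to `n`, names preserved.
#' @keywords internal
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")")
  }
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    # deterministic tie-break: larger remainder first, then earlier index
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  setNames(as.integer(counts), names(proportions))
}

#' Deterministic random DNA string(s)
#' @keywords internal
random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}
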