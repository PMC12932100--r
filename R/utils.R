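#' Evaluate an expression under a local random seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed}, restoring the global
#' RNG state afterwards so seeded package operations never perturb a user's
#' random stream.
#'
#' @param seed integer seed, or \code{NULL} to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize the stream before snapshotting it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# clamp to the 8-bit intensity range and round to whole levels
clip8 <- function(x) {
  pmin(pmax(round(x), 0), 255)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# scalar finite numeric check used by config validators
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
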