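# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the caller's `.Random.seed`
#' afterwards so that no package function leaves a trace in the global RNG
#' state. All stochastic generators in the package route their randomness
#' through this helper with an explicit `seed` argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Smallest power of two >= x (x >= 1).
next_pow2 <- function(x) {
  stopifnot(x >= 1)
  2^ceiling(log2(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fbft <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fbft_error")))
}
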