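`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards (same contract as simulate()'s seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "lpcscore_error")))
}

abort_format <- function(msg) abort(msg, "lpcscore_format_error")
abort_argument <- function(msg) abort(msg, "lpcscore_argument_error")

## Signalled when a kernel neighborhood is empty or a local covariance is
## degenerate; callers catch these to stop a traversal or skip a process.
signal_degenerate <- function(msg) abort(msg, "lpcscore_degenerate")

vec_norm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vec_norm(x)
  if (n == 0) signal_degenerate("cannot normalize a zero vector")
  x / n
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
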