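# Internal helpers shared across the pipeline stages.

# Signal a classed error so callers can distinguish failure modes
# programmatically (all conditions also inherit from "tepsig_error").
stop_tep <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "tepsig_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_tep <- function(msg) warning(msg, call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded operations never perturb the global stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of distinct 31-bit sub-seeds from one user seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
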