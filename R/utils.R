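## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards.  All stochastic
## functions in the package take an explicit seed and route through
## this, so they are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministic hash of a stage label folded into a master seed,
#' yielding an integer in `[0, 2^31)`.  One master seed thus fans out
#' to independent, reproducible per-stage RNG streams without manual
#' seed bookkeeping.
#'
#' @param master Master seed (integer-valued).
#' @param label Stage label, e.g. `"kinetics/WT"`.
#' @return An integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 * 2654435 + h) %% 2147483647)
}

## Stop with a classed condition so callers/tests can distinguish
## failure modes (config vs data vs numerical).
tf_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "templefold_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

tf_warn <- function(class, msg, ...) {
  warning(structure(class = c(class, "templefold_warning", "warning", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
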