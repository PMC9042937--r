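# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

abort_if <- function(cond, msg) if (isTRUE(cond)) rlang::abort(msg)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == trunc(x)

# derive a per-stage 31-bit seed from a master seed (stable, documented fan-out)
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483647)
}
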