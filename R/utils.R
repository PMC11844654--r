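# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed: must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with the offending field named first, for config validation.
fail_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_prob_vector <- function(p, field, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    fail_field(field, "probabilities must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > tol) {
    fail_field(field, sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
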