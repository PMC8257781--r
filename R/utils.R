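# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number or NULL", call. = FALSE)
    }
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_numeric_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and free of NA", name),
         call. = FALSE)
  }
  invisible(x)
}

is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 1) && all(x == round(x))
}
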