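# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the generator seeded at `seed` and restores the caller's
#' random stream afterwards, so seeded package functions never disturb user
#' simulations.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit substream seed from a root seed and a string key.
# Polynomial rolling hash modulo a prime below 2^31, so the result is always
# a valid argument to set.seed() and intermediate products stay well inside
# the exact-double range (31 * 2^31 << 2^53).
substream_seed <- function(seed, keys) {
  M <- 2147483629
  seed <- as.numeric(seed) %% M
  vapply(keys, function(k) {
    h <- seed
    for (b in utf8ToInt(k)) h <- (h * 31 + b) %% M
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
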