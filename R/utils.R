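#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not disturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

## Deterministic derivation of sub-stream seeds from a root seed.
## Kept below 2^31 - 1; the multiplier is an arbitrary prime.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

is_number <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && is.finite(x)
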