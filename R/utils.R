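# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that package functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Byte-wise (locale-independent) string ordering; keeps pathway / gene IDs
# reproducible across platforms.
order_bytes <- function(...) order(..., method = "radix")

sort_bytes <- function(x) x[order_bytes(x)]

# Byte-wise rank of each string within the pooled vocabulary; used to put
# unordered pairs into canonical (lo, hi) form without locale-dependent `<`.
pair_canonical <- function(a, b) {
  lev <- sort_bytes(unique(c(a, b)))
  ra <- match(a, lev)
  rb <- match(b, lev)
  swap <- ra > rb
  list(
    a = ifelse(swap, b, a),
    b = ifelse(swap, a, b),
    degenerate = ra == rb
  )
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
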