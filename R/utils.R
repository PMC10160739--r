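#' @keywords internal
#' @useDynLib swindiff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip values to a range
#' @param x numeric vector/array
#' @param lo,hi range limits
#' @return x with values outside [lo, hi] replaced by the nearest limit
#' @export
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evenly spaced numbers (inclusive endpoints)
#' @param from,to endpoints
#' @param n number of points
#' @keywords internal
linspace <- function(from, to, n) {
  if (n == 1L) return(from)
  from + (seq_len(n) - 1) * (to - from) / (n - 1)
}

# Derive a reproducible sub-seed from a master seed and a component label.
# Keeps results below 2^31 so set.seed() accepts them.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
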