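#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed without clobbering the caller's
## RNG stream. Every stochastic entry point in the package funnels through
## this helper so that a single integer seed makes a whole run reproducible.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a user seed, kept inside the
## 32-bit signed integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

## Percentile rank of each value within a vector: 100 * (# strictly
## smaller) / n. This convention makes thresholding deterministic under
## ties and is the one the suspect-record detector documents.
percentileRank <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  100 * (rank(x, ties.method = "min") - 1) / n
}

## Population standard deviation (divide by n), so a single measurement has
## spread exactly 0 without special-casing.
popSd <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
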