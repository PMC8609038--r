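#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils read.csv write.csv read.delim write.table packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ag <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_ag(msg)
  invisible(TRUE)
}

#' Derive a child seed from a top-level seed
#'
#' All generators in the package draw their randomness from one top-level
#' seed; independent streams (one per well, per image, per matrix) are derived
#' with this rule so that adding wells or reordering calls never perturbs the
#' other streams.  The rule is a Lehmer step modulo the Mersenne prime
#' 2^31 - 1, mapped away from 0.
#'
#' @param seed integer top-level seed.
#' @param index non-negative integer stream index.
#' @return a scalar integer usable with [set.seed()].
#' @export
split_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + as.double(index) * 9973 + 1
  as.integer(s %% m)
}

# Evaluate expr under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pearson correlation of two numeric vectors after removing pairwise NAs.
# Thin wrapper used by the image and omics layers so the guard logic
# (length, constancy) lives in one place.
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
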