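# Small shared helpers.

#' Round half away from zero
#'
#' Fixed-decimal rounding where ties go away from zero (so 0.435 -> 0.44 and
#' -0.435 -> -0.44), the convention used when comparing recomputed statistics
#' with values printed at two decimals. Base \code{round()} rounds half to
#' even and is not suitable for that comparison.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' roundHalfAway(c(0.435, -0.435, 2.124), 2)
#' @export
roundHalfAway <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.assertNumericVector <- function(x, what, minLength = 1L) {
  if (!is.numeric(x) || length(x) < minLength) {
    stop("'", what, "' must be a numeric vector of length >= ", minLength,
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("'", what, "' contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

# smallest admissible p-value: the contract is p in (0, 1], never 0
.clampP <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)
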