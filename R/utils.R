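# Internal helpers shared across the package.

# Clamp x into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Two-sided p-value for a Pearson correlation
#'
#' Closed-form t-test for a correlation coefficient: t = r sqrt(n-2)/sqrt(1-r^2)
#' on n - 2 degrees of freedom. With 9 samples this gives 7 df.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param n Number of paired observations (n > 2).
#' @return Two-sided p-value(s).
#' @keywords internal
cor_test_pvalue <- function(r, n) {
  if (n <= 2) stop("correlation p-value requires n > 2")
  r <- clamp(r, -1, 1)
  df <- n - 2
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
# All package randomness flows through this helper so identical seeds give
# byte-identical output without clobbering the user's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# stopifnot-with-message for scalar numeric arguments
check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
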