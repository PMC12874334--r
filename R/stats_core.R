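#' Two-sided Welch's t-test for two groups
#'
#' Unequal-variance two-sample t-test with the Welch-Satterthwaite degrees of
#' freedom, the two-group comparison used throughout the pipeline (mutational
#' burden, module scores, deconvolution scores, methylation M-values).
#'
#' Degenerate inputs follow fixed conventions rather than producing `NaN`:
#' when both groups have zero variance the test returns `t = 0, p = 1` for
#' equal means and `p = 0` (with infinite `t` of the appropriate sign) for
#' unequal means, so that exactly-tied small-sample comparisons still rank.
#'
#' @param a,b Numeric vectors, one per group; each must contain at least two
#'   non-missing observations.
#' @return A list with elements `t`, `df` and `p` (two-sided).
#' @examples
#' welch_t_test(c(4, 5, 6), c(1, 2, 3))
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: each group needs at least 2 observations")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = 0))
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' Product-moment correlation; the p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' correlation of exactly +/-1 (legitimate at n = 3) clamps the p-value to 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; both must be
#'   non-constant, otherwise the correlation is undefined and an error is
#'   raised (callers decide how to handle exclusion).
#' @return A list with elements `r` and `p`.
#' @examples
#' pearson_corr_test(c(1, 2, 3), c(3, 2, 1))
#' @export
pearson_corr_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("pearson_corr_test: unequal lengths")
  n <- length(x)
  if (n < 3L) stop("pearson_corr_test: need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("pearson_corr_test: missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_corr_test: constant input vector, correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) >= 1 - 1e-12) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement. Length and input
#' order are preserved; permuting the input permutes the output identically.
#'
#' @param raw_p Numeric vector of p-values in `[0, 1]`.
#' @return A list with `raw_p` and `adjusted_p` (same length and order).
#' @export
bh_adjust <- function(raw_p) {
  p <- as.numeric(raw_p)
  if (length(p) == 0L) return(list(raw_p = p, adjusted_p = p))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  list(raw_p = p, adjusted_p = adj)
}
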