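## Exact and closed-form statistics used throughout the pipeline.

#' Exact binomial sign test
#'
#' Tail probabilities of the binomial distribution at success probability
#' 1/2, computed exactly (no normal approximation).  The one-tailed value
#' is the upper tail P(X >= s | n, 1/2); the two-tailed value doubles the
#' smaller tail and is capped at 1.
#'
#' @param s Number of outcomes in the predicted direction.
#' @param n Number of trials.
#' @return List of class `"sign_test"` with elements `s`, `n`,
#'   `p_one_tailed`, `p_two_tailed`.
#' @export
#' @examples
#' sign_test(16, 20)$p_one_tailed  # 0.0059
#' sign_test(8, 8)$p_one_tailed    # 1 / 2^8
sign_test <- function(s, n) {
  if (length(s) != 1L || length(n) != 1L || is.na(s) || is.na(n)) {
    stop("s and n must be single non-missing values")
  }
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (s < 0 || s > n || s != round(s)) stop("s must be an integer in 0..n")
  s <- as.integer(s); n <- as.integer(n)
  upper <- pbinom(s - 1L, n, 0.5, lower.tail = FALSE)  # P(X >= s)
  lower <- pbinom(s, n, 0.5)                           # P(X <= s)
  structure(list(s = s, n = n,
                 p_one_tailed = upper,
                 p_two_tailed = min(1, 2 * min(lower, upper))),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf("Exact sign test: s = %d of n = %d, one-tailed P = %.4g, two-tailed P = %.4g\n",
              x$s, x$n, x$p_one_tailed, x$p_two_tailed))
  invisible(x)
}

#' Fisher's method for combining P values
#'
#' Combines k independent P values through the statistic -2 * sum(log(P)),
#' chi-square distributed with 2k degrees of freedom under the joint null.
#'
#' @param p Numeric vector of P values, each in (0, 1].
#' @return List with `chi_square`, `df` (= 2k) and the combined `p`.
#' @export
#' @examples
#' fisher_combine(c(0.01, 0.02, 0.5))
fisher_combine <- function(p) {
  if (length(p) == 0L) stop("no P values to combine")
  if (anyNA(p)) stop("P values must not be missing")
  if (any(p <= 0)) stop("P values must be > 0 (log undefined at 0)")
  if (any(p > 1)) stop("P values must be <= 1")
  chi <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi_square = chi, df = df, p = pchisq(chi, df, lower.tail = FALSE))
}

#' False-discovery-rate adjusted critical value for dependent tests
#'
#' For k tests performed at nominal level alpha, the mean
#' false-discovery-rate correction replaces alpha by
#' `alpha * (k + 1) / (2 * k)`, guarding against (possibly) dependent
#' tests without the full severity of a Bonferroni correction.
#'
#' @param alpha Nominal significance level, in (0, 1).
#' @param k Number of tests, a positive integer.
#' @return The adjusted critical value.
#' @export
#' @examples
#' fdr_critical(0.05, 10)  # 0.0275
#' fdr_critical(0.05, 20)  # 0.02625
fdr_critical <- function(alpha, k) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("k must be a positive integer")
  }
  alpha * (k + 1) / (2 * k)
}

.flagged_cor <- function(n, reason, alternative) {
  list(r = NA_real_, n = n, p_one_tailed = NA_real_, p_two_tailed = NA_real_,
       alternative = alternative, flagged = TRUE, reason = reason)
}

#' Pearson correlation with exact t-distribution P values
#'
#' Pearson's r with one- and two-tailed P values from the t
#' transformation `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom.  The one-tailed P defaults to the negative direction (the
#' prediction tested throughout this package).  Degenerate inputs (fewer
#' than 3 complete pairs, or a constant vector) return a flagged-missing
#' result with a `reason`, never an error or raw NaN.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alternative Direction of the one-tailed P: `"less"` (negative
#'   association, default), `"greater"`, or `"two.sided"` (one-tailed
#'   entry then equals the two-tailed P).
#' @return List with `r`, `n`, `p_one_tailed`, `p_two_tailed`,
#'   `alternative`, `flagged` (+ `reason` when flagged).
#' @export
#' @examples
#' pearson_test(1:5, c(5, 4, 3, 2, 1))$r  # -1
pearson_test <- function(x, y, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(.flagged_cor(n, "fewer than 3 complete pairs", alternative))
  if (sd(x) == 0 || sd(y) == 0) return(.flagged_cor(n, "constant input (zero variance)", alternative))
  r <- cor(x, y)
  r <- max(-1, min(1, r))
  df <- n - 2L
  tt <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p_less <- pt(tt, df)
  p_greater <- pt(tt, df, lower.tail = FALSE)
  p_two <- 2 * min(p_less, p_greater)
  p_one <- switch(alternative, less = p_less, greater = p_greater, two.sided = p_two)
  list(r = r, n = n, p_one_tailed = p_one, p_two_tailed = p_two,
       alternative = alternative, flagged = FALSE)
}

#' Spearman rank correlation
#'
#' Convenience wrapper: Pearson correlation of the (mid-)ranks of both
#' arguments, with P values from the same t transformation as
#' [pearson_test()].
#'
#' @inheritParams pearson_test
#' @return As [pearson_test()].
#' @export
spearman_test <- function(x, y, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  pearson_test(rank(x[ok]), rank(y[ok]), alternative = alternative)
}
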