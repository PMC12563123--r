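# Statistical protocol for descriptor samples: Shapiro-Wilk normality,
# Filliben probability-plot R^2, Welch's t-test with Welch-Satterthwaite
# degrees of freedom, and box-plot distribution summaries.
#
# Shapiro-Wilk and Welch are implemented from their defining formulas (with
# Royston's 1995 coefficient and p-value approximations for Shapiro-Wilk);
# the test suite checks them against the independent reference
# implementations in the stats package.

#' Shapiro-Wilk normality test
#'
#' `W = (sum a_i x_(i))^2 / sum (x_i - mean)^2` with weights `a_i` from the
#' expected normal order statistics. Coefficients and p-values follow
#' Royston's approximation (AS R94), the standard computational route for
#' sample sizes 3 to 5000; small samples are particularly well served, which
#' is why the protocol leans on this test.
#'
#' @param x Numeric sample, 3 <= n <= 5000, finite, non-constant.
#' @return A list with `W` and `p_value`.
#' @examples
#' shapiro_wilk(c(1, 2, 3))$W  # exactly 1
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("shapiro_wilk() requires 3 <= n <= 5000", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  xs <- sort(x)
  m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  summ2 <- sum(m^2)
  if (n == 3) {
    a <- c(-sqrt(0.5), 0, sqrt(0.5))
  } else {
    rsn <- 1 / sqrt(n)
    poly <- function(cc) sum(cc * rsn^(seq_along(cc) - 1))
    c_n <- m[n] / sqrt(summ2)
    a_n <- c_n + poly(c(0, 0.221157, -0.147981, -2.071190, 4.434685,
                        -2.706056))
    if (n <= 5) {
      phi <- (summ2 - 2 * m[n]^2) / (1 - 2 * a_n^2)
      a <- m / sqrt(phi)
      a[n] <- a_n
      a[1] <- -a_n
    } else {
      c_n1 <- m[n - 1] / sqrt(summ2)
      a_n1 <- c_n1 + poly(c(0, 0.042981, -0.293762, -1.752461, 5.682633,
                            -3.582633))
      phi <- (summ2 - 2 * m[n]^2 - 2 * m[n - 1]^2) /
             (1 - 2 * a_n^2 - 2 * a_n1^2)
      a <- m / sqrt(phi)
      a[n] <- a_n;     a[1] <- -a_n
      a[n - 1] <- a_n1; a[2] <- -a_n1
    }
  }
  W <- sum(a * xs)^2 / sum((xs - mean(xs))^2)
  W <- min(W, 1)
  # p-value approximations (Royston 1995)
  if (n == 3) {
    pi6 <- 6 / pi
    stqr <- asin(sqrt(0.75))
    p <- pi6 * (asin(sqrt(W)) - stqr)
    p <- min(max(p, 0), 1)
  } else if (n <= 11) {
    gamma <- -2.273 + 0.459 * n
    w_ <- -log(gamma - log1p(-W))
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    p <- stats::pnorm((w_ - mu) / sig, lower.tail = FALSE)
  } else {
    ln <- log(n)
    w_ <- log1p(-W)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    p <- stats::pnorm((w_ - mu) / sig, lower.tail = FALSE)
  }
  list(W = W, p_value = p)
}

#' Filliben plotting probabilities
#'
#' Rank-based probability estimates for normal probability plots:
#' `p_1 = 1 - 0.5^(1/n)`, `p_i = (i - 0.3175)/(n + 0.365)` for the interior
#' ranks, `p_n = 0.5^(1/n)`. Ascending in i, and symmetric:
#' `p_i + p_(n+1-i) = 1`.
#'
#' @param n Sample size, at least 2.
#' @return Numeric vector of n strictly increasing probabilities.
#' @export
filliben_quantiles <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("filliben_quantiles() requires n >= 2",
                              call. = FALSE)
  p <- (seq_len(n) - 0.3175) / (n + 0.365)
  p[1] <- 1 - 0.5^(1 / n)
  p[n] <- 0.5^(1 / n)
  p
}

#' Normal probability-plot R-squared
#'
#' Coefficient of determination of the ordered sample against standard
#' normal quantiles evaluated at the Filliben probabilities. Values near 1
#' support normality.
#'
#' @param x Numeric sample, n >= 3, non-constant.
#' @return R-squared in [0, 1].
#' @export
probability_plot_r2 <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("probability_plot_r2() requires n >= 3",
                          call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  q <- stats::qnorm(filliben_quantiles(length(x)))
  stats::cor(sort(x), q)^2
}

#' Combined normality screen
#'
#' The two-part normality rule used throughout the pipeline: a sample is
#' "normal-supported" iff the Shapiro-Wilk p-value exceeds 0.05 AND the
#' probability-plot R-squared exceeds 0.9; otherwise "rejected".
#'
#' @param x Numeric sample, n >= 3.
#' @return A list with `W`, `p_value`, `r_squared`, `verdict`.
#' @export
normality_screen <- function(x) {
  sw <- shapiro_wilk(x)
  r2 <- probability_plot_r2(x)
  list(W = sw$W, p_value = sw$p_value, r_squared = r2,
       verdict = if (sw$p_value > 0.05 && r2 > 0.9) "normal-supported"
                 else "rejected")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance comparison of two sample means:
#' `t = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)`, with degrees of freedom
#' from the Welch-Satterthwaite approximation and a two-sided p-value.
#'
#' @param x,y Numeric samples, each n >= 2, finite, not both constant.
#' @return A list with `t`, `df`, `p_value` and `significant` (p < 0.05).
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("welch_t() requires n >= 2 in both samples",
                             call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    stop("degenerate samples: both variances are zero", call. = FALSE)
  }
  se2 <- v1 / n1 + v2 / n2
  t_ <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_), df, lower.tail = FALSE)
  list(t = t_, df = df, p_value = p, significant = p < 0.05)
}

#' Box-plot distribution summary
#'
#' Mean, quartiles (linear interpolation between closest ranks, i.e.
#' quantile type 7), whiskers at the most extreme values within 1.5 times
#' the interquartile range of the quartiles, and the outliers beyond them.
#'
#' @param x Numeric sample, n >= 1.
#' @return A list with `mean`, `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
summarize_distribution <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 1, all(is.finite(x)))
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(mean = mean(x), q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]))
}
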