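# Univariate stages of the analysis workflow: normality description,
# two-sample comparison and correlation.

#' Normality description of a feature
#'
#' Moments plus the two standard normality tests. Skewness and excess
#' kurtosis use the bias-corrected (type 2) estimators so that normal samples
#' cluster near zero. The Kolmogorov-Smirnov test defaults to the
#' Lilliefors-corrected variant, appropriate when mean and SD are estimated
#' from the same sample; the naive fitted-normal KS is available.
#'
#' @param x numeric vector, `n >= 8`, non-constant.
#' @param ks_variant `"lilliefors"` (default) or `"fitted_normal"`.
#' @return A one-row data frame of class `normality_result`: `n`, `mean`,
#'   `sd`, `skewness`, `excess_kurtosis`, `ks_D`, `ks_p`, `sw_W`, `sw_p`.
#' @export
describe_normality <- function(x, ks_variant = c("lilliefors",
                                                 "fitted_normal")) {
  ks_variant <- match.arg(ks_variant)
  x <- x[is.finite(x)]
  if (length(x) < 8) stopf("need at least 8 finite observations")
  if (sd(x) == 0) stopf("constant vector: normality tests undefined")
  ks <- if (ks_variant == "lilliefors") {
    nortest::lillie.test(x)
  } else {
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  sw <- shapiro.test(x)
  out <- data.frame(n = length(x), mean = mean(x), sd = sd(x),
                    skewness = e1071::skewness(x, type = 2),
                    excess_kurtosis = e1071::kurtosis(x, type = 2),
                    ks_D = unname(ks$statistic), ks_p = ks$p.value,
                    sw_W = unname(sw$statistic), sw_p = sw$p.value)
  class(out) <- c("normality_result", "data.frame")
  out
}

ttest_result <- function(t, df, p, m1, s1, n1, m2, s2, n2, variant) {
  out <- data.frame(t = t, df = df, p = p,
                    mean_1 = m1, sd_1 = s1, n_1 = n1,
                    mean_2 = m2, sd_2 = s2, n_2 = n2,
                    variant = variant)
  class(out) <- c("ttest_result", "data.frame")
  out
}

#' Independent two-sample t-test
#'
#' Welch (default) or pooled-variance Student statistics, two-sided.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param variant `"welch"` or `"student"`.
#' @return A one-row data frame of class `ttest_result`.
#' @export
two_sample_ttest <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stopf("need n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(ttest_result(0, length(x) + length(y) - 2, 1,
                          mean(x), 0, length(x), mean(y), 0, length(y),
                          variant))
    }
    stopf("zero variance in both groups with unequal means")
  }
  tt <- t.test(x, y, var.equal = (variant == "student"))
  ttest_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
               mean(x), sd(x), length(x), mean(y), sd(y), length(y), variant)
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form Welch or Student test from printed group means, SDs and sizes;
#' agrees with [two_sample_ttest()] on the underlying raw data to numerical
#' precision.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param variant `"welch"` or `"student"`.
#' @return A one-row data frame of class `ttest_result`.
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2,
                               variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stopf("need n >= 2 per group")
  if (s1 < 0 || s2 < 0) stopf("standard deviations must be non-negative")
  if (s1 == 0 && s2 == 0) stopf("zero variance in both groups")
  if (variant == "welch") {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  ttest_result(t, df, 2 * pt(-abs(t), df), m1, s1, n1, m2, s2, n2, variant)
}

#' Correlation between two features
#'
#' Spearman by default (rank correlation, reported as rho); Pearson
#' available. Both use the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom for the
#' two-sided p-value, which is what [corr_pvalue_from_r()] recomputes from a
#' printed coefficient.
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row data frame of class `correlation_result`: `method`, `r`,
#'   `n`, `t_stat`, `p`.
#' @export
correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 paired observations")
  r <- cor(x, y, method = method)
  p <- corr_pvalue_from_r(r, n)
  t_stat <- if (abs(r) < 1) r * sqrt((n - 2) / (1 - r^2)) else Inf * sign(r)
  out <- data.frame(method = method, r = r, n = n, t_stat = t_stat, p = p)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' p-value from a printed correlation coefficient
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @param n sample size (> 2).
#' @return Two-sided p-value from the t approximation; exactly 0 when
#'   `|r| = 1`.
#' @export
#' @examples
#' corr_pvalue_from_r(0.317, 50)
corr_pvalue_from_r <- function(r, n) {
  if (any(abs(r) > 1)) stopf("|r| must not exceed 1")
  if (n <= 2) stopf("n must exceed 2")
  ifelse(abs(r) == 1, 0,
         2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
}
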