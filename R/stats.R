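new_stat_result <- function(statistic, df, p_value, estimate, conf_low,
                            conf_high, cohens_d, method, degenerate = FALSE) {
  out <- tibble(statistic = statistic, df = df, p_value = p_value,
                estimate = estimate, conf_low = conf_low,
                conf_high = conf_high, cohens_d = cohens_d, method = method,
                degenerate = degenerate)
  class(out) <- c("stat_result", class(out))
  out
}

#' Two-sample t-test with effect size
#'
#' Two-tailed t-test of the difference in means, pooled-variance Student
#' form by default (Welch available), with Cohen's d computed from the
#' pooled SD and a 95% confidence interval of the difference. If both
#' groups have zero variance and equal means the statistic is 0 by
#' convention and the result is flagged degenerate.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @param kind `"pooled"` (Student) or `"welch"`.
#' @param conf_level Confidence level for the difference CI.
#' @return A one-row `stat_result` tibble with columns `statistic`, `df`,
#'   `p_value`, `estimate` (mean difference), `conf_low`, `conf_high`,
#'   `cohens_d`, `method`, `degenerate`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(x, y, kind = c("pooled", "welch"),
                         conf_level = 0.95) {
  kind <- match.arg(kind)
  stopifnot(length(x) >= 2, length(y) >= 2)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    md <- mean(x) - mean(y)
    if (md == 0) {
      warn("zero variance in both groups with equal means; t = 0 by convention")
      return(new_stat_result(0, nx + ny - 2, 1, 0, 0, 0, 0,
                             paste0("two-sample (", kind, ")"),
                             degenerate = TRUE))
    }
    warn("zero within-group variance with unequal means; perfect separation, statistic infinite")
    return(new_stat_result(sign(md) * Inf, nx + ny - 2, 0, md, md, md,
                           sign(md) * Inf, paste0("two-sample (", kind, ")"),
                           degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = (kind == "pooled"),
               conf.level = conf_level)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  new_stat_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  unname(diff(rev(tt$estimate))), tt$conf.int[1],
                  tt$conf.int[2], d, paste0("two-sample (", kind, ")"))
}

#' Paired t-test
#'
#' One-sample t-test on the within-pair differences (`df = n - 1`). All-
#' equal nonzero differences have zero SD; the result is flagged degenerate
#' with an infinite statistic rather than erroring, since the direction is
#' still interpretable.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @param conf_level Confidence level for the mean-difference CI.
#' @return A one-row `stat_result` tibble; `cohens_d` is the paired effect
#'   size (mean difference / SD of differences).
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(new_stat_result(0, n - 1, 1, 0, 0, 0, 0, "paired",
                             degenerate = TRUE))
    warn("zero SD of nonzero differences; statistic infinite (degenerate)")
    return(new_stat_result(sign(mean(d)) * Inf, n - 1, 0, mean(d), mean(d),
                           mean(d), sign(mean(d)) * Inf, "paired",
                           degenerate = TRUE))
  }
  tt <- t.test(d, conf.level = conf_level)
  new_stat_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  mean(d), tt$conf.int[1], tt$conf.int[2],
                  mean(d) / sd(d), "paired")
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normal-approximation z-scores of sample skewness and
#' kurtosis into the K-squared statistic, referred to a chi-squared
#' distribution with 2 df. Used here as the gate for parametric testing
#' (proceed parametric when p > 0.05). Requires n >= 8, below which the
#' kurtosis approximation is invalid.
#'
#' @param x Numeric vector, n >= 8.
#' @return A one-row tibble with `k_squared`, `z_skewness`, `z_kurtosis`,
#'   `p_value`, `n`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) abort("dagostino_pearson requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3

  # skewness z (D'Agostino 1970 transformation)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983 transformation)
  e_g2 <- -6 / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - e_g2) / sqrt(var_g2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  term <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  z2 <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble(k_squared = k2, z_skewness = z1, z_kurtosis = z2,
         p_value = pchisq(k2, df = 2, lower.tail = FALSE), n = n)
}

#' Holm-Bonferroni step-down correction
#'
#' Step-down multiple-comparison control of the family-wise error rate:
#' p-values are sorted ascending, the i-th smallest is compared against
#' `alpha / (m - i + 1)`, and testing stops at the first failure (all later
#' hypotheses are retained). Adjusted p-values are the running-maximum
#' `min(1, (m - i + 1) p_(i))`, monotone by construction. Uniformly at
#' least as powerful as the plain Bonferroni correction.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate.
#' @return A tibble in the input order with columns `p_value`, `p_adjusted`,
#'   `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  o <- order(pvals)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (pvals[o[i]] < alpha / (m - i + 1)) reject_sorted[i] <- TRUE
    else break  # step-down stops at the first failure
  }
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  out <- tibble(p_value = pvals, p_adjusted = NA_real_, reject = NA)
  out$p_adjusted[o] <- adj_sorted
  out$reject[o] <- reject_sorted
  out
}
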