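#' Tukey box-plot outlier removal
#'
#' Removes values above `Q3 + 1.5 IQR` or below `Q1 - 1.5 IQR`, with
#' quartiles by linear interpolation between order statistics
#' (`quantile(type = 7)`). Collections smaller than 4 are returned unchanged
#' with a warning.
#'
#' @param values numeric vector.
#' @param k whisker multiplier (default 1.5).
#' @return Filtered numeric vector.
#' @export
tukey_filter <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) {
    warning("fewer than 4 values: outlier filter skipped")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' Two-group comparison with normality- and variance-driven test choice
#'
#' The fixed comparison procedure applied to every dynamics metric: Tukey
#' outlier removal per group, Shapiro-Wilk normality check per group at
#' alpha 0.05; if both groups pass, Levene's test decides between the
#' pooled-variance and Welch t-tests; if either fails, the two-sided
#' rank-sum (Wilcoxon) test is used. Raw p-values are reported without
#' multiplicity correction.
#'
#' @param a,b numeric vectors (each >= 3 values after filtering).
#' @param alpha significance threshold (default 0.05).
#' @param metric label recorded on the result.
#' @return A `comparison_result`: `metric`, `n` (group sizes after
#'   filtering), `test` (one of `"t-equal-var"`, `"t-unequal-var"`,
#'   `"rank-sum"`), `statistic`, `p_value`, `significant`, `checks`
#'   (the normality and variance p-values that drove the branch).
#' @export
compare_groups <- function(a, b, alpha = 0.05, metric = "metric") {
  a <- tukey_filter(a)
  b <- tukey_filter(b)
  if (length(a) < 3L || length(b) < 3L) {
    warning("insufficient observations after outlier removal")
    return(structure(
      list(metric = metric, n = c(length(a), length(b)), test = NA_character_,
           statistic = NA_real_, p_value = NA_real_, significant = NA,
           checks = NULL),
      class = "comparison_result"))
  }
  sw_a <- tryCatch(stats::shapiro.test(a)$p.value, error = function(e) 0)
  sw_b <- tryCatch(stats::shapiro.test(b)$p.value, error = function(e) 0)
  normal <- sw_a > 0.05 && sw_b > 0.05
  checks <- list(shapiro_a = sw_a, shapiro_b = sw_b, levene = NA_real_)
  if (normal) {
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(c(a, b) ~ grp)
    checks$levene <- lev[["Pr(>F)"]][1]
    equal_var <- checks$levene > 0.05
    ht <- stats::t.test(a, b, var.equal = equal_var)
    test <- if (equal_var) "t-equal-var" else "t-unequal-var"
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    test <- "rank-sum"
  }
  structure(
    list(metric = metric, n = c(length(a), length(b)), test = test,
         statistic = unname(ht$statistic), p_value = ht$p.value,
         significant = ht$p.value < alpha, checks = checks),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s, stat = %.4g, p = %.4g%s\n",
              x$metric, x$test, x$statistic, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
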