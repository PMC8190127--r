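# Outlier screening and pairwise comparisons used across the plate-level
# reports.

#' Significance stars
#'
#' Maps a p-value to the reporting convention
#' `* p <= 0.05, ** p <= 0.01, *** p <= 0.001, **** p <= 0.0001`
#' (`"ns"` otherwise).
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 1e-2) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs screen: `G = max |x_i - mean| / sd`, compared with the
#' critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` quantile of the t distribution with `n - 2` degrees
#' of freedom. At most one observation is flagged per call; iterate
#' externally to screen repeatedly. A zero-variance sample has no
#' outliers by definition.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level (default 0.05).
#' @return A list with `outlier_index` (`NA` when nothing is flagged),
#'   `outlier_value`, `statistic` (G), `critical` and `flagged`.
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(outlier_index = NA_integer_, outlier_value = NA_real_,
                statistic = 0, critical = NA_real_, flagged = FALSE))
  }
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  flagged <- g > crit
  list(outlier_index = if (flagged) which.max(dev) else NA_integer_,
       outlier_value = if (flagged) values[which.max(dev)] else NA_real_,
       statistic = g, critical = crit, flagged = flagged)
}

#' Pairwise Welch comparison of two groups
#'
#' Two-sided two-sample t test. The default is Welch's unequal-variance
#' form (with Welch-Satterthwaite degrees of freedom); set
#' `var_equal = TRUE` for the pooled-variance Student form. Reports group
#' summaries, the test statistic, the p-value and significance stars.
#'
#' @param x,y Numeric vectors, n >= 2 each with positive variance in at
#'   least one group.
#' @param var_equal Use pooled variance instead of Welch (default FALSE).
#' @param labels Length-2 character vector of group labels.
#' @return An object of class `comparison_result` (a list with `labels`,
#'   `means`, `sds`, `n`, `statistic`, `df`, `p_value`, `stars`).
#' @export
pairwise_welch <- function(x, y, var_equal = FALSE,
                           labels = c("group1", "group2")) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                  p.value = 1)
    } else {
      stop("both groups are constant with different means: ",
           "t statistic undefined", call. = FALSE)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(labels = labels,
                 means = c(mean(x), mean(y)),
                 sds = c(stats::sd(x), stats::sd(y)),
                 n = c(length(x), length(y)),
                 statistic = res$statistic,
                 df = res$parameter,
                 p_value = res$p.value,
                 stars = significance_stars(res$p.value)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (n=%d): %.4g +/- %.4g  vs  %s (n=%d): %.4g +/- %.4g\n",
              x$labels[1], x$n[1], x$means[1], x$sds[1],
              x$labels[2], x$n[2], x$means[2], x$sds[2]))
  cat(sprintf("t = %.4g, df = %.3g, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}
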