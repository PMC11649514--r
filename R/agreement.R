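# Method-comparison statistics: consensus averaging, Spearman correlation,
# Bland-Altman limits of agreement with >1.96 SD case listing, paired t-test,
# and Table-style distribution summaries.

#' Consensus of two observers' scores
#' @param obs1,obs2 equal-length numeric vectors (PI %).
#' @return element-wise arithmetic mean.
#' @export
consensus_mean <- function(obs1, obs2) {
  if (length(obs1) != length(obs2)) stop("score vectors differ in length")
  (obs1 + obs2) / 2
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Undefined (NA)
#' when either argument has zero rank variance.
#'
#' @param a,b numeric vectors, length >= 3.
#' @return correlation in [-1, 1], or NA when undefined.
#' @export
spearman_r <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(rank(a)) == 0 || stats::sd(rank(b)) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' Paired scores of two scoring methods
#' @param case_ids identifiers.
#' @param a,b PI scores (%) of methods A and B, pairwise complete.
#' @param label_a,label_b method labels.
#' @return object of class `paired_scores`.
#' @export
paired_scores <- function(case_ids, a, b, label_a = "A", label_b = "B") {
  if (length(a) != length(b) || length(a) != length(case_ids)) {
    stop("case ids and score vectors differ in length")
  }
  if (length(a) < 3) stop("need at least 3 paired cases")
  if (anyNA(a) || anyNA(b)) stop("paired scores must be complete (exclude unscored cases pairwise)")
  if (any(c(a, b) < 0 | c(a, b) > 100)) stop("PI scores must lie in [0, 100]")
  structure(list(case_ids = case_ids, a = a, b = b,
                 label_a = label_a, label_b = label_b),
            class = "paired_scores")
}

#' Bland-Altman agreement analysis
#'
#' Differences d = A - B; mean and SD (n-1 denominator); limits of agreement
#' mean +/- 1.96 SD; cases with |d - mean| strictly greater than 1.96 SD are
#' listed as outside. Also carries the Spearman r, Pearson r and paired t of
#' the pair, and the plot payload (per-case means vs differences).
#'
#' @param pairs a [paired_scores()].
#' @return object of class `agreement_report`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$a - pairs$b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  outside <- which(abs(d - m) > 1.96 * s)
  tt <- paired_t(pairs$a, pairs$b)
  pear <- if (stats::sd(pairs$a) == 0 || stats::sd(pairs$b) == 0) {
    NA_real_
  } else {
    stats::cor(pairs$a, pairs$b)
  }
  structure(list(n = n, label_a = pairs$label_a, label_b = pairs$label_b,
                 spearman_r = spearman_r(pairs$a, pairs$b),
                 pearson_r = pear,
                 mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 outside_cases = pairs$case_ids[outside],
                 outside_fraction = length(outside) / n,
                 t_statistic = tt$t, t_p_value = tt$p,
                 means = (pairs$a + pairs$b) / 2, differences = d,
                 case_ids = pairs$case_ids),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("%s vs %s (n = %d)\n", x$label_a, x$label_b, x$n))
  cat(sprintf("  Spearman r %.3f | Pearson r %.3f\n", x$spearman_r, x$pearson_r))
  cat(sprintf("  mean diff %.2f, SD %.2f, LoA [%.2f, %.2f]\n",
              x$mean_difference, x$sd_difference, x$loa_low, x$loa_high))
  cat(sprintf("  outside >1.96 SD: %d (%.1f%%) | paired t %.2f, p %.3g\n",
              length(x$outside_cases), 100 * x$outside_fraction,
              x$t_statistic, x$t_p_value))
  invisible(x)
}

#' Paired-samples t-test
#'
#' t = mean(d) / (sd(d) / sqrt(n)), df = n - 1, two-sided p. Degenerate
#' variance: zero mean gives an undefined t (NA); a non-zero constant
#' difference is reported as +/- Inf with p = 0 (documented convention).
#'
#' @param a,b numeric vectors, length >= 2.
#' @return list(t, df, p).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = NA_real_, df = n - 1, p = NA_real_))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Distribution summary (mean, min, Q1, median, Q3, max)
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention fixed for all reported tables.
#'
#' @param x numeric vector, length >= 1.
#' @return named numeric vector.
#' @export
summarize_distribution <- function(x) {
  if (!length(x)) stop("empty input")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(x), min = min(x), q1 = q[1], median = q[2], q3 = q[3],
    max = max(x))
}

#' Bland-Altman plot of an agreement report
#' @param report an [bland_altman()] result.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(report) {
  df <- data.frame(mean = report$means, difference = report$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = report$mean_difference, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = sprintf("mean of %s and %s (PI %%)",
                              report$label_a, report$label_b),
                  y = sprintf("%s - %s (PI %%)", report$label_a, report$label_b),
                  title = sprintf("Bland-Altman: %s vs %s",
                                  report$label_a, report$label_b)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an agreement report
#' @param report an [bland_altman()] result.
#' @return a ggplot object.
#' @export
plot_score_scatter <- function(report) {
  df <- data.frame(a = report$means + report$differences / 2,
                   b = report$means - report$differences / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = b, y = a)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("%s (PI %%)", report$label_b),
                  y = sprintf("%s (PI %%)", report$label_a),
                  title = sprintf("r = %.2f (Spearman)", report$spearman_r)) +
    ggplot2::theme_minimal()
}
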