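# Group-comparison statistics and broad-sense heritability. The t-test
# entry points accept either raw values or (mean, sd, n) summaries, so
# published group summaries can be re-analysed directly.

#' Summarize a group
#'
#' @param x numeric values (missing dropped).
#' @param label optional group label.
#' @return a `group_summary`: list with `label`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(x, label = NULL) {
  x <- x[!is.na(x)]
  structure(list(label = label, n = length(x), mean = mean(x), sd = sd(x)),
            class = "group_summary")
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  if (is.numeric(g) && is.null(names(g)) && length(g) > 1)
    return(group_summary(g))
  if (is.list(g) || !is.null(names(g))) {
    g <- as.list(g)
    stopifnot(all(c("mean", "sd", "n") %in% names(g)))
    return(structure(list(label = g$label, n = g$n, mean = g$mean,
                          sd = g$sd), class = "group_summary"))
  }
  stop("cannot interpret group input")
}

comparison_result <- function(estimate, ci, statistic, df, p, method) {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 statistic = statistic, df = df, p = p, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.3g, CI = %.3g-%.3g, statistic = %.3g (df = %.3g), p = %.3g\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$statistic,
              x$df, x$p))
  invisible(x)
}

#' Welch's two-sample t-test (raw data or summaries)
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, computed
#' from raw values or from (mean, sd, n) summaries such as published
#' "mean +/- SD, n" triples.
#'
#' @param g1,g2 numeric vectors, `group_summary` objects, or lists with
#'   `mean`, `sd`, `n`.
#' @param level confidence level for the mean-difference interval.
#' @return a `comparison_result` (estimate = mean1 - mean2).
#' @export
welch_t <- function(g1, g2, level = 0.95) {
  s1 <- as_group_summary(g1); s2 <- as_group_summary(g2)
  stopifnot(s1$n >= 2, s2$n >= 2, is.finite(s1$sd), is.finite(s2$sd))
  v1 <- s1$sd^2 / s1$n; v2 <- s2$sd^2 / s2$n
  if (v1 + v2 == 0) {
    if (s1$mean == s2$mean)
      stop("zero variance in both groups with equal means: test undefined")
    return(comparison_result(s1$mean - s2$mean, rep(s1$mean - s2$mean, 2),
                             Inf, NA, 0, "Welch two-sample t"))
  }
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  est <- s1$mean - s2$mean
  tt <- est / se
  p <- 2 * pt(-abs(tt), df)
  crit <- qt(1 - (1 - level) / 2, df)
  comparison_result(est, est + c(-1, 1) * crit * se, tt, df, p,
                    "Welch two-sample t")
}

#' Pooled (Student) two-sample t-test (raw data or summaries)
#'
#' @inheritParams welch_t
#' @return a `comparison_result` (estimate = mean1 - mean2).
#' @export
student_t <- function(g1, g2, level = 0.95) {
  s1 <- as_group_summary(g1); s2 <- as_group_summary(g2)
  stopifnot(s1$n >= 2, s2$n >= 2)
  df <- s1$n + s2$n - 2
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
  if (sp2 == 0) {
    if (s1$mean == s2$mean)
      stop("zero variance in both groups with equal means: test undefined")
    return(comparison_result(s1$mean - s2$mean, rep(s1$mean - s2$mean, 2),
                             Inf, df, 0, "Student two-sample t"))
  }
  se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  est <- s1$mean - s2$mean
  tt <- est / se
  p <- 2 * pt(-abs(tt), df)
  crit <- qt(1 - (1 - level) / 2, df)
  comparison_result(est, est + c(-1, 1) * crit * se, tt, df, p,
                    "Student two-sample t")
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum test with exact p-value when the smaller group has at most
#' `exact_max` observations and there are no ties, and the tie-corrected
#' normal approximation otherwise; the estimate and confidence interval
#' are the Hodges-Lehmann location shift.
#'
#' @param x,y numeric samples.
#' @param level confidence level.
#' @param exact_max largest min-group size for which the exact null
#'   distribution is enumerated.
#' @return a `comparison_result` (statistic = rank-sum W).
#' @export
wilcoxon_rank_sum <- function(x, y, level = 0.95, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && all(c(x, y) == c(x, y)[1]))
    return(comparison_result(0, c(NA, NA), NA, NA, 1,
                             "Wilcoxon rank sum (degenerate)"))
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE, conf.int = TRUE,
                conf.level = level))
  comparison_result(unname(wt$estimate), as.numeric(wt$conf.int),
                    unname(wt$statistic), NA, wt$p.value,
                    if (use_exact) "Wilcoxon rank sum (exact)"
                    else "Wilcoxon rank sum (normal approx.)")
}

#' Fold change between two group means
#'
#' @param mean_num,mean_den numerator and denominator group means.
#' @param digits decimals in the reported ratio (default 2, the usual
#'   reporting convention); `NULL` for the unrounded ratio.
#' @return the (optionally rounded) ratio.
#' @export
fold_change <- function(mean_num, mean_den, digits = 2) {
  if (mean_den == 0) stop("zero denominator: fold change undefined")
  fc <- mean_num / mean_den
  if (is.null(digits)) fc else round(fc, digits)
}

#' Broad-sense heritability from F2 and F1 variances
#'
#' The F1 population is genetically uniform, so its phenotypic variance
#' estimates the environmental variance; the F2 variance adds the genetic
#' variance. The default estimator is H2 = (V_F2 - V_F1) / V_F2,
#' truncated to \[0, 1\]. `method = "ratio"` gives the literal variance
#' ratio V_F2 / V_F1 (which can exceed 1).
#'
#' @param var_f2,var_f1 phenotypic variances of the F2 and F1 populations.
#' @param method `"excess"` (default) or `"ratio"`.
#' @return heritability estimate.
#' @export
broad_sense_heritability <- function(var_f2, var_f1,
                                     method = c("excess", "ratio")) {
  method <- match.arg(method)
  stopifnot(var_f1 >= 0, var_f2 >= 0)
  if (var_f2 == 0) stop("zero F2 variance: heritability undefined")
  if (method == "ratio") return(var_f2 / var_f1)
  min(max((var_f2 - var_f1) / var_f2, 0), 1)
}
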