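#' Group comparison (paired t, unpaired t, or one-way ANOVA)
#'
#' Two-tailed classical (equal-variance) Student's t tests and one-way
#' ANOVA, as used for the group comparisons throughout the study: paired t
#' for measurements in the same fish, unpaired t for different fish, ANOVA
#' across more than two groups. Identical samples (zero-variance
#' difference / identical groups) return statistic 0 and p = 1 rather than
#' erroring, so degenerate-but-meaningful comparisons are representable.
#'
#' @param groups list of numeric vectors (two for the t designs).
#' @param design `"paired"`, `"unpaired"`, or `"anova"`.
#' @param alpha nominal significance level (default 0.05).
#' @param n_tests number of tests in the family for Bonferroni adjustment
#'   (default 1 = no correction).
#' @return object of class `comparison_result`: list with `test`,
#'   `statistic`, `df`, `p_value`, `alpha_adjusted`, `significant`.
#' @export
compare_groups <- function(groups, design = c("paired", "unpaired", "anova"),
                           alpha = 0.05, n_tests = 1) {
  design <- match.arg(design)
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of at least two numeric vectors")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  if (design %in% c("paired", "unpaired") && length(groups) != 2)
    stop("t-test designs take exactly two groups")
  a_adj <- bonferroni_alpha(alpha, n_tests)
  if (design == "paired") {
    if (length(groups[[1]]) != length(groups[[2]]))
      stop("paired design requires equal group lengths")
    d <- groups[[1]] - groups[[2]]
    df <- length(d) - 1
    if (stats::sd(d) == 0) {
      stat <- 0; p <- 1
      if (mean(d) != 0)
        stop("paired differences are constant and nonzero: t is undefined")
    } else {
      stat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      p <- 2 * stats::pt(-abs(stat), df)
    }
    test <- "paired_t"
  } else if (design == "unpaired") {
    x <- groups[[1]]; y <- groups[[2]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) != mean(y))
        stop("both groups have zero variance: t is undefined")
      stat <- 0; p <- 1; df <- length(x) + length(y) - 2
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- unname(tt$p.value)
      df <- unname(tt$parameter)
    }
    test <- "unpaired_t"
  } else {
    vals <- unlist(groups)
    g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    if (all(vapply(groups, stats::sd, 0) == 0))
      stop("all groups have zero variance: F is undefined")
    ow <- stats::oneway.test(vals ~ g, var.equal = TRUE)
    stat <- unname(ow$statistic); p <- unname(ow$p.value)
    df <- unname(ow$parameter)  # c(df_between, df_within)
    test <- "anova_oneway"
  }
  structure(list(test = test, statistic = stat, df = df, p_value = p,
                 alpha_adjusted = a_adj, significant = p < a_adj),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g df=%s p=%.4g (alpha_adj=%s) %s\n",
              x$test, x$statistic, paste(round(x$df, 2), collapse = ","),
              x$p_value, format_alpha(x$alpha_adjusted),
              if (x$significant) "significant" else "n.s."))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Exact adjusted level `alpha / n_tests`. Figures in the field display the
#' threshold truncated to 4 decimals (0.05/3 is printed 0.0166); use
#' [format_alpha()] for that display form. Comparisons use the exact value.
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return exact adjusted alpha (numeric).
#' @examples
#' format_alpha(bonferroni_alpha(0.05, 3))  # "0.0166"
#' bonferroni_alpha(0.05, 4)                # 0.0125
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("`n_tests` must be >= 1")
  alpha / n_tests
}

#' @rdname bonferroni_alpha
#' @param x an adjusted alpha to format.
#' @return `format_alpha`: the threshold truncated (not rounded) to 4
#'   decimals, as a string.
#' @export
format_alpha <- function(x) sprintf("%.4f", floor(x * 1e4) / 1e4)

#' Episode-duration summary per group
#'
#' Mean and SEM of swimming-episode durations, pooled across animals
#' (the published convention: e.g. 50 episodes = 10 per fish for five
#' fish), or optionally per-animal averages first.
#'
#' @param durations_by_animal list of numeric vectors, one per animal,
#'   episode durations in seconds.
#' @param method `"pooled"` (default) pools all episodes; `"per_animal"`
#'   averages within animal first.
#' @return list with `mean`, `sem`, `n` (number of values the SEM is over).
#' @export
episode_duration_summary <- function(durations_by_animal,
                                     method = c("pooled", "per_animal")) {
  method <- match.arg(method)
  if (!is.list(durations_by_animal)) durations_by_animal <- list(durations_by_animal)
  if (length(durations_by_animal) == 0 ||
      any(vapply(durations_by_animal, length, 0L) == 0))
    stop("every animal must contribute at least one episode")
  vals <- if (method == "pooled") unlist(durations_by_animal)
          else vapply(durations_by_animal, mean, 0)
  n <- length(vals)
  sem <- if (n > 1) stats::sd(vals) / sqrt(n) else 0
  list(mean = mean(vals), sem = sem, n = n)
}
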