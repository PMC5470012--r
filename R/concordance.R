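#' Paired observations
#'
#' The concordance analyses all operate on a table of paired observations:
#' one row per participant with the same quantity (minutes in an intensity
#' class, or average MET) measured by two methods or two replicate recalls.
#' Column `value_a` holds the instrument under evaluation and `value_b` the
#' criterion; differences are always `value_a - value_b`.
#'
#' @param pairs Tibble with columns `value_a` and `value_b` (and
#'   `participant_id`, covariates as needed).
#' @name pairs
NULL

check_pairs <- function(pairs, min_n = 1L) {
  if (!all(c("value_a", "value_b") %in% names(pairs))) {
    stop_par24("pairs need columns value_a and value_b", "par24_contract_error")
  }
  if (nrow(pairs) < min_n) {
    stop_par24(sprintf("need at least %d pairs, got %d", min_n, nrow(pairs)),
               "par24_contract_error")
  }
  if (any(!is.finite(pairs$value_a)) || any(!is.finite(pairs$value_b))) {
    stop_par24("pair values must be finite", "par24_validation_error")
  }
  invisible(pairs)
}

#' Spearman rank correlation
#'
#' The primary concordance measure: the Pearson correlation of midranks
#' (average ranks on ties). Undefined when either vector is constant.
#'
#' @inheritParams pairs
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' spearman(tibble::tibble(value_a = c(1, 2, 2, 4), value_b = c(10, 20, 30, 40)))
#' @export
spearman <- function(pairs) {
  check_pairs(pairs, min_n = 3L)
  if (stats::sd(pairs$value_a) == 0 || stats::sd(pairs$value_b) == 0) {
    stop_par24("Spearman correlation undefined: one method is constant",
               "par24_degenerate_error")
  }
  stats::cor(pairs$value_a, pairs$value_b, method = "spearman")
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test of a median shift. Zero differences are dropped
#' before ranking (the classic Wilcoxon convention; `zeros = "pratt"` ranks
#' them first and then discards their ranks). The exact null distribution is
#' used when, after zero handling, there are no ties and at most
#' `exact_max_n` differences; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max_n Largest tie-free n for which the exact distribution is
#'   enumerated; default 25.
#' @param zeros `"drop"` (default) or `"pratt"`.
#' @return List with `p_value`, `n_used` (differences ranked), `exact`
#'   (logical), `degenerate` (`TRUE` when every difference is zero, in which
#'   case `p_value` is 1).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value  # 2/32
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max_n = 25L,
                                 zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  if (length(diffs) < 1 || any(!is.finite(diffs))) {
    stop_par24("diffs must be a non-empty finite numeric vector",
               "par24_contract_error")
  }
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) {
    return(list(p_value = 1, n_used = 0L, exact = TRUE, degenerate = TRUE))
  }
  if (zeros == "drop") {
    ties <- anyDuplicated(abs(nz)) > 0
    exact <- !ties && length(nz) <= exact_max_n
    p <- suppressWarnings(
      stats::wilcox.test(nz, exact = exact, correct = TRUE)$p.value
    )
    return(list(p_value = min(p, 1), n_used = length(nz), exact = exact,
                degenerate = FALSE))
  }
  # Pratt: rank |diffs| including zeros, drop the zeros' ranks, then use the
  # normal approximation with the matching mean/variance terms.
  r <- rank(abs(diffs))
  keep <- diffs != 0
  v <- sum(r[keep][diffs[keep] > 0])
  n <- length(diffs)
  n0 <- sum(!keep)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  tie_tab <- table(r[keep])
  sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  list(p_value = min(2 * stats::pnorm(-abs(z)), 1), n_used = length(nz),
       exact = FALSE, degenerate = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample test of a location shift between independent groups.
#' Exact by enumeration of rank splits when the groups are tie-free and
#' jointly no larger than `exact_max_total`; otherwise the midrank normal
#' approximation with continuity and tie correction.
#'
#' @param group_x,group_y Numeric vectors, both non-empty.
#' @param exact_max_total Largest tie-free combined size for which the exact
#'   distribution is used; default 12.
#' @return List with `p_value` and `exact` (logical).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(group_x, group_y, exact_max_total = 12L) {
  if (length(group_x) == 0 || length(group_y) == 0) {
    stop_par24("both groups must be non-empty", "par24_contract_error")
  }
  if (any(!is.finite(c(group_x, group_y)))) {
    stop_par24("group values must be finite", "par24_validation_error")
  }
  if (identical(sort(group_x), sort(group_y))) {
    # Indistinguishable groups carry no evidence of a shift.
    return(list(p_value = 1, exact = TRUE))
  }
  ties <- anyDuplicated(c(group_x, group_y)) > 0
  exact <- !ties && (length(group_x) + length(group_y)) <= exact_max_total
  p <- suppressWarnings(
    stats::wilcox.test(group_x, group_y, exact = exact, correct = TRUE)$p.value
  )
  list(p_value = min(p, 1), exact = exact)
}

#' Median of paired differences
#'
#' The per-participant difference `value_a - value_b` summarised by its
#' median, with a median percent difference. Note the median of differences
#' need not equal the difference of medians. Percent differences use each
#' pair's own criterion value as denominator by default (pairs with
#' `value_b = 0` are excluded from the percent median); the alternative
#' pools the criterion median as a common denominator.
#'
#' @inheritParams pairs
#' @param denominator `"per_pair"` (default) or `"pooled_median"`.
#' @return One-row tibble with `median_diff` and `median_pct_diff`.
#' @examples
#' median_of_differences(tibble::tibble(value_a = c(1, 2, 3), value_b = c(3, 1, 2)))
#' @export
median_of_differences <- function(pairs, denominator = c("per_pair", "pooled_median")) {
  denominator <- match.arg(denominator)
  check_pairs(pairs, min_n = 1L)
  d <- pairs$value_a - pairs$value_b
  md <- stats::median(d)
  if (denominator == "per_pair") {
    ok <- pairs$value_b > 0
    pct <- if (any(ok)) stats::median(100 * d[ok] / pairs$value_b[ok]) else NA_real_
  } else {
    mb <- stats::median(pairs$value_b)
    pct <- if (mb > 0) 100 * md / mb else NA_real_
  }
  tibble(median_diff = md, median_pct_diff = pct)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of the paired differences) and 95% limits of agreement
#' `bias +/- 1.96 * SD` with the sample (n-1) standard deviation, together
#' with the per-pair (mean, difference) points used for plotting.
#'
#' @inheritParams pairs
#' @return An object of class `par24_blandaltman`: list with `n`, `bias`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, and `points` (tibble with columns
#'   `mean` and `diff`).
#' @examples
#' ba <- bland_altman(tibble::tibble(value_a = c(3, 5, 9), value_b = c(5, 5, 7)))
#' ba$bias
#' @export
bland_altman <- function(pairs) {
  check_pairs(pairs, min_n = 2L)
  d <- pairs$value_a - pairs$value_b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(
      n = nrow(pairs),
      bias = bias,
      sd_diff = sd_d,
      loa_lower = bias - 1.96 * sd_d,
      loa_upper = bias + 1.96 * sd_d,
      points = tibble(mean = (pairs$value_a + pairs$value_b) / 2, diff = d)
    ),
    class = "par24_blandaltman"
  )
}

#' @export
print.par24_blandaltman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %.2f, 95%% LoA [%.2f, %.2f]\n",
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Intraclass correlation (two-way random, single measure)
#'
#' Optional extra reliability statistic: ICC(2,1) from the two-way ANOVA
#' mean squares of the paired table (participants crossed with the two
#' measurements). The package's tabulated reliability statistic is the
#' Spearman correlation; this is provided for comparison only.
#'
#' @inheritParams pairs
#' @return A single ICC value.
#' @export
icc_two_way <- function(pairs) {
  check_pairs(pairs, min_n = 3L)
  m <- cbind(pairs$value_a, pairs$value_b)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - outer(rowMeans(m), rep(1, k)) -
                 outer(rep(1, n), colMeans(m)) + grand)^2)) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
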