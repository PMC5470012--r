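#' Full method-agreement analysis of one paired quantity
#'
#' Bundles the concordance statistics for one quantity measured by two
#' methods (or two replicate recalls): Spearman correlation, Wilcoxon
#' signed-rank p for a method difference, median of differences with median
#' percent difference, and Bland-Altman bias with 95% limits of agreement.
#'
#' @inheritParams pairs
#' @param quantity Label for the quantity compared (e.g. `"light_min"`).
#' @param denominator Passed to [median_of_differences()].
#' @param exact_max_n Passed to [wilcoxon_signed_rank()].
#' @return An object of class `par24_agreement`; use [generics::tidy()] for
#'   a one-row tibble of its statistics.
#' @examples
#' pairs <- tibble::tibble(value_a = c(10, 12, 9, 15), value_b = c(11, 10, 9, 14))
#' tidy(method_agreement(pairs, "demo"))
#' @export
method_agreement <- function(pairs, quantity = "value",
                             denominator = c("per_pair", "pooled_median"),
                             exact_max_n = 25L) {
  denominator <- match.arg(denominator)
  check_pairs(pairs, min_n = 3L)
  d <- pairs$value_a - pairs$value_b
  wsr <- wilcoxon_signed_rank(d, exact_max_n = exact_max_n)
  med <- median_of_differences(pairs, denominator = denominator)
  ba <- bland_altman(pairs)
  structure(
    list(
      quantity = quantity,
      n = nrow(pairs),
      spearman_r = spearman(pairs),
      p_method_diff = wsr$p_value,
      p_exact = wsr$exact,
      degenerate_diff = wsr$degenerate,
      median_a = stats::median(pairs$value_a),
      median_b = stats::median(pairs$value_b),
      median_diff = med$median_diff,
      median_pct_diff = med$median_pct_diff,
      bias = ba$bias,
      loa_lower = ba$loa_lower,
      loa_upper = ba$loa_upper,
      bland_altman = ba,
      pairs = pairs
    ),
    class = "par24_agreement"
  )
}

#' @export
print.par24_agreement <- function(x, ...) {
  cat(sprintf("Method agreement for %s (n = %d)\n", x$quantity, x$n))
  cat(sprintf("  Spearman r = %.3f; signed-rank p = %.3g%s\n",
              x$spearman_r, x$p_method_diff,
              if (x$degenerate_diff) " (all differences zero)" else ""))
  cat(sprintf("  median diff = %.1f (%.0f%%); bias = %.1f, LoA [%.1f, %.1f]\n",
              x$median_diff,
              ifelse(is.na(x$median_pct_diff), NaN, x$median_pct_diff),
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname method_agreement
#' @param x A `par24_agreement` object.
#' @param ... Unused.
#' @method tidy par24_agreement
#' @export
tidy.par24_agreement <- function(x, ...) {
  tibble(
    quantity = x$quantity,
    n = x$n,
    median_a = x$median_a,
    median_b = x$median_b,
    median_diff = x$median_diff,
    median_pct_diff = x$median_pct_diff,
    p_method_diff = x$p_method_diff,
    spearman_r = x$spearman_r,
    bias = x$bias,
    loa_lower = x$loa_lower,
    loa_upper = x$loa_upper
  )
}

#' @rdname method_agreement
#' @method glance par24_agreement
#' @export
glance.par24_agreement <- function(x, ...) {
  tibble(
    quantity = x$quantity,
    n = x$n,
    spearman_r = x$spearman_r,
    p_method_diff = x$p_method_diff,
    p_exact = x$p_exact
  )
}

#' @rdname bland_altman
#' @param x A `par24_blandaltman` object.
#' @param ... Unused.
#' @method tidy par24_blandaltman
#' @export
tidy.par24_blandaltman <- function(x, ...) {
  x$points
}

#' @rdname bland_altman
#' @method glance par24_blandaltman
#' @export
glance.par24_blandaltman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper)
}

#' Agreement stratified by a participant covariate
#'
#' Splits the pairs into two strata — age below/at-or-above 60 years, gender,
#' or BMI below/at-or-above 25 kg/m2 — computes the full agreement analysis
#' within each, and tests whether the per-participant differences
#' `value_a - value_b` differ between strata with the Wilcoxon rank-sum
#' test.
#'
#' @inheritParams method_agreement
#' @param stratifier One of `"age"`, `"gender"`, `"bmi"`. The pairs table
#'   must carry the matching covariate column (`age`, `gender`, `bmi`).
#' @param age_cut,bmi_cut Stratum boundaries; the upper stratum is inclusive
#'   (`>=`). Defaults 60 years and 25 kg/m2.
#' @return An object of class `par24_stratified`: list with `stratifier`,
#'   named `strata` (two `par24_agreement` objects), and `between_p`.
#' @export
stratified_comparison <- function(pairs, stratifier = c("age", "gender", "bmi"),
                                  quantity = "value", age_cut = 60,
                                  bmi_cut = 25,
                                  denominator = c("per_pair", "pooled_median")) {
  stratifier <- match.arg(stratifier)
  denominator <- match.arg(denominator)
  if (!stratifier %in% names(pairs)) {
    stop_par24(paste0("pairs lack the covariate column: ", stratifier),
               "par24_contract_error")
  }
  cov <- pairs[[stratifier]]
  if (anyNA(cov)) {
    stop_par24(paste0("missing ", stratifier, " covariate in pairs"),
               "par24_stratification_error")
  }
  labels <- switch(
    stratifier,
    age = list(lo = sprintf("age<%g", age_cut), hi = sprintf("age>=%g", age_cut),
               split = cov >= age_cut),
    bmi = list(lo = sprintf("bmi<%g", bmi_cut), hi = sprintf("bmi>=%g", bmi_cut),
               split = cov >= bmi_cut),
    gender = {
      lv <- sort(unique(as.character(cov)))
      if (length(lv) != 2) {
        stop_par24("gender stratification needs exactly two observed levels",
                   "par24_stratification_error")
      }
      list(lo = lv[1], hi = lv[2], split = as.character(cov) == lv[2])
    }
  )
  lo <- pairs[!labels$split, , drop = FALSE]
  hi <- pairs[labels$split, , drop = FALSE]
  if (nrow(lo) == 0 || nrow(hi) == 0) {
    empty <- if (nrow(lo) == 0) labels$lo else labels$hi
    stop_par24(paste0("empty stratum: ", empty), "par24_stratification_error")
  }
  strata <- list(
    method_agreement(lo, quantity = quantity, denominator = denominator),
    method_agreement(hi, quantity = quantity, denominator = denominator)
  )
  names(strata) <- c(labels$lo, labels$hi)
  rs <- wilcoxon_rank_sum(lo$value_a - lo$value_b, hi$value_a - hi$value_b)
  structure(
    list(stratifier = stratifier, quantity = quantity, strata = strata,
         between_p = rs$p_value),
    class = "par24_stratified"
  )
}

#' @rdname stratified_comparison
#' @param x A `par24_stratified` object.
#' @param ... Unused.
#' @method tidy par24_stratified
#' @export
tidy.par24_stratified <- function(x, ...) {
  rows <- purrr::imap(x$strata, function(ag, label) {
    dplyr::mutate(tidy(ag), stratum = label, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$stratifier <- x$stratifier
  out$between_strata_p <- x$between_p
  out
}

#' @export
print.par24_stratified <- function(x, ...) {
  cat(sprintf("Stratified agreement for %s by %s (between-strata p = %.3g)\n",
              x$quantity, x$stratifier, x$between_p))
  print(tidy(x))
  invisible(x)
}
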