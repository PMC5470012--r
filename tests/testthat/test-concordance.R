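pairs_of <- function(a, b) tibble::tibble(value_a = a, value_b = b)

test_that("spearman matches the rank-then-Pearson definition", {
  expect_equal(spearman(pairs_of(c(1, 2, 3, 5), c(1, 2, 3, 5))), 1)
  expect_equal(spearman(pairs_of(c(1, 2, 3, 5), c(5, 3, 2, 1))), -1)
  a <- c(1, 2, 2, 4); b <- c(10, 20, 30, 40)
  expect_equal(spearman(pairs_of(a, b)), oracle_spearman(a, b))
  set.seed(301)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    a <- round(stats::runif(n, 0, 20))  # coarse values force ties
    b <- round(stats::runif(n, 0, 20))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    expect_equal(spearman(pairs_of(a, b)), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("spearman on a constant vector is a degenerate-correlation error", {
  expect_error(spearman(pairs_of(c(1, 1, 1), c(1, 2, 3))),
               class = "par24_degenerate_error")
  expect_error(spearman(pairs_of(c(1, 2), c(1, 2))),
               class = "par24_contract_error")
})

test_that("signed-rank test handles zeros, exact and approximate regimes", {
  # all differences zero: no evidence of a shift
  res0 <- wilcoxon_signed_rank(rep(0, 5))
  expect_equal(res0$p_value, 1)
  expect_true(res0$degenerate)
  # all-positive tie-free differences: exact p = 2/32
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 32)
  expect_equal(res$p_value, oracle_signed_rank(c(1, 2, 3, 4, 5)))
  # symmetric two-point case
  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p_value, 1)
  # zeros dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5))$p_value, 2 / 32)
})

test_that("signed-rank exact p equals the sign-enumeration oracle", {
  set.seed(302)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    d <- round(stats::rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d)) > 0) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank(d),
                 info = paste(d, collapse = ","))
  }
})

test_that("signed-rank normal approximation is close to exact at n = 20", {
  set.seed(303)
  for (i in 1:10) {
    d <- round(stats::rnorm(20, 0.2, 1), 4)
    if (anyDuplicated(abs(d)) > 0 || any(d == 0)) next
    exact <- wilcoxon_signed_rank(d, exact_max_n = 25L)
    approx <- wilcoxon_signed_rank(d, exact_max_n = 5L)
    expect_true(exact$exact)
    expect_false(approx$exact)
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  }
})

test_that("the Pratt zero-handling option is available and sane", {
  d <- c(0, 0, 1, 2, -3, 4, 5)
  res <- wilcoxon_signed_rank(d, zeros = "pratt")
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # with no zeros, pratt and drop agree in the approximate regime
  d2 <- c(1.2, -0.7, 2.1, 3.3, -1.8, 0.4, 2.8, -0.2)
  expect_equal(wilcoxon_signed_rank(d2, zeros = "pratt")$p_value,
               wilcoxon_signed_rank(d2, exact_max_n = 0L)$p_value,
               tolerance = 1e-10)
})

test_that("rank-sum test: exact enumeration, identical groups, errors", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(3, 1, 2), c(2, 3, 1))$p_value, 1)
  interleaved <- wilcoxon_rank_sum(c(1, 3, 5), c(2, 4, 6))
  expect_equal(interleaved$p_value, oracle_rank_sum(c(1, 3, 5), c(2, 4, 6)))
  expect_error(wilcoxon_rank_sum(numeric(0), c(1, 2)),
               class = "par24_contract_error")
})

test_that("rank-sum exact p equals the split-enumeration oracle", {
  set.seed(304)
  for (i in 1:40) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(stats::rnorm(nx, 0, 2), 3)
    y <- round(stats::rnorm(ny, 1, 2), 3)
    if (anyDuplicated(c(x, y)) > 0) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_rank_sum(x, y),
                 info = paste(c(x, "|", y), collapse = ","))
  }
})

test_that("median of differences is not the difference of medians", {
  md <- median_of_differences(pairs_of(c(1, 2, 3), c(3, 1, 2)))
  expect_equal(md$median_diff, 1)
  diff_of_medians <- stats::median(c(1, 2, 3)) - stats::median(c(3, 1, 2))
  expect_equal(diff_of_medians, 0)
  expect_false(md$median_diff == diff_of_medians)
})

test_that("median_of_differences handles agreement, zeros, and denominators", {
  same <- pairs_of(c(5, 8, 2), c(5, 8, 2))
  expect_equal(median_of_differences(same),
               tibble::tibble(median_diff = 0, median_pct_diff = 0))
  md <- median_of_differences(pairs_of(c(10, 5, 8), c(7, 5, 9)))
  expect_equal(md$median_diff, 0)
  # pairs with value_b = 0 are excluded from the percent median
  withzero <- pairs_of(c(10, 5), c(0, 4))
  expect_equal(median_of_differences(withzero)$median_pct_diff, 25)
  pooled <- median_of_differences(pairs_of(c(10, 5, 8), c(7, 5, 9)),
                                  denominator = "pooled_median")
  expect_equal(pooled$median_pct_diff, 0)
})

test_that("Bland-Altman closed forms: identity, offset, spread", {
  same <- bland_altman(pairs_of(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(c(same$bias, same$loa_lower, same$loa_upper), c(0, 0, 0))
  off <- bland_altman(pairs_of(c(11, 12, 13), c(1, 2, 3)))
  expect_equal(c(off$bias, off$loa_lower, off$loa_upper), c(10, 10, 10))
  spread <- bland_altman(pairs_of(c(3, 5, 9), c(5, 5, 7)))  # diffs -2, 0, 2
  expect_equal(spread$bias, 0)
  expect_equal(spread$loa_upper, 1.96 * 2)
  expect_equal(spread$loa_lower, -1.96 * 2)
  expect_equal(spread$points$mean, c(4, 5, 8))
  expect_equal(spread$points$diff, c(-2, 0, 2))
  expect_error(bland_altman(pairs_of(1, 2)), class = "par24_contract_error")
})

test_that("swapping methods negates the Bland-Altman geometry", {
  set.seed(305)
  pairs <- pairs_of(stats::rnorm(15, 100, 10), stats::rnorm(15, 90, 10))
  ab <- bland_altman(pairs)
  ba <- bland_altman(pairs_of(pairs$value_b, pairs$value_a))
  expect_equal(ba$bias, -ab$bias)
  expect_equal(ba$loa_lower, -ab$loa_upper)
  expect_equal(ba$loa_upper, -ab$loa_lower)
  expect_equal(ba$points$diff, -ab$points$diff)
  expect_equal(ba$points$mean, ab$points$mean)
  # LoA symmetric about the bias
  expect_equal(ab$loa_upper - ab$bias, ab$bias - ab$loa_lower)
})

test_that("method_agreement bundles its components consistently", {
  # perfect agreement
  perfect <- pairs_of(c(3, 1, 4, 2), c(3, 1, 4, 2))
  ag <- method_agreement(perfect, "demo")
  expect_equal(ag$spearman_r, 1)
  expect_equal(ag$p_method_diff, 1)
  expect_true(ag$degenerate_diff)
  expect_equal(ag$median_diff, 0)
  expect_equal(ag$bias, 0)

  # component-wise recomputation on a random cohort
  set.seed(306)
  pairs <- pairs_of(round(stats::rnorm(15, 300, 60)),
                    round(stats::rnorm(15, 250, 50)))
  ag <- method_agreement(pairs, "minutes")
  expect_equal(ag$spearman_r, spearman(pairs))
  expect_equal(ag$p_method_diff,
               wilcoxon_signed_rank(pairs$value_a - pairs$value_b)$p_value)
  expect_equal(ag$median_diff, median_of_differences(pairs)$median_diff)
  ba <- bland_altman(pairs)
  expect_equal(ag$bias, ba$bias)
  expect_equal(ag$loa_lower, ba$loa_lower)
  td <- tidy(ag)
  expect_equal(td$median_diff, ag$median_diff)
  expect_equal(td$spearman_r, ag$spearman_r)

  # degenerate propagation
  const <- pairs_of(rep(5, 4), c(1, 2, 3, 4))
  expect_error(method_agreement(const), class = "par24_degenerate_error")
})

test_that("spearman in method_agreement is invariant to monotone transforms", {
  set.seed(307)
  pairs <- pairs_of(stats::runif(20, 1, 100), stats::runif(20, 1, 100))
  r0 <- method_agreement(pairs)$spearman_r
  r_cube <- method_agreement(pairs_of(pairs$value_a^3, pairs$value_b^3))$spearman_r
  r_log <- method_agreement(pairs_of(log(pairs$value_a), log(pairs$value_b)))$spearman_r
  expect_equal(r_cube, r0)
  expect_equal(r_log, r0)
})

test_that("stratified comparison tests the differences between strata", {
  base <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:6),
    value_a = c(11, 22, 33, 110, 112, 114),
    value_b = c(10, 20, 30, 100, 101, 102),
    age = c(45, 50, 55, 62, 65, 70)
  )
  st <- stratified_comparison(base, "age")
  # strata differences (1,2,3) vs (10,11,12): enumeration p = 0.1
  expect_equal(st$between_p, 0.1)
  td <- tidy(st)
  expect_equal(td$stratum, c("age<60", "age>=60"))
  expect_equal(td$n, c(3L, 3L))

  # identical difference distributions across strata -> p = 1
  same <- base
  same$value_a <- same$value_b + rep(c(1, 2, 3), 2)
  expect_equal(stratified_comparison(same, "age")$between_p, 1)
})

test_that("stratum membership uses inclusive upper cuts at 60 and 25", {
  pairs <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:6),
    value_a = c(1, 2, 3, 4, 5, 6), value_b = c(2, 1, 4, 3, 6, 5),
    age = c(59, 58, 57, 60, 61, 62),
    bmi = c(24.9, 24, 23, 25, 26, 27)
  )
  st_age <- stratified_comparison(pairs, "age")
  expect_equal(unname(vapply(st_age$strata, function(s) s$n, integer(1))),
               c(3L, 3L))
  expect_equal(names(st_age$strata), c("age<60", "age>=60"))
  st_bmi <- stratified_comparison(pairs, "bmi")
  expect_equal(names(st_bmi$strata), c("bmi<25", "bmi>=25"))
  expect_error(
    stratified_comparison(dplyr::mutate(pairs, age = age + 100), "age"),
    class = "par24_stratification_error"
  )
})

test_that("the optional ICC is 1 for perfect agreement and near r for noise", {
  perfect <- pairs_of(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_two_way(perfect), 1)
  set.seed(308)
  a <- stats::rnorm(40, 100, 20)
  noisy <- pairs_of(a, a + stats::rnorm(40, 0, 5))
  icc <- icc_two_way(noisy)
  expect_gt(icc, 0.8)
  expect_lte(icc, 1)
})
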