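test_that("rank-sum test matches hand-enumerated exact cases", {
  # a entirely below b: U_a = 0; one-sided exact p = 1/choose(6,3) = 0.05
  gc <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(gc$u_statistic, 0)
  expect_equal(gc$p_value, 0.05)
  expect_equal(gc$method, "exact")

  # identical multisets: U at its null mean, two-sided p = 1
  gc2 <- rank_sum_test(c(1, 2), c(1, 2))
  expect_equal(gc2$u_statistic, 2)   # midranks 1.5,1.5,3.5,3.5
  expect_equal(gc2$p_value, 1)

  gc3 <- rank_sum_test(c(100, 100, 100), c(90, 90, 90))
  expect_equal(gc3$percent_reduction, 10)
})

test_that("U lies in [0, n_a*n_b] and means/percent reduction are filled", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(sample(2:15, 1)); b <- rnorm(sample(2:15, 1))
    gc <- rank_sum_test(a, b)
    expect_gte(gc$u_statistic, 0)
    expect_lte(gc$u_statistic, gc$n_a * gc$n_b)
    expect_equal(gc$mean_a, mean(a))
    expect_equal(gc$percent_reduction, 100 * (mean(a) - mean(b)) / mean(a))
    expect_true(gc$p_value >= 0 && gc$p_value <= 1)
  }
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("exact p-values agree with brute-force enumeration on tie-free samples", {
  set.seed(13)
  for (i in 1:60) {
    n_a <- sample(2:8, 1)
    n_b <- sample(2:(10 - n_a), 1)
    vals <- sample(1:1000, n_a + n_b)       # tie-free
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    oracle <- brute_force_rank_sum(a, b)
    expect_equal(rank_sum_test(a, b)$u_statistic, oracle$u)
    expect_equal(rank_sum_test(a, b, "less")$p_value, oracle$p_less)
    expect_equal(rank_sum_test(a, b, "greater")$p_value, oracle$p_greater)
    expect_equal(rank_sum_test(a, b, "two.sided")$p_value, oracle$p_two_sided)
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(14)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  gc <- rank_sum_test(a, b)
  expect_equal(gc$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(gc$p_value, ref$p.value)

  tied <- rank_sum_test(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(tied$method, "normal approximation")
  ref2 <- suppressWarnings(stats::wilcox.test(c(1, 2, 2, 3), c(2, 3, 3, 4),
                                              exact = FALSE, correct = TRUE))
  expect_equal(tied$p_value, ref2$p.value)
})

test_that("ratio correlation matches the closed-form Pearson oracle", {
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  rc <- ratio_correlation(a, b)
  oracle <- pearson_closed_form(a, b)
  expect_equal(rc$r, oracle$r, tolerance = 1e-12)
  expect_equal(rc$r, 0.9819805, tolerance = 1e-6)
  expect_equal(rc$p_value, oracle$p_value, tolerance = 1e-12)

  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x)) + 0.3 * x
    rc <- ratio_correlation(x, y)
    oracle <- pearson_closed_form(x, y)
    expect_equal(rc$r, oracle$r, tolerance = 1e-12)
    expect_equal(rc$p_value, oracle$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate correlations are exact or reported undefined", {
  a <- 1:10
  expect_equal(ratio_correlation(a, 2 * a + 1)$r, 1)
  expect_equal(ratio_correlation(a, -a)$r, -1)
  expect_true(is.na(ratio_correlation(c(1, 2), c(3, 4))$r))          # n < 3
  expect_true(is.na(ratio_correlation(c(1, 1, 1), c(1, 2, 3))$r))    # zero variance
  # undefined (NA) pairs are dropped before computing
  rc <- ratio_correlation(c(a, NA), c(2 * a, 5))
  expect_equal(rc$n, 10L)
  expect_equal(rc$r, 1)
})

test_that("Dunn's z-tests follow Kruskal-Wallis with the expected statistics", {
  # 3 groups of 3, values 1..9, no ties: mean ranks 2, 5, 8,
  # se = sqrt(9*10/12 * (1/3+1/3)) = sqrt(5)
  vals <- 1:9
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  d <- dunn_test(vals, grp)
  expect_equal(d$pairwise$z[d$pairwise$group_1 == "g1" & d$pairwise$group_2 == "g2"],
               -3 / sqrt(5), tolerance = 1e-12)
  expect_equal(d$pairwise$z[d$pairwise$group_1 == "g1" & d$pairwise$group_2 == "g3"],
               -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(d$kruskal$p.value, stats::kruskal.test(vals, factor(grp))$p.value)
  expect_equal(d$pairwise$p_adjusted, pmin(1, d$pairwise$p_value * 3))
  expect_error(dunn_test(1:3, rep("a", 3)), "two groups")
})
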