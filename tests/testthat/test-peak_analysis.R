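test_that("peak scores normalize read counts to 10 million aligned reads", {
  expect_equal(compute_peak_score(0, 191404803), 0)
  expect_equal(compute_peak_score(5, 1e7), 5)
  expect_equal(compute_peak_score(20, 2e8), 1)
  expect_error(compute_peak_score(5, 0), "positive")
  expect_error(compute_peak_score(-1, 1e7), "nonnegative")
})

test_that("peak scores are invariant to joint depth scaling", {
  set.seed(3)
  reads <- sample.int(1000, 50)
  total <- 5e7
  for (s in c(2, 10, 0.5)) {
    expect_equal(compute_peak_score(reads * s, total * s),
                 compute_peak_score(reads, total))
  }
})

test_that("binding surface score is log2(peak score x length)", {
  expect_equal(binding_surface_score(1, 1), 0)
  expect_equal(binding_surface_score(0.1, 10), 0)
  expect_equal(binding_surface_score(2, 1024), 11)
  expect_error(binding_surface_score(0, 10), "positive")
  expect_error(binding_surface_score(1, 0), ">= 1")
})

test_that("doubling length raises every binding surface score by exactly 1", {
  set.seed(4)
  score <- runif(100, 0.1, 50)
  len <- sample.int(1e5, 100)
  expect_equal(binding_surface_score(score, 2 * len),
               binding_surface_score(score, len) + 1)
})

test_that("the score filter discards strictly below threshold and keeps the boundary", {
  df <- data.frame(gene_id = letters[1:3], peak_score = c(0.05, 0.1, 0.2))
  expect_message(kept <- filter_peaks(df), "discarded 1")
  expect_equal(kept$peak_score, c(0.1, 0.2))

  expect_equal(nrow(filter_peaks(df[0, ])), 0L)
  above <- data.frame(gene_id = "a", peak_score = 3)
  expect_identical(filter_peaks(above), above)
  expect_error(filter_peaks(df, min_score = -1), "nonnegative")
})

test_that("the score filter is idempotent and order-preserving", {
  set.seed(5)
  df <- data.frame(gene_id = sprintf("g%d", 1:50),
                   peak_score = round(runif(50, 0, 0.3), 3))
  once <- suppressMessages(filter_peaks(df))
  twice <- suppressMessages(filter_peaks(once))
  expect_identical(twice, once)
  expect_identical(once$gene_id, df$gene_id[df$peak_score >= 0.1])
})

test_that("target subsetting intersects on exact gene ids and flags matches", {
  df <- data.frame(gene_id = c("FUS", "fus", "TARDBP", "SOD1", "HNRNPA1"),
                   peak_score = 1:5, is_target = FALSE)
  out <- subset_by_targets(df, c("FUS", "SOD1"))
  expect_equal(out$gene_id, c("FUS", "SOD1"))    # case-sensitive: "fus" excluded
  expect_true(all(out$is_target))

  expect_message(none <- subset_by_targets(df, "NOPE"), "no transcripts")
  expect_equal(nrow(none), 0L)

  all_in <- subset_by_targets(df, df$gene_id)
  expect_equal(all_in$gene_id, df$gene_id)
})

test_that("score_transcripts composes removal, scoring, filtering and flags", {
  ps <- peak_set(data.frame(
    peak_id = sprintf("p%d", 1:4),
    gene_id = c("A", "B", "C", "D"), chrom = "chr1",
    start = c(0L, 0L, 0L, 0L), end = c(100L, 501L, 1024L, 10L),
    strand = "+", raw_reads = c(0, 12, 2, 1)),
    total_aligned_reads = 1e7)
  expect_message(sc <- score_transcripts(ps, targets = "B"), "removed 1 zero-read")
  expect_equal(sc$gene_id, c("B", "C", "D"))
  expect_equal(sc$length, c(501L, 1024L, 10L))
  expect_equal(sc$peak_score, c(12, 2, 1))
  expect_equal(sc$binding_surface_score, log2(c(12 * 501, 2048, 10)))
  expect_equal(sc$is_target, c(TRUE, FALSE, FALSE))
})

test_that("stored binding surface scores are reproducible from stored fields", {
  set.seed(6)
  sim <- simulate_peak_pair(peak_sim_config(n_transcripts = 300, seed = 9))
  sc <- suppressMessages(score_transcripts(sim$control))
  expect_true(all(abs(sc$binding_surface_score -
                        log2(sc$peak_score * sc$length)) < 1e-9))
})

test_that("per-gene aggregation sums scores and takes the max length", {
  ps <- peak_set(data.frame(
    peak_id = c("p1", "p2", "p3"), gene_id = c("A", "A", "B"), chrom = "chr1",
    start = c(0L, 200L, 0L), end = c(100L, 700L, 50L), strand = "+",
    raw_reads = c(10, 20, 5)), 1e7)
  sc <- score_transcripts(ps, aggregate_by_gene = TRUE)
  expect_equal(sc$gene_id, c("A", "B"))
  expect_equal(sc$peak_score, c(30, 5))
  expect_equal(sc$length, c(500L, 50L))
})

test_that("the empirical CDF steps at k/n through sorted values", {
  expect_equal(cumulative_distribution(7), data.frame(value = 7, fraction = 1))
  e <- cumulative_distribution(c(3, 1, 4, 2))
  expect_equal(e$value, 1:4)
  expect_equal(e$fraction, c(0.25, 0.5, 0.75, 1))
  expect_error(cumulative_distribution(numeric(0)), "at least one")
})

test_that("ECDF reflects multiplicity of duplicated values and ends at 1", {
  x <- c(5, 2, 2, 9, 2, 5)           # 6-element multiset
  e <- cumulative_distribution(x)
  # brute-force ECDF oracle: fraction of values <= v
  brute <- vapply(e$value, function(v) mean(x <= v), numeric(1))
  expect_equal(max(e$fraction[e$value == 2]), brute[e$value == 2][1])
  expect_equal(max(e$fraction[e$value == 2]), 0.5)  # step height 3/6 reached
  expect_true(all(diff(e$fraction) >= 0))
  expect_gt(e$fraction[1], 0)
  expect_identical(e$fraction[length(x)], 1)

  set.seed(8)
  for (i in 1:5) {
    v <- sample(1:5, 20, replace = TRUE)
    e <- cumulative_distribution(v)
    expect_equal(max(e$fraction), 1)
    expect_equal(vapply(unique(e$value), function(u) max(e$fraction[e$value == u]),
                        numeric(1)),
                 vapply(unique(e$value), function(u) mean(v <= u), numeric(1)))
  }
})

test_that("sample summaries aggregate counts, totals and means", {
  sc <- data.frame(gene_id = c("A", "B"), peak_score = c(1, 2),
                   length = c(1L, 1024L),
                   binding_surface_score = c(0, 11), is_target = FALSE)
  s <- summarize_sample(sc)
  expect_equal(s$n_peaks, 2L)
  expect_equal(s$total_binding_surface, 11)
  expect_equal(s$mean_peak_score, 1.5)
  expect_equal(s$mean_binding_surface, 5.5)

  s0 <- summarize_sample(sc[0, ])
  expect_equal(s0$n_peaks, 0L)
  expect_true(is.na(s0$mean_peak_score))

  s1 <- summarize_sample(sc[2, ])
  expect_equal(s1$mean_binding_surface, 11)
})
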