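test_that("complexity endpoints and hand-computed entropy values are exact", {
  # all reads at one start: degenerate single peak
  expect_identical(cluster_complexity(rep(100L, 50)), 0)
  # one length-1 read at every base of the span: uniform tiling
  expect_equal(cluster_complexity(1:64, span = 64L), 1)
  # two equal-mass starts in a 4 bp span: ln2 / ln4 = 0.5
  expect_equal(cluster_complexity(c(1L, 3L), span = 4L), 0.5)
  # span of 1 is defined as 0
  expect_identical(cluster_complexity(5L, span = 1L), 0)
})

test_that("complexity stays in [0,1], is 0 iff one start, and grows under mass spreading", {
  set.seed(5)
  for (i in 1:50) {
    starts <- sample(1:200, sample(2:100, 1), replace = TRUE)
    w <- stats::runif(length(starts), 0.1, 2)
    cx <- cluster_complexity(starts, w, span = 250L)
    expect_gte(cx, 0)
    expect_lte(cx, 1)
    if (length(unique(starts)) == 1L) expect_identical(cx, 0)
    else expect_gt(cx, 0)
  }
  # moving mass from the modal start to an empty base increases complexity
  starts <- c(rep(10L, 80), rep(40L, 20))
  w <- rep(1, 100)
  base_cx <- cluster_complexity(starts, w, span = 100L)
  spread <- c(rep(10L, 70), rep(40L, 20), rep(70L, 10))
  expect_gt(cluster_complexity(spread, w, span = 100L), base_cx)
  # uniform weight rescaling leaves complexity unchanged
  expect_equal(cluster_complexity(starts, w * 3.7, span = 100L), base_cx)
})

test_that("peak statistics count reads covering the maximal-depth base", {
  # identical reads: everything covers the peak
  p <- peak_stats(rep(100L, 100), rep(121L, 100))
  expect_equal(p$peak_fraction, 1)
  expect_equal(p$peak_coverage, 100)
  expect_equal(p$peak_pos, 100L)

  # 60 reads stacked + 40 elsewhere not covering that base -> 0.6
  st <- c(rep(100L, 60), rep(300L, 40))
  en <- st + 21L
  p <- peak_stats(st, en)
  expect_equal(p$peak_fraction, 0.6)
  expect_equal(p$peak_pos, 100L)

  # equal-depth candidate peaks: leftmost chosen
  p <- peak_stats(c(10L, 50L), c(20L, 60L))
  expect_equal(p$peak_pos, 10L)

  # weighted depth decides the peak
  p <- peak_stats(c(10L, 50L), c(20L, 60L), weights = c(1, 2))
  expect_equal(p$peak_pos, 50L)
  expect_equal(p$peak_fraction, 2 / 3)
})

test_that("consensus is the weighted per-column majority over peak reads", {
  # a single read reproduces its own sequence
  expect_identical(peak_consensus(10L, 13L, "ACGT"), "ACGT")
  # identical reads reproduce the shared sequence
  expect_identical(peak_consensus(rep(10L, 3), rep(13L, 3),
                                  rep("ACGT", 3)), "ACGT")
  # 2x A beats 1x C at the first column
  expect_identical(peak_consensus(rep(10L, 3), rep(13L, 3),
                                  c("ACGT", "ACGT", "CCGT")), "ACGT")
  # weights flip the vote
  expect_identical(peak_consensus(rep(10L, 2), rep(13L, 2),
                                  c("ACGT", "CCGT"), weights = c(1, 3)),
                   "CCGT")
  # ties resolve in A < C < G < T order
  expect_identical(peak_consensus(rep(10L, 2), rep(13L, 2),
                                  c("TCGT", "GCGT")), "GCGT")
  # staggered reads extend the consensus across the peak-read span
  expect_identical(peak_consensus(c(10L, 12L), c(13L, 15L),
                                  c("ACGT", "GTAA")), "ACGTAA")
  # columns with no sequenced base emit N
  expect_identical(peak_consensus(c(10L, 10L), c(17L, 17L),
                                  c("ACGT", "ACGT")), "ACGTNNNN")
  # sequence-less peak reads give an empty consensus with a warning
  expect_warning(out <- peak_consensus(10L, 13L, NA_character_), "empty")
  expect_identical(out, "")
})

test_that("cluster_metrics assembles all per-cluster properties consistently", {
  reads <- c(make_reads("chr1", rep(1000L, 120), seq = strrep("A", 22)),
             make_reads("chr1", 2000L + 0:119, seq = strrep("C", 22)))
  reads$n_sites[1:10] <- 2L
  cl <- call_clusters(reads)
  cl <- cluster_metrics(cl, reads)
  expect_equal(length(cl), 2L)
  stack <- cl[GenomicRanges::start(cl) == 1000L]
  expect_equal(stack$complexity, 0)
  expect_equal(stack$peak_fraction, 1)
  expect_equal(stack$n_unique_reads, 110L)
  expect_equal(stack$n_distinct_sequences, 1L)
  expect_identical(stack$consensus, strrep("A", 22))
  tiled <- cl[GenomicRanges::start(cl) == 2000L]
  expect_gt(tiled$complexity, 0.9)
  expect_lt(tiled$peak_fraction, 0.3)
  # metrics unchanged under uniform weight rescaling
  reads2 <- reads
  reads2$weight <- reads2$weight * 5
  cl2 <- cluster_metrics(call_clusters(reads2, min_reads = 500), reads2)
  expect_equal(cl2$complexity, cl$complexity)
  expect_equal(cl2$peak_fraction, cl$peak_fraction)
})

test_that("group comparisons match the exact rank-sum tail and flag degenerate input", {
  a <- data.frame(complexity = seq(0.5, 0.69, by = 0.01))  # n = 20, all larger
  b <- data.frame(complexity = seq(0.1, 0.29, by = 0.01))
  res <- compare_properties(a, b, properties = "complexity")
  # complete separation, no ties: two-sided exact p = 2 / choose(40, 20)
  expect_equal(res$p_value, 2 / choose(40, 20), tolerance = 1e-12)
  expect_false(res$degenerate)

  same <- data.frame(complexity = stats::runif(30))
  res2 <- compare_properties(same, same, properties = "complexity")
  expect_gt(res2$p_value, 0.9)

  const <- data.frame(complexity = rep(0.2, 10))
  res3 <- compare_properties(const, const, properties = "complexity")
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)

  # BH adjustment across multiple properties
  a$length <- 1:20; b$length <- 1:20
  a$peak_fraction <- stats::runif(20); b$peak_fraction <- stats::runif(20)
  multi <- compare_properties(a, b, properties = c("complexity", "length",
                                                   "peak_fraction"))
  expect_equal(multi$fdr, stats::p.adjust(multi$p_value, "BH"))
})

test_that("permuted group labels give uniformly distributed rank-sum p-values", {
  set.seed(77)
  pooled <- stats::rnorm(40)
  pvals <- replicate(400, {
    lab <- sample(rep(c(TRUE, FALSE), each = 20))
    stats::wilcox.test(pooled[lab], pooled[!lab])$p.value
  })
  # exact rank-sum p-values live on a fine discrete grid, so duplicates are
  # expected; the KS comparison against the uniform is still informative
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})
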