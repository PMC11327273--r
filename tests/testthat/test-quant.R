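simple_clusters <- function(starts, ends, chrom = "chr1") {
  cl <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  cl$ugr_id <- sprintf("%s:%d-%d", chrom, starts, ends)
  cl
}

test_that("quantification assigns each read to its greatest-overlap cluster once", {
  cl <- simple_clusters(c(1000L, 1200L), c(1100L, 1300L))
  # 100 unit reads fully inside the first cluster
  inside <- make_reads("chr1", rep(1010L, 100))
  m <- quantify_clusters(list(s1 = inside), cl)
  expect_equal(unname(m[, "s1"]), c(100, 0))
  expect_equal(unname(attr(m, "library_sizes")), 100)

  # read overlapping cluster A by 20 bp and B by 5 bp -> counted in A only
  straddle <- make_reads("chr1", 1081L, width = 125L)  # [1081,1205]
  m2 <- quantify_clusters(list(s1 = straddle), cl)
  expect_equal(unname(m2[, "s1"]), c(1, 0))

  # exact-tie overlap goes to the leftmost cluster
  tie_cl <- simple_clusters(c(100L, 131L), c(120L, 151L))
  tie_rd <- make_reads("chr1", 111L, width = 30L)      # 10 bp in each
  m3 <- quantify_clusters(list(s1 = tie_rd), tie_cl)
  expect_equal(unname(m3[, "s1"]), c(1, 0))

  # overlapping cluster sets are rejected
  bad <- simple_clusters(c(100L, 150L), c(200L, 250L))
  expect_error(quantify_clusters(list(s1 = inside), bad), "non-overlapping")

  # empty sample yields a zero column with a warning
  expect_warning(
    m4 <- quantify_clusters(list(s1 = inside,
                                 s2 = make_reads("chr1", integer(0))), cl),
    "zero retained")
  expect_equal(unname(m4[, "s2"]), c(0, 0))
})

test_that("column sums never exceed library sizes across random simulations", {
  set.seed(9)
  cl <- simple_clusters(c(500L, 1500L, 3000L), c(700L, 1700L, 3300L))
  for (i in 1:10) {
    reads <- make_reads("chr1", sample(1:4000, 200, TRUE),
                        weights = stats::runif(200, 0.2, 1))
    m <- quantify_clusters(list(s = reads), cl)
    expect_lte(sum(m), sum(reads$weight) + 1e-9)
  }
  # when every read falls in a cluster the column sum equals the library size
  all_in <- make_reads("chr1", sample(500:679, 150, TRUE))
  m <- quantify_clusters(list(s = all_in), cl)
  expect_equal(sum(m), 150)
})

test_that("CPM and log2-CPM follow their definitions", {
  m <- matrix(c(10, 90), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  attr(m, "library_sizes") <- c(s1 = 1e6)
  expect_equal(unname(cpm(m)[, 1]), c(10, 90))
  # doubling counts and library size leaves CPM unchanged
  m2 <- m * 2
  attr(m2, "library_sizes") <- c(s1 = 2e6)
  expect_equal(cpm(m2)[, 1], cpm(m)[, 1])
  # log2-CPM is monotone in the count at fixed library size
  lc <- log2_cpm(m)
  expect_lt(lc["a", 1], lc["b", 1])
  expect_equal(attr(lc, "prior"), 0.5)
  # voom-style closed form
  expect_equal(lc["a", 1], log2((10 + 0.5) / (1e6 + 1) * 1e6))
})

test_that("the CPM expression filter keeps and drops rows at the threshold", {
  m <- matrix(c(9.9, 9.9, 0, 10.5, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("edge_low", "edge_high", "zero"),
                              c("s1", "s2")))
  attr(m, "library_sizes") <- c(s1 = 1e6, s2 = 1e6)
  f <- filter_expressed(m)
  expect_equal(rownames(f), "edge_high")       # max 9.9 dropped, 10.5 kept
  expect_equal(attr(f, "n_dropped"), 2L)
  f2 <- filter_expressed(m, cpm_threshold = 5)
  expect_setequal(rownames(f2), c("edge_low", "edge_high"))
  # filtering twice is idempotent
  ff <- filter_expressed(f)
  expect_equal(dim(ff), dim(f))
  expect_equal(as.numeric(ff), as.numeric(f))
  # group-wise: require the qualifying sample within one phenotype group
  g <- filter_expressed(m, groups = c("x", "y"), min_samples = 1L)
  expect_equal(rownames(g), "edge_high")
})

test_that("profile correlations reproduce exact rank arithmetic", {
  m <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40,
                40, 30, 20, 10), ncol = 3,
              dimnames = list(letters[1:4], c("s1", "s2", "s3")))
  attr(m, "library_sizes") <- c(s1 = 1e6, s2 = 1e6, s3 = 1e6)
  expect_equal(spearman_profile_correlation(m, "s1", "s1")$rho, 1)
  expect_equal(spearman_profile_correlation(m, "s1", "s2")$rho, 1)
  expect_equal(spearman_profile_correlation(m, "s1", "s3")$rho, -1)
  # hand-ranked oracle on a non-monotone profile
  m2 <- matrix(c(5, 1, 4, 2, 8, 6, 7, 9), ncol = 2,
               dimnames = list(letters[1:4], c("s1", "s2")))
  attr(m2, "library_sizes") <- c(s1 = 1e6, s2 = 1e6)
  ra <- rank(m2[, 1]); rb <- rank(m2[, 2])
  rho_hand <- 1 - 6 * sum((ra - rb)^2) / (4 * (16 - 1))
  expect_equal(spearman_profile_correlation(m2, "s1", "s2")$rho, rho_hand)
  # constant profile is flagged, not silently correlated
  m3 <- matrix(c(1, 1, 1, 1, 2, 3), ncol = 2,
               dimnames = list(letters[1:3], c("s1", "s2")))
  attr(m3, "library_sizes") <- c(s1 = 1e6, s2 = 1e6)
  res <- spearman_profile_correlation(m3, "s1", "s2")
  expect_true(res$degenerate)
  expect_true(is.na(res$rho))
})

test_that("count matrices round-trip through TSV at full precision", {
  set.seed(4)
  m <- matrix(stats::runif(12) * 1000, nrow = 4,
              dimnames = list(sprintf("chr1:%d-%d", 1:4, 11:14),
                              c("s1", "s2", "s3")))
  attr(m, "library_sizes") <- c(s1 = 1234.5, s2 = 999, s3 = 5e4)
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  back <- read_count_matrix(path)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-12)
  expect_equal(attr(back, "library_sizes"), attr(m, "library_sizes"))
})
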