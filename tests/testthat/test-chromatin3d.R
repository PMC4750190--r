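make_hic <- function(n, seed = 1, boost_pairs = NULL, boost = 0) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- abs(rnorm(sum(up), 5, 1))
  m <- m + t(m * upper.tri(m))
  if (!is.null(boost_pairs))
    for (q in seq_len(nrow(boost_pairs))) {
      i <- boost_pairs[q, 1]; j <- boost_pairs[q, 2]
      m[i, j] <- m[i, j] + boost; m[j, i] <- m[i, j]
    }
  hic_matrix("chr1", m, 40000L)
}

test_that("bin membership requires full containment; sub-bin blocks are excluded", {
  h <- make_hic(10)
  blocks <- gr_from_bed0("chr1", c(0, 40000, 161000), c(39000, 120000, 250000),
                         chrom_sizes = c(chr1 = 400000L))
  blocks$block_id <- c("tiny", "exact", "offset")
  bm <- map_blocks_to_bins(blocks, h)
  expect_null(bm$tiny)                       # 39-kb block: no full bin
  expect_equal(attr(bm, "n_excluded"), 1L)
  expect_equal(bm$exact, c(2L, 3L))          # [40000,120000) = bins 2,3 (1-based)
  expect_equal(bm$offset, 6L)                # only [200000,240000) fits fully
})

test_that("bin membership agrees with brute-force containment on a 20-block fixture", {
  h <- make_hic(100)
  set.seed(2)
  st <- sort(sample(seq(0, 3800000, 10000), 20))
  en <- st + sample(30000:150000, 20, TRUE)
  en <- pmin(en, 4000000)
  ok <- c(TRUE, en[-20] < st[-1])   # keep non-overlapping subset
  blocks <- gr_from_bed0("chr1", st[ok], en[ok],
                         chrom_sizes = c(chr1 = 4000000L))
  blocks$block_id <- seq_len(sum(ok))
  bm <- map_blocks_to_bins(blocks, h)
  for (i in seq_len(sum(ok))) {
    manual <- which(vapply(0:99, function(k)
      k * 40000 >= st[ok][i] && (k + 1) * 40000 <= en[ok][i], logical(1)))
    got <- bm[[as.character(i)]]
    if (length(manual) == 0) expect_null(got) else expect_equal(got, manual)
  }
})

test_that("interaction strength is the pairwise sum over bins divided by bin count", {
  m <- matrix(0, 5, 5)
  m[2, 3] <- m[3, 2] <- 2; m[2, 4] <- m[4, 2] <- 4; m[3, 4] <- m[4, 3] <- 6
  h <- hic_matrix("chr1", m, 40000L)
  expect_equal(interaction_strength(c(2, 3, 4), h), (2 + 4 + 6) / 3)
  expect_equal(interaction_strength(c(2, 3, 4), make_hic(5, boost = 0)),
               bf_strength(c(2, 3, 4), make_hic(5)$mat))
  expect_equal(interaction_strength(c(1, 5), hic_matrix("chr1",
               matrix(0, 5, 5), 40000L)), 0)
  expect_true(is.na(interaction_strength(3, h)))
  # oracle on a 6-bin block; invariance to relabeling; linearity
  h2 <- make_hic(30, seed = 3)
  bins <- c(4, 9, 11, 17, 20, 26)
  expect_equal(interaction_strength(bins, h2), bf_strength(bins, h2$mat))
  expect_equal(interaction_strength(sample(bins), h2),
               interaction_strength(bins, h2))
  h3 <- hic_matrix("chr1", 2 * h2$mat, 40000L)
  expect_equal(interaction_strength(bins, h3), 2 * interaction_strength(bins, h2))
})

planted_blocks <- function(n_blocks = 50, seed = 4) {
  set.seed(seed)
  st <- seq(0, by = 240000, length.out = n_blocks) +
    sample(0:30000, n_blocks, TRUE)
  len <- sample(c(120000, 160000, 200000), n_blocks, TRUE)
  gr_from_bed0("chr1", st, st + len,
               chrom_sizes = c(chr1 = 240000 * n_blocks + 80000))
}

test_that("planted intra-block lift is detected and the null is calibrated", {
  blocks <- planted_blocks()
  n <- as.integer((240000 * 50 + 80000) / 40000)
  base <- make_hic(n, seed = 5)
  bm <- map_blocks_to_bins(blocks, base)
  pairs <- do.call(rbind, lapply(bm, function(b)
    if (length(b) >= 2) t(utils::combn(b, 2))))
  lifted <- make_hic(n, seed = 5, boost_pairs = pairs, boost = 5)
  res <- strength_vs_random(blocks, lifted, seed = 6)
  expect_gt(res$mean_blocks, res$mean_random)
  expect_lt(res$p_value, 0.01)
  # identical block and control sets tie exactly
  s <- hmboundary:::block_strengths(blocks, lifted)
  expect_equal(suppressWarnings(stats::wilcox.test(s, s)$p.value), 1)
  # null: no lift -> p > 0.05 in at least 17 of 20 replicates
  hits <- sum(vapply(1:20, function(i) {
    r <- strength_vs_random(blocks, make_hic(n, seed = 100 + i), seed = i)
    r$p_value > 0.05
  }, logical(1)))
  expect_gte(hits, 17)
})

test_that("TAD distances follow the minimum-to-any-edge definition", {
  blocks <- gr_from_bed0("chr1", 90, 240, chrom_sizes = c(chr1 = 100000L))
  expect_equal(hmboundary:::min_distances(100,
               hmboundary:::boundary_points(blocks)), 10)
  expect_equal(hmboundary:::min_distances(90,
               hmboundary:::boundary_points(blocks)), 0)
  expect_equal(hmboundary:::min_distances(c(0, 239, 500),
               hmboundary:::boundary_points(blocks)), c(90, 1, 260))
})

test_that("jittered TADs are closer to block boundaries than random controls", {
  blocks <- planted_blocks(seed = 7)
  cl <- 240000 * 50 + 80000
  set.seed(8)
  st <- pmax(0, GenomicRanges::start(blocks) - 1 + round(rnorm(50, 0, 5000)))
  en <- pmin(cl, GenomicRanges::end(blocks) + round(rnorm(50, 0, 5000)))
  tads <- gr_from_bed0("chr1", st[en - st > 5000], en[en - st > 5000],
                       chrom_sizes = c(chr1 = cl))
  res <- tad_proximity(tads, blocks, cl, seed = 9)
  expect_lt(res$median_obs, res$median_control)
  expect_lt(res$p_value, 0.01)
  # decoupled TADs show no association
  set.seed(10)
  st2 <- sort(sample(seq(0, cl - 200000, 1000), 50))
  tads2 <- gr_from_bed0("chr1", st2, st2 + 150000, chrom_sizes = c(chr1 = cl))
  res2 <- tad_proximity(tads2, blocks, cl, seed = 11)
  expect_gt(res2$p_value, 0.001)
})

test_that("Hi-C matrices round-trip through the dense text format", {
  h <- make_hic(12, seed = 12)
  path <- tempfile(fileext = ".txt")
  write_hic(h, path)
  back <- read_hic(path)
  expect_equal(back$chrom, "chr1")
  expect_equal(back$bin_width, 40000L)
  expect_equal(back$mat, h$mat, tolerance = 1e-6)
  expect_error(hic_matrix("chr1", matrix(1:6, 2, 3)), "square")
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(hic_matrix("chr1", m), "symmetric")
})
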