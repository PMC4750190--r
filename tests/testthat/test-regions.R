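cs1 <- c(chr1 = 400000L)

test_that("boundary arithmetic follows the 5 kb outside + 1 kb inside rule", {
  blocks <- gr_from_bed0("chr1", 100000, 200000, chrom_sizes = cs1)
  bd <- derive_boundaries(blocks)
  df <- bed0_from_gr(bd)
  expect_equal(df$start, c(95000, 199000))
  expect_equal(df$end, c(101000, 205000))
  expect_equal(df$side, c("left", "right"))
  expect_true(all(GenomicRanges::width(bd) == 6000))
})

test_that("unclipped blocks yield exactly two boundaries each; clipped ones are dropped", {
  b <- default_bundle()
  bd <- derive_boundaries(b$blocks, boundary_spec(), b$chrom_sizes)
  expect_equal(length(bd) + attr(bd, "n_clipped"), 2L * length(b$blocks))
  # block too close to the chromosome start loses its left boundary only
  blocks <- gr_from_bed0("chr1", c(2000, 100000), c(30000, 150000),
                         chrom_sizes = cs1)
  bd2 <- derive_boundaries(blocks)
  expect_equal(length(bd2), 3L)
  expect_equal(attr(bd2, "n_clipped"), 1L)
  expect_false(any(bd2$side == "left" & bd2$block_id == 1))
})

test_that("overlapping input blocks are rejected with the offending pair", {
  blocks <- gr_from_bed0("chr1", c(1000, 5000), c(10000, 20000),
                         chrom_sizes = cs1)
  expect_error(derive_boundaries(blocks), "overlap")
})

test_that("control sampling respects geometry, disjointness and length", {
  # a 6-kb block has no interior left after the two 1-kb inside flanks
  small <- gr_from_bed0("chr1", 50000, 56000, chrom_sizes = cs1)
  bd <- derive_boundaries(small)
  expect_error(sample_controls(small, bd, "inside", 1, 6000, seed = 1, cs1),
               "achieved 0")
  b <- default_bundle()
  r <- bundle_regions()
  for (set in list(r$inside, r$outside)) {
    expect_length(set, 60L)
    expect_true(all(GenomicRanges::width(set) == 6000))
    expect_equal(length(GenomicRanges::findOverlaps(set, r$boundaries)), 0L)
    # brute-force pairwise overlap check within the sampled set
    df <- bed0_from_gr(set)
    for (i in seq_len(nrow(df) - 1))
      for (j in (i + 1):nrow(df))
        expect_true(df$chrom[i] != df$chrom[j] ||
                    df$end[i] <= df$start[j] || df$end[j] <= df$start[i])
  }
  ins_hits <- GenomicRanges::findOverlaps(r$inside, b$blocks, type = "within")
  expect_equal(length(unique(S4Vectors::queryHits(ins_hits))), 60L)
  expect_equal(length(GenomicRanges::findOverlaps(r$outside, b$blocks)), 0L)
  # deterministic under seed
  again <- sample_controls(b$blocks, r$boundaries, "inside", 60, seed = 101,
                           chrom_sizes = b$chrom_sizes)
  expect_identical(bed0_from_gr(again), bed0_from_gr(r$inside))
})

test_that("promoters are strand-aware, deduplicated and require strands", {
  tss <- gr_from_bed0("chr1", c(50000, 150000), c(50001, 150001),
                      strand = c("+", "-"), chrom_sizes = cs1)
  pr <- derive_promoters(tss)
  df <- bed0_from_gr(pr)
  expect_equal(df$start[df$strand == "+"], 45000)
  expect_equal(df$end[df$strand == "+"], 51000)
  expect_equal(df$start[df$strand == "-"], 149000)
  expect_equal(df$end[df$strand == "-"], 155000)
  # two TSS 100 b apart on the same strand keep only the first window
  tss2 <- gr_from_bed0("chr1", c(50000, 50100), c(50001, 50101),
                       strand = "+", chrom_sizes = cs1)
  expect_length(derive_promoters(tss2), 1L)
  tss3 <- gr_from_bed0("chr1", 50000, 50001, chrom_sizes = cs1)
  expect_error(derive_promoters(tss3), "strand")
})

test_that("GC matching returns a permutation on identical inputs and reports disjoint histograms", {
  g <- tiny_genome(100000, seed = 3)
  set.seed(4)
  cases <- gr_from_bed0("chr1", st <- sample(0:90000, 20), st + 1000,
                        chrom_sizes = c(chr1 = 100000L))
  m <- gc_match(cases, cases, g, seed = 9)
  expect_equal(bed0_from_gr(GenomicRanges::sort(m))[, 1:3],
               bed0_from_gr(GenomicRanges::sort(cases))[, 1:3])
  # all-AT candidates cannot match ~50%-GC cases: empty selection, full report
  g2 <- Biostrings::DNAStringSet(c(as.character(g[["chr1"]]),
                                   paste(rep("AT", 50000), collapse = "")))
  names(g2) <- c("chr1", "chr2")
  cand <- gr_from_bed0("chr2", seq(0, 19000, 1000), seq(0, 19000, 1000) + 1000)
  m2 <- gc_match(cases, cand, g2, seed = 2)
  expect_length(m2, 0L)
  short <- attr(m2, "shortfall")
  expect_equal(sum(short$needed), 20)
  expect_equal(sum(short$selected), 0)
})

test_that("GC-matched selection tracks the case GC distribution (small KS distance)", {
  g <- tiny_genome(2e6, seed = 21)
  cs <- c(chr1 = 2000000L)
  set.seed(22)
  cases <- gr_from_bed0("chr1", st <- sample(0:1990000, 2000), st + 500,
                        chrom_sizes = cs)
  cand <- gr_from_bed0("chr1", st2 <- sample(0:1990000, 8000), st2 + 500,
                       chrom_sizes = cs)
  m <- gc_match(cases, cand, g, seed = 23)
  gc_case <- hmboundary:::gc_fraction(cases, g)
  gc_sel <- hmboundary:::gc_fraction(m, g)
  grid <- sort(unique(c(gc_case, gc_sel)))
  F1 <- ecdf(gc_case)(grid); F2 <- ecdf(gc_sel)(grid)
  expect_lt(max(abs(F1 - F2)), 0.05)
})

test_that("TSS exclusion follows half-open semantics and matches a brute-force scan", {
  regions <- gr_from_bed0("chr1", c(1000, 5000, 9000), c(2000, 6000, 10000),
                          chrom_sizes = cs1)
  tss_in <- gr_from_bed0("chr1", 1500, 1501, strand = "+", chrom_sizes = cs1)
  expect_length(exclude_tss_overlaps(regions, tss_in), 2L)
  # TSS exactly at a region end is outside the half-open interval
  tss_end <- gr_from_bed0("chr1", 2000, 2001, strand = "+", chrom_sizes = cs1)
  kept <- exclude_tss_overlaps(regions, tss_end)
  expect_length(kept, 3L)
  # brute force on a random 100-region fixture
  set.seed(12)
  st <- sample(0:99000, 100)
  reg <- gr_from_bed0("chr1", st, st + 500, chrom_sizes = c(chr1 = 100000L))
  tp <- sample(0:99500, 40)
  tss <- gr_from_bed0("chr1", tp, tp + 1, strand = "+",
                      chrom_sizes = c(chr1 = 100000L))
  got <- exclude_tss_overlaps(reg, tss)
  manual_keep <- vapply(seq_along(reg), function(i)
    !any(tp >= st[i] & tp < st[i] + 500), logical(1))
  expect_equal(bed0_from_gr(got)[, 1:3], bed0_from_gr(reg[manual_keep])[, 1:3])
  expect_equal(attr(got, "n_removed"), sum(!manual_keep))
})

test_that("BED round trip preserves intervals, names and strands", {
  gr <- gr_from_bed0("chr1", c(0, 100, 5000), c(50, 400, 9000),
                     strand = c("+", "-", "*"), chrom_sizes = cs1)
  gr$name <- c("a", "b", "c")
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path, cs1)
  expect_equal(bed0_from_gr(back)[, c("chrom", "start", "end", "strand")],
               bed0_from_gr(gr)[, c("chrom", "start", "end", "strand")])
  expect_equal(back$name, gr$name)
})
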