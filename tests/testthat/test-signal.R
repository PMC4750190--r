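flat_track <- function(value, n = 5000, chrom = "chr1", bw = 20L)
  binned_track(stats::setNames(list(rep(value, n)), chrom), bw)

test_that("log-ratio normalization has the expected identities", {
  t1 <- flat_track(2); i1 <- flat_track(2)
  expect_true(all(normalize_track(t1, i1)$values$chr1 == 0))
  t2 <- flat_track(exp(1)); i2 <- flat_track(1)
  expect_true(all(abs(normalize_track(t2, i2, pseudocount = 0)$values$chr1 - 1)
                  < 1e-12))
  # spot-check bins against hand computation with the default pseudocount
  set.seed(3)
  tv <- runif(10, 0, 5); iv <- runif(10, 0, 5)
  tt <- binned_track(list(chr1 = tv), 20L)
  ii <- binned_track(list(chr1 = iv), 20L)
  nn <- normalize_track(tt, ii)
  expect_equal(nn$values$chr1, log((tv + 0.5) / (iv + 0.5)))
  expect_error(normalize_track(tt, flat_track(1, n = 11)), "grid")
})

test_that("region means weight partial bins and match a per-base oracle", {
  tr <- flat_track(3.5)
  reg <- gr_from_bed0("chr1", c(100, 5000), c(700, 9000))
  expect_equal(region_mean(tr, reg), c(3.5, 3.5))
  # region covering two bins equally with values 0 and 2
  tr2 <- binned_track(list(chr1 = c(0, 2)), 20L)
  reg2 <- gr_from_bed0("chr1", 10, 30)
  expect_equal(region_mean(tr2, reg2), 1.0)
  # per-base expansion oracle on a 1-kb fixture
  set.seed(4)
  v <- rnorm(50)
  tr3 <- binned_track(list(chr1 = v), 20L)
  per_base <- rep(v, each = 20)
  st <- sample(0:800, 20); en <- st + sample(37:150, 20)
  reg3 <- gr_from_bed0("chr1", st, en)
  oracle <- vapply(seq_len(20), function(i)
    mean(per_base[(st[i] + 1):en[i]]), numeric(1))
  expect_equal(region_mean(tr3, reg3), oracle, tolerance = 1e-12)
  # linearity in the track
  expect_equal(region_mean(binned_track(list(chr1 = 2.5 * v), 20L), reg3),
               2.5 * region_mean(tr3, reg3))
})

test_that("metaprofiles are flat on flat tracks and localize the planted peak", {
  b <- default_bundle(); r <- bundle_regions()
  flat <- binned_track(lapply(b$chrom_sizes, function(L) rep(1, ceiling(L / 20))),
                       20L)
  mp0 <- metaprofile(flat, r$boundaries, span = 10000)
  expect_true(all(abs(mp0$mean - 1) < 1e-12))
  norm <- normalize_track(b$chip_tracks$H3K4me3$treatment,
                          b$chip_tracks$H3K4me3$input)
  mp <- metaprofile(norm, r$boundaries)
  peak_at <- mp$offset[which.max(mp$mean)]
  expect_lte(abs(peak_at), 1500)          # within 1.5 kb of the boundary
  expect_lt(peak_at, 0)                   # on the outside
  # left-only vs right-only profiles agree within sampling error
  mpl <- metaprofile(norm, r$boundaries[r$boundaries$side == "left"])
  mpr <- metaprofile(norm, r$boundaries[r$boundaries$side == "right"])
  expect_lt(abs(mpl$offset[which.max(mpl$mean)] -
                mpr$offset[which.max(mpr$mean)]), 1500)
  # shuffled anchors see no structure
  set.seed(6)
  fake <- r$boundaries
  sh <- sample(10000:1400000, length(fake))
  fake2 <- gr_from_bed0(as.character(GenomeInfoDb::seqnames(fake)), sh,
                        sh + 6000, chrom_sizes = b$chrom_sizes)
  fake2$side <- fake$side
  mps <- metaprofile(norm, fake2)
  expect_lt(max(mps$mean) - min(mps$mean),
            max(mp$mean) - min(mp$mean))
})

test_that("rank-sum comparison matches exact enumeration and detects planted lift", {
  tr <- flat_track(1, n = 50000)
  reg <- gr_from_bed0("chr1", seq(0, 4000, 1000), seq(0, 4000, 1000) + 500)
  ident <- compare_sets(tr, reg, reg)
  expect_equal(ident$p_value, 1)
  # 5 vs 5 fixture against enumeration of all rank assignments
  set.seed(7)
  v <- rnorm(50)
  tr2 <- binned_track(list(chr1 = v), 20L)
  a <- gr_from_bed0("chr1", c(0, 100, 200, 300, 400), c(60, 160, 260, 360, 460))
  b2 <- gr_from_bed0("chr1", c(500, 600, 700, 800, 900),
                     c(560, 660, 760, 860, 960))
  got <- compare_sets(tr2, a, b2)
  expect_equal(got$p_value,
               bf_ranksum_p(region_mean(tr2, a), region_mean(tr2, b2)),
               tolerance = 1e-12)
  # power: boundary-peaked synthetic track, 200 regions per set
  set.seed(8)
  n_bins <- 250000
  vals <- rnorm(n_bins, 0, 0.5)
  anchors <- seq(1000, by = 1200, length.out = 200)    # bin indices
  for (anc in anchors) vals[(anc - 50):(anc + 50)] <-
    vals[(anc - 50):(anc + 50)] + 0.3
  tr3 <- binned_track(list(chr1 = vals), 20L)
  set_a <- gr_from_bed0("chr1", (anchors - 75) * 20, (anchors + 75) * 20)
  set_b <- gr_from_bed0("chr1", (anchors + 200) * 20, (anchors + 350) * 20)
  cmp <- compare_sets(tr3, set_a, set_b)
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$p_value, 0.05)
  expect_error(compare_sets(tr3, set_a[1], set_b), "at least 2")
})

test_that("CTCF stratification recovers the planted boundary occupancy", {
  expect_equal(site_frequency(gr_from_bed0("chr1", 0, 100),
                              GenomicRanges::GRanges()), 0)
  b <- simulate_bundle(sim_config(seed = 31, n_motifs = 0L, n_genes = 0L,
                                  ctcf_boundary_prob = 0.3,
                                  ctcf_background_prob = 0.1))
  bd <- derive_boundaries(b$blocks, boundary_spec(), b$chrom_sizes)
  freq <- site_frequency(bd, b$ctcf_sites)
  # boundary occupancy: planted 0.3 plus background leakage; binomial band
  expect_gt(freq, 0.3 - 3 * sqrt(0.3 * 0.7 / length(bd)))
  expect_lt(freq, 0.55)
  out <- sample_controls(b$blocks, bd, "outside", 60, seed = 1,
                         chrom_sizes = b$chrom_sizes)
  expect_gt(freq, site_frequency(out, b$ctcf_sites))
  # stratified comparison runs on the default bundle
  bb <- default_bundle(); rr <- bundle_regions()
  norm <- normalize_track(bb$chip_tracks$H3K4me3$treatment,
                          bb$chip_tracks$H3K4me3$input)
  strat <- ctcf_stratify(norm, rr$boundaries, bb$ctcf_sites)
  expect_false(strat$skipped)
  expect_equal(strat$freq_with,
               site_frequency(rr$boundaries, bb$ctcf_sites))
  # no sites: skipped with frequency zero
  s0 <- ctcf_stratify(norm, rr$boundaries, GenomicRanges::GRanges())
  expect_true(s0$skipped)
  expect_equal(s0$freq_with, 0)
})

test_that("bedGraph track round trip preserves values on the bin grid", {
  set.seed(9)
  v <- round(rnorm(200), 6)
  tr <- binned_track(list(chr1 = v), 20L)
  path <- tempfile(fileext = ".bedGraph")
  write_track(tr, path)
  back <- read_track(path, 20L, c(chr1 = 4000L))
  expect_equal(back$values$chr1, v, tolerance = 1e-9)
})
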