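# Hi-C intra-block interaction strength with a length-matched random-region
# null, and proximity of TAD boundaries to block boundaries.

#' Normalized Hi-C contact matrix for one chromosome
#' @param chrom chromosome name.
#' @param matrix square symmetric nonnegative contact matrix.
#' @param bin_width bin width in bases (default 40000).
#' @return object of class `hic_matrix`.
#' @export
hic_matrix <- function(chrom, matrix, bin_width = 40000L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stopf("Hi-C matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-6) stopf("Hi-C matrix must be symmetric")
  if (any(matrix < 0)) stopf("Hi-C matrix must be nonnegative")
  structure(list(chrom = chrom, mat = matrix, bin_width = as.integer(bin_width)),
            class = "hic_matrix")
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat(sprintf("Hi-C matrix %s: %d x %d bins of %d b\n", x$chrom,
              nrow(x$mat), ncol(x$mat), x$bin_width))
  invisible(x)
}

#' Map blocks to fully contained Hi-C bins
#'
#' A bin belongs to a block only when it lies entirely within it, so blocks
#' shorter than one bin are excluded.
#'
#' @param blocks `GRanges` on the matrix's chromosome.
#' @param hic a [hic_matrix()].
#' @return named list of 1-based bin-index vectors, one per retained block;
#'   attribute `n_excluded` counts blocks with no fully contained bin.
#' @export
map_blocks_to_bins <- function(blocks, hic) {
  bw <- hic$bin_width
  blocks <- blocks[as.character(GenomeInfoDb::seqnames(blocks)) == hic$chrom]
  ids <- as.character(blocks$block_id %||% seq_along(blocks))
  s0 <- GenomicRanges::start(blocks) - 1L
  e0 <- GenomicRanges::end(blocks)
  out <- list()
  excluded <- 0L
  for (i in seq_along(blocks)) {
    k0 <- ceiling(s0[i] / bw)           # first bin starting at/after block start
    k1 <- floor(e0[i] / bw) - 1L        # last bin ending at/before block end
    k1 <- min(k1, nrow(hic$mat) - 1L)
    if (k1 < k0) { excluded <- excluded + 1L; next }
    out[[ids[i]]] <- (k0:k1) + 1L
  }
  attr(out, "n_excluded") <- excluded
  out
}

#' Intra-block interaction strength
#'
#' Sum of contacts over distinct within-block bin pairs (diagonal excluded)
#' divided by the number of bins.
#'
#' @param bins 1-based bin indices of one block.
#' @param hic a [hic_matrix()].
#' @return strength (contact units per bin), or `NA` when fewer than 2 bins.
#' @export
interaction_strength <- function(bins, hic) {
  n <- length(bins)
  if (n < 2L) return(NA_real_)
  sub <- hic$mat[bins, bins, drop = FALSE]
  sum(sub[upper.tri(sub)]) / n
}

block_strengths <- function(blocks, hic) {
  bm <- map_blocks_to_bins(blocks, hic)
  s <- vapply(bm, interaction_strength, numeric(1), hic = hic)
  s[!is.na(s)]
}

# Length-matched non-overlapping random regions on the same chromosome,
# placed longest-first by uniform draws over the remaining free segments.
random_length_matched <- function(lengths, chrom, chrom_len, seed,
                                  avoid = NULL) {
  lengths <- sort(as.integer(lengths), decreasing = TRUE)
  seg_s <- 0; seg_e <- as.numeric(chrom_len)   # 0-based half-open segments
  out_s <- numeric(length(lengths))
  with_seed(seed, {
    for (q in seq_along(lengths)) {
      L <- lengths[q]
      avail <- pmax(seg_e - seg_s - L + 1, 0)
      if (sum(avail) == 0)
        stopf("cannot place random %d-b region on %s", L, chrom)
      k <- if (length(avail) == 1L) 1L else
        sample.int(length(avail), 1L, prob = avail)
      st <- seg_s[k] + sample.int(avail[k], 1L) - 1
      out_s[q] <- st
      old_e <- seg_e[k]
      seg_e[k] <- st
      if (st + L < old_e) { seg_s <- c(seg_s, st + L); seg_e <- c(seg_e, old_e) }
      keep <- seg_e > seg_s
      seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
    }
  })
  placed <- gr_from_bed0(chrom, out_s, out_s + lengths,
                         chrom_sizes = stats::setNames(chrom_len, chrom))
  placed <- GenomicRanges::sort(placed)
  placed$block_id <- seq_along(placed)
  placed
}

#' Intra-block strength versus random length-matched regions
#'
#' @param blocks `GRanges` of blocks on the matrix's chromosome.
#' @param hic a [hic_matrix()].
#' @param seed RNG seed for the random placement.
#' @return list: `mean_blocks`, `mean_random`, `p_value` (two-sided rank-sum),
#'   `strength_blocks`, `strength_random`.
#' @export
strength_vs_random <- function(blocks, hic, seed = 1L) {
  blocks <- blocks[as.character(GenomeInfoDb::seqnames(blocks)) == hic$chrom]
  chrom_len <- nrow(hic$mat) * hic$bin_width
  rnd <- random_length_matched(GenomicRanges::width(blocks), hic$chrom,
                               chrom_len, seed)
  sb <- block_strengths(blocks, hic)
  sr <- block_strengths(rnd, hic)
  if (length(sb) < 2L || length(sr) < 2L)
    stopf("too few blocks with >= 2 fully contained bins")
  wt <- suppressWarnings(stats::wilcox.test(sb, sr, alternative = "two.sided"))
  list(mean_blocks = mean(sb), mean_random = mean(sr), p_value = wt$p.value,
       strength_blocks = sb, strength_random = sr)
}

boundary_points <- function(blocks) {
  sort(c(GenomicRanges::start(blocks) - 1L, GenomicRanges::end(blocks)))
}

min_distances <- function(points, targets) {
  targets <- sort(targets)
  idx <- findInterval(points, targets)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(targets))
  pmin(abs(points - targets[lo]), abs(points - targets[hi]))
}

#' Proximity of TAD boundaries to block boundaries
#'
#' For every TAD boundary, the minimum distance to any block edge (starts and
#' ends both count); as a null, the same distances against random
#' length-matched non-overlapping blocks.
#'
#' @param tads,blocks `GRanges` on one chromosome.
#' @param chrom_len chromosome length in bases (defaults to `seqlengths`).
#' @param seed RNG seed for the random blocks.
#' @return list: `distances`, `control_distances`, means, medians, and the
#'   two-sided rank-sum `p_value`.
#' @export
tad_proximity <- function(tads, blocks, chrom_len = NULL, seed = 1L) {
  if (!length(tads) || !length(blocks)) stopf("empty TAD or block set")
  chrom <- unique(as.character(GenomeInfoDb::seqnames(blocks)))
  if (length(chrom) != 1L) stopf("tad_proximity works per chromosome")
  chrom_len <- chrom_len %||% GenomeInfoDb::seqlengths(blocks)[[chrom]]
  tp <- boundary_points(tads)
  d_obs <- min_distances(tp, boundary_points(blocks))
  rnd <- random_length_matched(GenomicRanges::width(blocks), chrom, chrom_len,
                               seed)
  d_ctl <- min_distances(tp, boundary_points(rnd))
  wt <- suppressWarnings(stats::wilcox.test(d_obs, d_ctl,
                                            alternative = "two.sided"))
  list(distances = d_obs, control_distances = d_ctl,
       mean_obs = mean(d_obs), mean_control = mean(d_ctl),
       median_obs = stats::median(d_obs), median_control = stats::median(d_ctl),
       p_value = wt$p.value)
}

#' Read a dense Hi-C matrix with its sidecar header
#'
#' The matrix file is whitespace-delimited; the sidecar `<path>.json` holds
#' `chrom` and `bin_width`.
#'
#' @param path matrix file.
#' @return a [hic_matrix()].
#' @export
read_hic <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  hic_matrix(meta$chrom, m, meta$bin_width)
}

#' Write a dense Hi-C matrix and its sidecar header
#' @param hic a [hic_matrix()].
#' @param path output matrix file (sidecar written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_hic <- function(hic, path) {
  utils::write.table(format(hic$mat, trim = TRUE), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(chrom = hic$chrom, bin_width = hic$bin_width),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
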