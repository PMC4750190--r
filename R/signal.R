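# Binned ChIP-signal tracks: input normalization, per-region summaries,
# boundary-aligned metaprofiles, and CTCF-stratified comparisons.

#' Fixed-width binned signal track
#' @param values named list, one numeric vector per chromosome; `NA` encodes
#'   missing data.
#' @param bin_width bin width in bases (default 20).
#' @return object of class `binned_track`.
#' @export
binned_track <- function(values, bin_width = 20L) {
  stopifnot(is.list(values), !is.null(names(values)))
  structure(list(values = values, bin_width = as.integer(bin_width)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned track: %d chromosome(s), %d-b bins\n",
              length(x$values), x$bin_width))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (a$bin_width != b$bin_width ||
      !identical(sort(names(a$values)), sort(names(b$values))) ||
      !all(vapply(names(a$values),
                  function(c) length(a$values[[c]]) == length(b$values[[c]]),
                  logical(1))))
    stopf("tracks are not on the same bin grid")
}

#' Log-ratio normalization of a ChIP track against its input
#'
#' value = log((treatment + eps) / (input + eps)), natural log; missing bins
#' propagate.
#'
#' @param treatment,input `binned_track`s on the same grid.
#' @param pseudocount eps (default 0.5).
#' @return normalized `binned_track`.
#' @export
normalize_track <- function(treatment, input, pseudocount = 0.5) {
  check_same_grid(treatment, input)
  vals <- lapply(names(treatment$values), function(c)
    log((treatment$values[[c]] + pseudocount) /
        (input$values[[c]] + pseudocount)))
  binned_track(stats::setNames(vals, names(treatment$values)),
               treatment$bin_width)
}

#' Mean track signal per region
#'
#' Bins partially covered by the region edge are weighted by their overlap
#' fraction; missing bins are excluded from the mean.
#'
#' @param track a `binned_track`.
#' @param regions `GRanges` within the track extent.
#' @return numeric vector, one (possibly `NA`) mean per region.
#' @export
region_mean <- function(track, regions) {
  bw <- track$bin_width
  ch <- as.character(GenomeInfoDb::seqnames(regions))
  s0 <- GenomicRanges::start(regions) - 1L
  e0 <- GenomicRanges::end(regions)
  vapply(seq_along(regions), function(i) {
    v <- track$values[[ch[i]]]
    if (is.null(v)) stopf("chromosome '%s' absent from track", ch[i])
    k0 <- s0[i] %/% bw
    k1 <- (e0[i] - 1L) %/% bw
    if (k1 + 1L > length(v)) stopf("region beyond track extent on '%s'", ch[i])
    ks <- k0:k1
    w <- pmin(e0[i], (ks + 1) * bw) - pmax(s0[i], ks * bw)
    vv <- v[ks + 1L]
    ok <- !is.na(vv)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * vv[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Boundary-aligned signal metaprofile
#'
#' Averages the track around each block edge; right-side boundaries are
#' mirrored so that positive offsets always point into the block and negative
#' offsets outside.  Positions beyond a chromosome contribute nothing.
#'
#' @param track a `binned_track`.
#' @param boundaries boundary `GRanges` with `side` metadata
#'   (from [derive_boundaries()]).
#' @param span half-width of the profile in bases (default 20000).
#' @param spec the [boundary_spec()] used to build the boundaries (locates
#'   the block edge inside each region).
#' @return object of class `metaprofile`: data.frame `offsets` (bases,
#'   negative = outside), `mean`, `n`.
#' @export
metaprofile <- function(track, boundaries, span = 20000L,
                        spec = boundary_spec()) {
  if (is.null(boundaries$side)) stopf("boundaries need 'side' metadata")
  bw <- track$bin_width
  offs <- seq(-span, span, by = bw)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  ch <- as.character(GenomeInfoDb::seqnames(boundaries))
  s0 <- GenomicRanges::start(boundaries) - 1L
  e0 <- GenomicRanges::end(boundaries)
  for (i in seq_along(boundaries)) {
    v <- track$values[[ch[i]]]
    if (is.null(v)) next
    left <- boundaries$side[i] == "left"
    anchor <- if (left) s0[i] + spec$flank_outside else e0[i] - spec$flank_outside
    pos <- if (left) anchor + offs else anchor - offs - bw
    k <- pos %/% bw
    ok <- k >= 0 & k < length(v)
    val <- rep(NA_real_, length(offs))
    val[ok] <- v[k[ok] + 1L]
    use <- !is.na(val)
    acc[use] <- acc[use] + val[use]
    cnt[use] <- cnt[use] + 1L
  }
  structure(data.frame(offset = offs, mean = ifelse(cnt > 0, acc / cnt, NA),
                       n = cnt),
            class = c("metaprofile", "data.frame"))
}

#' Compare mean signal between two region sets
#'
#' Per-region means compared by a two-sided Wilcoxon rank-sum test (exact for
#' small untied samples, normal approximation with tie/continuity correction
#' otherwise).
#'
#' @param track a `binned_track`.
#' @param set_a,set_b `GRanges` (each with at least 2 regions).
#' @return list: `mean_a`, `mean_b`, `p_value`, `statistic` (Mann-Whitney U
#'   for set_a), `n_a`, `n_b`.
#' @export
compare_sets <- function(track, set_a, set_b) {
  if (length(set_a) < 2L || length(set_b) < 2L)
    stopf("need at least 2 regions per set")
  a <- region_mean(track, set_a)
  b <- region_mean(track, set_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1   # fully tied samples carry no evidence
  list(mean_a = mean(a), mean_b = mean(b), p_value = p,
       statistic = unname(wt$statistic), n_a = length(a), n_b = length(b))
}

#' Fraction of regions containing at least one site
#' @param regions,sites `GRanges`.
#' @return fraction in [0, 1].
#' @export
site_frequency <- function(regions, sites) {
  if (!length(regions)) return(NA_real_)
  mean(GenomicRanges::countOverlaps(regions, sites, ignore.strand = TRUE) > 0)
}

#' Stratify boundary signal by CTCF co-occurrence
#'
#' Splits boundaries by whether they overlap a CTCF site and compares the
#' mean normalized signal between the strata.
#'
#' @param track a `binned_track` (normalized signal).
#' @param boundaries boundary `GRanges`.
#' @param ctcf `GRanges` of CTCF sites.
#' @return list: `freq_with` (fraction of boundaries with a site),
#'   `mean_with`, `mean_without`, `p_value`, `skipped` (TRUE when a stratum
#'   is too small to compare).
#' @export
ctcf_stratify <- function(track, boundaries, ctcf) {
  has <- GenomicRanges::countOverlaps(boundaries, ctcf,
                                      ignore.strand = TRUE) > 0
  freq <- mean(has)
  if (sum(has) < 2L || sum(!has) < 2L)
    return(list(freq_with = freq, mean_with = NA_real_,
                mean_without = NA_real_, p_value = NA_real_, skipped = TRUE))
  cmp <- compare_sets(track, boundaries[has], boundaries[!has])
  list(freq_with = freq, mean_with = cmp$mean_a, mean_without = cmp$mean_b,
       p_value = cmp$p_value, skipped = FALSE)
}

#' Read a fixed-bin bedGraph-like track
#' @param path bedGraph file (chrom, start, end, value; fixed-width bins).
#' @param bin_width expected bin width.
#' @param chrom_sizes named chromosome lengths (fixes vector lengths; bins
#'   absent from the file become `NA`).
#' @return a `binned_track`.
#' @export
read_track <- function(path, bin_width = 20L, chrom_sizes) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(names(chrom_sizes), function(c) {
    n <- ceiling(chrom_sizes[[c]] / bin_width)
    v <- rep(NA_real_, n)
    g <- gr[as.character(GenomeInfoDb::seqnames(gr)) == c]
    if (length(g)) {
      k <- (GenomicRanges::start(g) - 1L) %/% bin_width
      v[k + 1L] <- g$score
    }
    v
  })
  binned_track(stats::setNames(vals, names(chrom_sizes)), bin_width)
}

#' Write a binned track as bedGraph
#' @param track a `binned_track`.
#' @param path output path.  `NA` bins are omitted.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  bw <- track$bin_width
  parts <- lapply(names(track$values), function(c) {
    v <- track$values[[c]]
    k <- which(!is.na(v)) - 1L
    data.frame(chrom = c, start0 = k * bw, score = v[k + 1L])
  })
  df <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start0 + 1L, df$start0 + bw),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
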