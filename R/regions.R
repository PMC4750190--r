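# Region model: boundary derivation around block edges, control sampling,
# promoter windows, GC matching, and TSS exclusion.
#
# A "region set" is a GRanges; classifier inputs are fixed-length (6 kb by
# default: 5 kb outside the block plus 1 kb inside, the inside kilobase
# absorbing imprecision in the mapped block edge).

#' Boundary geometry specification
#'
#' @param flank_outside bases outside the block edge (default 5000).
#' @param flank_inside bases inside the block edge (default 1000).
#' @return list with the two flanks and their sum `length`.
#' @export
boundary_spec <- function(flank_outside = 5000L, flank_inside = 1000L) {
  stopifnot(flank_outside > 0, flank_inside > 0)
  list(flank_outside = as.integer(flank_outside),
       flank_inside = as.integer(flank_inside),
       length = as.integer(flank_outside + flank_inside))
}

check_no_overlap <- function(gr, what = "blocks") {
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits)) {
    i <- S4Vectors::queryHits(hits)[1]
    j <- S4Vectors::subjectHits(hits)[1]
    stopf("%s overlap: [%s:%d-%d) and [%s:%d-%d)", what,
          as.character(GenomeInfoDb::seqnames(gr))[i],
          GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
          as.character(GenomeInfoDb::seqnames(gr))[j],
          GenomicRanges::start(gr)[j] - 1L, GenomicRanges::end(gr)[j])
  }
  invisible(gr)
}

chrom_sizes_of <- function(gr, chrom_sizes = NULL) {
  cs <- chrom_sizes %||% GenomeInfoDb::seqlengths(gr)
  if (is.null(cs) || any(is.na(cs)))
    stopf("chromosome sizes required (seqlengths or chrom_sizes argument)")
  cs
}

#' Derive fixed-length boundary regions from blocks
#'
#' Each block contributes two boundary regions: the left one spans
#' `flank_outside` bases before the block start plus `flank_inside` bases into
#' the block, and symmetrically on the right.  Regions that would run past a
#' chromosome end are dropped (not truncated) so that every boundary has the
#' same length.
#'
#' @param blocks `GRanges` of non-overlapping blocks.
#' @param spec a [boundary_spec()].
#' @param chrom_sizes named vector of chromosome lengths; defaults to the
#'   `seqlengths` of `blocks`.
#' @return `GRanges` with metadata `block_id`, `side` ("left"/"right"),
#'   `label = "boundary"`.  Attribute `n_clipped` counts dropped regions;
#'   attribute `short_blocks` lists blocks whose two inside flanks overlap.
#' @export
derive_boundaries <- function(blocks, spec = boundary_spec(), chrom_sizes = NULL) {
  check_no_overlap(blocks)
  cs <- chrom_sizes_of(blocks, chrom_sizes)
  ch <- as.character(GenomeInfoDb::seqnames(blocks))
  bs0 <- GenomicRanges::start(blocks) - 1L     # 0-based block start
  be0 <- GenomicRanges::end(blocks)            # 0-based half-open block end
  ids <- blocks$block_id %||% seq_along(blocks)
  left <- data.frame(chrom = ch, start = bs0 - spec$flank_outside,
                     end = bs0 + spec$flank_inside, block_id = ids, side = "left")
  right <- data.frame(chrom = ch, start = be0 - spec$flank_inside,
                      end = be0 + spec$flank_outside, block_id = ids, side = "right")
  both <- rbind(left, right)
  ok <- both$start >= 0 & both$end <= unname(cs[both$chrom])
  out <- gr_from_bed0(both$chrom[ok], both$start[ok], both$end[ok],
                      chrom_sizes = cs,
                      block_id = both$block_id[ok], side = both$side[ok],
                      label = "boundary")
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  attr(out, "n_clipped") <- sum(!ok)
  attr(out, "short_blocks") <- ids[GenomicRanges::width(blocks) < 2L * spec$flank_inside]
  out
}

#' Sample non-overlapping control regions inside or outside blocks
#'
#' Controls are placed in the eligible space (block interiors or the
#' inter-block complement) after subtracting all boundary regions, so the
#' three region classes never overlap.  Placement draws a start uniformly from
#' the currently available positions and removes the occupied span before the
#' next draw, which is deterministic under `seed`.
#'
#' @param blocks `GRanges` of blocks.
#' @param boundaries boundary `GRanges` from [derive_boundaries()].
#' @param kind `"inside"` or `"outside"`.
#' @param n number of regions to sample.
#' @param length region length in bases (default 6000).
#' @param seed RNG seed.
#' @param chrom_sizes named chromosome lengths.
#' @return `GRanges` of `n` regions, `label = kind`.
#' @export
sample_controls <- function(blocks, boundaries, kind = c("inside", "outside"),
                            n, length = 6000L, seed = 1L, chrom_sizes = NULL) {
  kind <- match.arg(kind)
  cs <- chrom_sizes_of(blocks, chrom_sizes)
  genome_gr <- gr_from_bed0(names(cs), rep(0L, length(cs)), unname(cs),
                            chrom_sizes = cs)
  base <- if (kind == "inside") GenomicRanges::reduce(blocks, ignore.strand = TRUE)
          else GenomicRanges::setdiff(genome_gr, blocks, ignore.strand = TRUE)
  elig <- GenomicRanges::setdiff(base, boundaries, ignore.strand = TRUE)
  seg_ch <- as.character(GenomeInfoDb::seqnames(elig))
  seg_s <- GenomicRanges::start(elig)
  seg_e <- GenomicRanges::end(elig)
  picked <- matrix(0L, nrow = n, ncol = 2)  # start (1-based), row index into seg
  picked_ch <- character(n)
  got <- 0L
  with_seed(seed, {
    repeat {
      avail <- pmax(seg_e - seg_s + 1L - length + 1L, 0L)
      tot <- sum(as.numeric(avail))
      if (got >= n || tot == 0) break
      k <- sample.int(length(avail), 1L, prob = avail)
      st <- seg_s[k] + sample.int(avail[k], 1L) - 1L
      got <- got + 1L
      picked[got, ] <- c(st, k)
      picked_ch[got] <- seg_ch[k]
      # split segment k around the occupied span
      old_e <- seg_e[k]
      seg_e[k] <- st - 1L
      if (st + length <= old_e) {
        seg_ch <- c(seg_ch, seg_ch[k])
        seg_s <- c(seg_s, st + length)
        seg_e <- c(seg_e, old_e)
      }
    }
  })
  if (got < n)
    stopf("could not place %d %s control regions; achieved %d", n, kind, got)
  gr <- gr_from_bed0(picked_ch, picked[, 1] - 1L, picked[, 1] - 1L + length,
                     chrom_sizes = cs, label = kind)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Strand-aware promoter windows around TSS
#'
#' The promoter of a TSS at coordinate p (0-based) spans `[p - up, p + down)`
#' on the plus strand and the mirrored `[p - down, p + up)` on the minus
#' strand.
#'
#' @param tss `GRanges` of transcription start sites with strand; the TSS
#'   coordinate is the interval start (0-based).
#' @param up bases upstream of the TSS (default 5000).
#' @param down bases downstream (default 1000).
#' @return `GRanges` of equal-length promoter windows, overlapping windows
#'   deduplicated by keeping the first in sorted order; windows running off a
#'   chromosome are dropped.
#' @export
derive_promoters <- function(tss, up = 5000L, down = 1000L) {
  str <- as.character(GenomicRanges::strand(tss))
  if (any(str == "*"))
    stopf("TSS %d has no strand; promoters are strand-aware",
          which(str == "*")[1])
  p0 <- GenomicRanges::start(tss) - 1L
  st <- ifelse(str == "+", p0 - up, p0 - down)
  en <- ifelse(str == "+", p0 + down, p0 + up)
  cs <- GenomeInfoDb::seqlengths(tss)
  ch <- as.character(GenomeInfoDb::seqnames(tss))
  ok <- st >= 0
  if (!all(is.na(cs))) ok <- ok & en <= unname(cs[ch])
  pr <- gr_from_bed0(ch[ok], st[ok], en[ok], strand = str[ok],
                     chrom_sizes = if (all(is.na(cs))) NULL else cs)
  pr <- GenomicRanges::sort(pr, ignore.strand = TRUE)
  keep <- rep(TRUE, length(pr))
  last_end <- -Inf; last_ch <- ""
  s1 <- GenomicRanges::start(pr); e1 <- GenomicRanges::end(pr)
  chs <- as.character(GenomeInfoDb::seqnames(pr))
  for (i in seq_along(pr)) {
    if (chs[i] == last_ch && s1[i] <= last_end) { keep[i] <- FALSE; next }
    last_end <- e1[i]; last_ch <- chs[i]
  }
  pr <- pr[keep]
  pr$label <- "promoter"
  pr
}

#' Extract region sequences from a genome
#' @param regions `GRanges`.
#' @param genome named `DNAStringSet`.
#' @return `DNAStringSet`, one sequence per region (plus strand).
#' @export
region_seqs <- function(regions, genome) {
  out <- vector("list", length(regions))
  ch <- as.character(GenomeInfoDb::seqnames(regions))
  st <- GenomicRanges::start(regions); en <- GenomicRanges::end(regions)
  for (c in unique(ch)) {
    if (!c %in% names(genome)) stopf("chromosome '%s' absent from genome", c)
    i <- which(ch == c)
    if (any(st[i] < 1) || any(en[i] > length(genome[[c]])))
      stopf("region outside chromosome '%s'", c)
    ss <- Biostrings::extractAt(genome[[c]], IRanges::IRanges(st[i], en[i]))
    out[i] <- as.list(ss)
  }
  Biostrings::DNAStringSet(out)
}

gc_fraction <- function(regions, genome) {
  seqs <- region_seqs(regions, genome)
  as.numeric(Biostrings::letterFrequency(seqs, "GC")) / Biostrings::width(seqs)
}

#' GC-matched subsampling of candidate regions
#'
#' Bins case and candidate regions by GC fraction and samples, per bin, as
#' many candidates as there are cases (without replacement).  Bins where the
#' candidates run short are reported, not fatal.
#'
#' @param cases,candidates `GRanges`.
#' @param genome named `DNAStringSet`.
#' @param bin_width GC-fraction bin width (default 0.02).
#' @param seed RNG seed.
#' @return selected candidate `GRanges`; attribute `shortfall` is a data.frame
#'   (bin, needed, available, selected) for bins that ran short.
#' @export
gc_match <- function(cases, candidates, genome, bin_width = 0.02, seed = 1L) {
  gc_case <- gc_fraction(cases, genome)
  gc_cand <- gc_fraction(candidates, genome)
  bin <- function(x) pmin(floor(x / bin_width), floor(1 / bin_width) - 1L)
  bc <- bin(gc_case); bk <- bin(gc_cand)
  need <- table(bc)
  sel <- integer(0)
  short <- list()
  with_seed(seed, {
    for (b in names(need)) {
      avail <- which(bk == as.integer(b))
      take <- min(need[[b]], length(avail))
      if (take > 0)
        sel <- c(sel, avail[sample.int(length(avail), take)])
      if (take < need[[b]])
        short[[b]] <- data.frame(bin = as.integer(b), needed = need[[b]],
                                 available = length(avail), selected = take)
    }
  })
  out <- GenomicRanges::sort(candidates[sel], ignore.strand = TRUE)
  attr(out, "shortfall") <- if (length(short)) do.call(rbind, short)
    else data.frame(bin = integer(), needed = integer(),
                    available = integer(), selected = integer())
  out
}

#' Remove regions that contain a TSS
#'
#' A region is removed if any TSS base falls within it (half-open: a TSS at
#' the region end is outside).
#'
#' @param regions `GRanges`.
#' @param tss `GRanges` of TSS (the TSS coordinate is the interval
#'   start, as in [derive_promoters()]).
#' @return filtered `GRanges`; attribute `n_removed` counts removals.
#' @export
exclude_tss_overlaps <- function(regions, tss) {
  pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss),
                                IRanges::IRanges(GenomicRanges::start(tss),
                                                 width = 1L))
  drop <- GenomicRanges::countOverlaps(regions, pts, ignore.strand = TRUE) > 0
  out <- regions[!drop]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Read a BED file (0-based half-open) into a GRanges
#' @param path BED file with 3-6 columns.
#' @param chrom_sizes optional named lengths.
#' @return `GRanges`; BED name column, if present, becomes metadata `name`.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
  }
  gr
}

#' Write a GRanges to a BED file (0-based half-open)
#' @param gr `GRanges`; metadata `name` used for the BED name column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  if (!is.null(gr$name)) out$name <- as.character(gr$name)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path whitespace-delimited file: chrom, length.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}
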