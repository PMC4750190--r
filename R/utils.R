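# Internal helpers: coordinate conventions, seed substreams, small checks.
#
# All user-facing coordinates are 0-based half-open (BED convention); the
# in-memory currency is a GRanges (1-based closed), converted at the edges
# by gr_from_bed0() / bed0_from_gr().

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand optional strand vector ("+", "-", "*").
#' @param chrom_sizes optional named vector of chromosome lengths (bases);
#'   attached as `seqlengths`.
#' @param ... metadata columns.
#' @return A `GRanges`.
#' @export
gr_from_bed0 <- function(chrom, start, end, strand = "*", chrom_sizes = NULL, ...) {
  if (any(start < 0L)) stop("negative start coordinate")
  if (any(end <= start)) stop("empty or inverted interval (end <= start)")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L, end = end),
                               strand = strand, ...)
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
  }
  gr
}

#' Convert a GRanges back to a 0-based half-open data frame
#' @param gr A `GRanges`.
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   strand, plus any metadata columns.
#' @export
bed0_from_gr <- function(gr) {
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) out <- cbind(out, md)
  rownames(out) <- NULL
  out
}

# Deterministic per-component seeds derived from one run seed.  Streams are
# fixed small integers, one per independent draw; the affine map keeps the
# result a valid 32-bit seed.
substream_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) + 7919 * stream) %% 2147483647
}

# Evaluate expr with a local RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
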