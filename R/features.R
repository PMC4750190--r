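# Motif-count feature construction: one count column per PWM plus the
# CpG-island overlap fraction, over fixed-length regions.

#' Scan a motif library over regions
#'
#' @param regions equal-length `GRanges`.
#' @param library list of [pwm()] objects.
#' @param genome named `DNAStringSet`.
#' @param p_threshold hit-calling p-value threshold (default 1e-4).
#' @param background optional base frequencies overriding each PWM's own.
#' @return data.frame of hits: `region_id`, `motif_id`, `offset` (0-based
#'   within the region), `strand`, `score`, `p_value`, plus the region's
#'   `side` metadata when present.
#' @export
scan_regions <- function(regions, library, genome, p_threshold = 1e-4,
                         background = NULL) {
  seqs <- region_seqs(regions, genome)
  enc <- lapply(as.character(seqs), encode_dna)
  ids <- region_ids(regions)
  side <- regions$side %||% rep(NA_character_, length(regions))
  out <- list()
  for (m in library) {
    prep <- scan_prepare(m, p_threshold, background)
    for (i in seq_along(enc)) {
      h <- scan_with(prep, enc[[i]])
      if (nrow(h)) {
        h$region_id <- ids[i]
        h$side <- side[i]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), region_id = character(),
                      side = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

region_ids <- function(regions) {
  if (!is.null(regions$id)) return(as.character(regions$id))
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(regions)),
          GenomicRanges::start(regions) - 1L, GenomicRanges::end(regions))
}

#' Build the motif-count + CpG-fraction feature matrix
#'
#' Every region becomes a row with one non-negative count per motif (hits on
#' both strands; overlapping hits all counted) and a final `cpg_fraction`
#' column: the fraction of the region covered by CpG islands.
#'
#' @param regions equal-length `GRanges`; metadata `label` becomes the class.
#' @param library list of [pwm()] objects.
#' @param cpg `GRanges` of CpG islands.
#' @param genome named `DNAStringSet`.
#' @param p_threshold hit-calling threshold (default 1e-4).
#' @param background optional scanning background frequencies.
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   |library| + 1 columns), `labels` (factor), `region_ids`, `motif_ids`.
#' @export
build_features <- function(regions, library, cpg, genome, p_threshold = 1e-4,
                           background = NULL) {
  w <- GenomicRanges::width(regions)
  if (length(unique(w)) != 1L)
    stopf("regions must all have the same length (got %d distinct lengths)",
          length(unique(w)))
  seqs <- region_seqs(regions, genome)
  enc <- lapply(as.character(seqs), encode_dna)
  motif_ids <- vapply(library, function(m) m$id, character(1))
  counts <- matrix(0L, nrow = length(regions), ncol = length(library),
                   dimnames = list(NULL, motif_ids))
  # concatenate regions with N separators wider than any motif, so each
  # motif-strand needs a single scan; cross-region windows hit an N and drop
  L <- unique(w)
  sep <- 50L
  if (length(library) && max(vapply(library, pwm_width, integer(1))) > sep)
    stopf("motifs wider than %d b are not supported by build_features", sep)
  stride <- L + sep
  cat_idx <- unlist(lapply(enc, function(e) c(e, rep(NA_integer_, sep))),
                    use.names = FALSE)
  for (k in seq_along(library)) {
    prep <- scan_prepare(library[[k]], p_threshold, background)
    for (str in c("fwd", "rev")) {
      side <- prep[[str]]
      s_int <- window_scores(cat_idx, side$int)
      hit <- which(!is.na(s_int) & s_int >= side$thr)
      if (length(hit))
        counts[, k] <- counts[, k] +
          tabulate((hit - 1L) %/% stride + 1L, nbins = length(regions))
    }
  }
  cpg_frac <- region_overlap_fraction(regions, cpg)
  x <- cbind(counts, cpg_fraction = cpg_frac)
  labels <- regions$label %||% rep(NA_character_, length(regions))
  structure(list(x = x, labels = factor(labels),
                 region_ids = region_ids(regions), motif_ids = motif_ids),
            class = "feature_matrix")
}

# Fraction of each region covered by any interval in `set`.
region_overlap_fraction <- function(regions, set) {
  red <- GenomicRanges::reduce(set, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(regions, red, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(regions[S4Vectors::queryHits(hits)],
                                  red[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  covered <- numeric(length(regions))
  if (length(hits)) {
    agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / GenomicRanges::width(regions)
}

#' Combine feature matrices from several region classes
#' @param ... `feature_matrix` objects over the same motif library.
#' @return one `feature_matrix` with rows stacked.
#' @export
rbind_features <- function(...) {
  fms <- list(...)
  ids <- fms[[1]]$motif_ids
  for (f in fms)
    if (!identical(f$motif_ids, ids)) stopf("feature matrices differ in motifs")
  structure(list(x = do.call(rbind, lapply(fms, `[[`, "x")),
                 labels = factor(unlist(lapply(fms, function(f) as.character(f$labels)))),
                 region_ids = unlist(lapply(fms, `[[`, "region_ids")),
                 motif_ids = ids),
            class = "feature_matrix")
}

#' Write a feature matrix as TSV
#' @param fm `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(region_id = fm$region_ids, class = as.character(fm$labels),
                   fm$x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
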