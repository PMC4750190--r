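# Positional bias of motif occurrences across the fixed-length boundary
# region: hits binned into 100-bp windows (right-side boundaries mirrored so
# that the outside -> inside direction is consistent), and an extreme-window
# Z-score per motif.

#' Positional profile of motif hits across regions
#'
#' Hits are assigned to the window containing their start offset; hits from
#' right-side boundary regions are mirrored so that window 0 is always the
#' outside-most end and the block edge sits at `edge_offset`.
#'
#' @param hits data.frame from [scan_regions()] (columns `motif_id`,
#'   `offset`, `side`).
#' @param regions the profiled `GRanges` (equal length, divisible by
#'   `window`).
#' @param motif_id motif to profile; required when `hits` covers several.
#' @param window window width in bases (default 100).
#' @param edge_offset distance of the block edge from the outside end of the
#'   region (default 5000, i.e. the outside flank).
#' @return object of class `positional_profile`: `motif_id`,
#'   `window_counts` (summed over regions), `n_regions`, `window`,
#'   `edge_window`, plus Z-score fields from [profile_z()].
#' @export
positional_profile <- function(hits, regions, motif_id = NULL, window = 100L,
                               edge_offset = 5000L) {
  L <- unique(GenomicRanges::width(regions))
  if (length(L) != 1L) stopf("regions must be equal-length")
  if (L %% window != 0L)
    stopf("region length %d not divisible by window %d", L, window)
  n_win <- L %/% window
  if (is.null(motif_id)) {
    motif_id <- unique(hits$motif_id)
    if (length(motif_id) > 1L)
      stopf("hits cover %d motifs; give motif_id", length(motif_id))
  }
  h <- hits[hits$motif_id %in% motif_id, , drop = FALSE]
  win <- h$offset %/% window
  mirr <- !is.na(h$side) & h$side == "right"
  win[mirr] <- n_win - 1L - win[mirr]
  counts <- tabulate(win + 1L, nbins = n_win)
  prof <- structure(list(motif_id = motif_id, window_counts = counts,
                         n_regions = length(regions), window = window,
                         edge_window = as.integer(edge_offset %/% window)),
                    class = "positional_profile")
  profile_z(prof)
}

#' Extreme-window Z-score of a positional profile
#'
#' The most extreme window is the one whose count deviates most from the mean
#' across windows (ties broken toward the window nearest the block edge);
#' z = |extreme - mean| / sd with the population standard deviation.  A flat
#' profile (sd = 0) reports z = 0 with `sd_zero = TRUE`.
#'
#' @param profile a `positional_profile`.
#' @return the profile with `z_score`, `extreme_window_index` (0-based),
#'   `extreme_offset` (bases from the outside end) and `sd_zero` filled in.
#' @export
profile_z <- function(profile) {
  x <- profile$window_counts
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  dev <- abs(x - mu)
  if (sd_pop == 0) {
    profile$z_score <- 0
    profile$sd_zero <- TRUE
    profile$extreme_window_index <- profile$edge_window
  } else {
    cand <- which(dev == max(dev))
    pick <- cand[which.min(abs(cand - 1L - profile$edge_window))]
    profile$z_score <- dev[pick] / sd_pop
    profile$sd_zero <- FALSE
    profile$extreme_window_index <- pick - 1L
  }
  profile$extreme_offset <- profile$extreme_window_index * profile$window
  profile
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("positional profile %s: %d windows x %d b, z=%.2f extreme @ %d b%s\n",
              x$motif_id, length(x$window_counts), x$window, x$z_score,
              x$extreme_offset, if (x$sd_zero) " (flat)" else ""))
  invisible(x)
}

#' Positional profiles for many motifs
#' @inheritParams positional_profile
#' @param motif_ids motifs to profile (default: all in `hits`).
#' @return named list of `positional_profile` objects.
#' @export
positional_profiles <- function(hits, regions, motif_ids = NULL,
                                window = 100L, edge_offset = 5000L) {
  motif_ids <- motif_ids %||% unique(hits$motif_id)
  stats::setNames(lapply(motif_ids, function(m)
    positional_profile(hits, regions, m, window, edge_offset)), motif_ids)
}

#' Write positional profiles as TSV
#' @param profiles list from [positional_profiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  n_win <- length(profiles[[1]]$window_counts)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(motif = p$motif_id, t(p$window_counts), z = p$z_score,
               extreme_offset = p$extreme_offset)))
  names(df)[2:(n_win + 1)] <- sprintf("w%03d", seq_len(n_win) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
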