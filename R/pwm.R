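# Position weight matrices, exact-null log-odds scanning, and MEME-format I/O.
#
# Scoring follows the usual log-odds convention: for a window w of the same
# width as the motif, score(w) = sum_i log2( p(base_i, i) / bg(base_i) ) in
# bits.  P-values are exact under an i.i.d. background: per-column score
# distributions (discretized to 1/1000 bit) are convolved by dynamic
# programming, so the null distribution of the total score is known in closed
# form and a hit is any window whose p-value falls at or below the threshold.

PWM_SCALE <- 1000           # discretization: integer score units per bit
DNA_LEVELS <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param id motif identifier.
#' @param mat numeric matrix, 4 rows (A, C, G, T) by motif width; columns are
#'   (possibly unnormalized) base probabilities.
#' @param background base frequencies of the scanning null model, length 4.
#' @param pseudocount probability mass added to every cell before
#'   renormalization; keeps log-odds finite for zero entries.
#' @return An object of class `pwm` with elements `id`, `mat` (normalized),
#'   `background`, `pseudocount`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4), pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stopf("PWM '%s': matrix must have 4 rows (A,C,G,T)", id)
  if (ncol(mat) < 2L) stopf("PWM '%s': width must be >= 2", id)
  if (any(mat < 0)) stopf("PWM '%s': negative probabilities", id)
  if (length(background) != 4L || any(background <= 0))
    stopf("PWM '%s': background must be 4 positive frequencies", id)
  background <- background / sum(background)
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- DNA_LEVELS
  structure(list(id = id, mat = mat, background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s  width=%d\n", x$id, ncol(x$mat)))
  print(round(x$mat, 3))
  invisible(x)
}

pwm_width <- function(p) ncol(p$mat)

# Reverse complement of a probability matrix (A<->T, C<->G, columns reversed).
revcomp_mat <- function(mat) mat[4:1, rev(seq_len(ncol(mat))), drop = FALSE]

# Exact null distribution of the discretized score: survival function over
# integer scores, by convolution of per-column distributions.
score_survival <- function(int_mat, background) {
  lo <- 0
  p <- 1
  for (j in seq_len(ncol(int_mat))) {
    col <- int_mat[, j]
    nlo <- lo + min(col)
    nhi <- lo + length(p) - 1L + max(col)
    np <- numeric(nhi - nlo + 1L)
    for (b in 1:4) {
      sh <- lo + col[b] - nlo
      idx <- (sh + 1L):(sh + length(p))
      np[idx] <- np[idx] + p * background[b]
    }
    p <- np
    lo <- nlo
  }
  list(min = lo, sf = rev(cumsum(rev(p))))
}

sf_pvalue <- function(dist, s_int) {
  k <- s_int - dist$min + 1
  k <- pmin(k, length(dist$sf))
  out <- ifelse(k < 1, 1, dist$sf[pmax(k, 1L)])
  pmin(out, 1)
}

# Precompute everything scanning needs for one PWM: real and integer log-odds
# matrices for both strands, null survival functions, and the integer score
# threshold equivalent to the p-value threshold.
scan_prepare <- function(p, p_threshold = 1e-4, background = NULL) {
  stopifnot(inherits(p, "pwm"))
  bg <- background %||% p$background
  bg <- bg / sum(bg)
  per_strand <- function(mat) {
    lod <- log2(sweep(mat, 1, bg, "/"))
    int <- round(lod * PWM_SCALE)
    dist <- score_survival(int, bg)
    ok <- which(dist$sf <= p_threshold)
    thr <- if (length(ok)) dist$min + ok[1] - 1L else Inf
    list(lod = lod, int = int, dist = dist, thr = thr)
  }
  list(id = p$id, width = pwm_width(p), p_threshold = p_threshold,
       fwd = per_strand(p$mat), rev = per_strand(revcomp_mat(p$mat)))
}

# Encode a sequence as indices into A,C,G,T; N (or other IUPAC) -> NA.
encode_dna <- function(sequence) {
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, DNA_LEVELS)
  bad <- which(is.na(idx) & chars != "N")
  if (length(bad))
    stopf("non-ACGTN character '%s' at position %d", chars[bad[1]], bad[1])
  idx
}

# Sliding-window score: one vector pass per motif column.  NA (from N) in any
# window position propagates to an NA window score.
window_scores <- function(seq_idx, M) {
  .window_scores_cpp(as.integer(seq_idx), M)
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands and reports windows whose exact null
#' p-value is at or below `p_threshold`.  Windows containing N are skipped.
#'
#' @param p a [pwm()].
#' @param sequence character string or `DNAString` over A,C,G,T,N.
#' @param p_threshold hit-calling p-value threshold (default 1e-4, the usual
#'   FIMO default).
#' @param background optional base frequencies overriding the PWM's own.
#' @return data.frame with columns `motif_id`, `offset` (0-based window start),
#'   `strand`, `score` (bits), `p_value`, sorted by offset.
#' @export
scan_pwm <- function(p, sequence, p_threshold = 1e-4, background = NULL) {
  prep <- scan_prepare(p, p_threshold, background)
  scan_with(prep, encode_dna(sequence))
}

# Core scan on an encoded sequence given a prepared PWM.  count_only skips
# building the hit data frame.
scan_with <- function(prep, seq_idx, count_only = FALSE) {
  res <- list()
  for (str in c("+", "-")) {
    side <- if (str == "+") prep$fwd else prep$rev
    s_int <- window_scores(seq_idx, side$int)
    hit <- which(!is.na(s_int) & s_int >= side$thr)
    if (count_only) {
      res[[str]] <- length(hit)
    } else if (length(hit)) {
      s_real <- window_scores(seq_idx, side$lod)
      res[[str]] <- data.frame(motif_id = prep$id, offset = hit - 1L,
                               strand = str, score = s_real[hit],
                               p_value = sf_pvalue(side$dist, s_int[hit]),
                               stringsAsFactors = FALSE)
    }
  }
  if (count_only) return(sum(unlist(res)))
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a motif library to a MEME-format file
#' @param motifs list of [pwm()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m$mat)), con)
    writeLines(apply(t(m$mat), 1, function(r) sprintf(" %.10f %.10f %.10f %.10f",
                                                      r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME-format motif file
#' @param path MEME file (version 4 minimal format).
#' @return list of [pwm()] objects; matrices are taken as-is (pseudocount 0).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF ", lines)
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    id <- strsplit(lines[starts[k]], "\\s+")[[1]][2]
    hdr <- starts[k] + 1L
    while (!grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1L
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    motifs[[k]] <- pwm(id, t(mat), background = bg, pseudocount = 0)
  }
  motifs
}
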