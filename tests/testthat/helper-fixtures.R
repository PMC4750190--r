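# Shared fixtures (memoized per test run) and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default planted bundle: the study conditions at desk scale.
default_bundle <- function() memo("bundle", simulate_bundle(sim_config(seed = 42)))

bundle_regions <- function() memo("regions", {
  b <- default_bundle()
  bd <- derive_boundaries(b$blocks, boundary_spec(), b$chrom_sizes)
  ins <- sample_controls(b$blocks, bd, "inside", 60, seed = 101,
                         chrom_sizes = b$chrom_sizes)
  out <- sample_controls(b$blocks, bd, "outside", 60, seed = 102,
                         chrom_sizes = b$chrom_sizes)
  list(boundaries = bd, inside = ins, outside = out)
})

bundle_features <- function() memo("features", {
  b <- default_bundle(); r <- bundle_regions()
  list(boundary = build_features(r$boundaries, b$motif_library,
                                 b$cpg_islands, b$genome),
       inside = build_features(r$inside, b$motif_library,
                               b$cpg_islands, b$genome),
       outside = build_features(r$outside, b$motif_library,
                                b$cpg_islands, b$genome))
})

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_genome <- function(len = 10000, seed = 7, chroms = "chr1") {
  g <- Biostrings::DNAStringSet(vapply(seq_along(chroms), function(i)
    random_dna(len, seed + i), character(1)))
  names(g) <- chroms
  g
}

# ---- independent oracles -------------------------------------------------

# Enumerate all 4^w words: exact null p-values and per-window scores, with
# a word-index lookup so long fixtures stay fast.
bf_scan <- function(p, sequence, p_threshold) {
  w <- ncol(p$mat)
  bg <- p$background
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  word_p <- apply(words, 1, function(x) prod(bg[x]))
  tab_for <- function(mat) {
    scores <- apply(words, 1, function(x)
      sum(log2(mat[cbind(x, seq_len(w))] / bg[x])))
    ints <- apply(words, 1, function(x)
      sum(round(log2(mat[cbind(x, seq_len(w))] / bg[x]) * 1000)))
    pv <- vapply(ints, function(i) sum(word_p[ints >= i]), numeric(1))
    list(score = scores, p = pv)
  }
  rc <- p$mat[4:1, w:1, drop = FALSE]
  tf <- tab_for(p$mat); tr <- tab_for(rc)
  s <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  n <- length(s) - w + 1
  # base-4 word index per window (NA when the window touches an N)
  idx <- numeric(n)
  for (j in seq_len(w)) idx <- idx + (s[j:(j + n - 1)] - 1) * 4^(j - 1)
  idx <- idx + 1
  out <- NULL
  for (str in c("+", "-")) {
    tabs <- if (str == "+") tf else tr
    ok <- which(!is.na(idx) & tabs$p[idx] <= p_threshold)
    if (length(ok))
      out <- rbind(out, data.frame(offset = ok - 1L, strand = str,
                                   score = tabs$score[idx[ok]],
                                   p_value = tabs$p[idx[ok]]))
  }
  out
}

# Two-sided Fisher p by hypergeometric enumeration (sum of tables with
# probability <= observed, fixed margins).
bf_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + c          # first-row total (presence)
  c1 <- a + b          # first-column total (cases)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- function(k) lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  probs <- exp(vapply(ks, logp, numeric(1)))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
bf_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Double-loop intra-block Hi-C strength.
bf_strength <- function(bins, mat) {
  s <- 0
  for (i in seq_along(bins))
    for (j in seq_along(bins))
      if (i < j) s <- s + mat[bins[i], bins[j]]
  s / length(bins)
}
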