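# End-to-end orchestration: region construction, GC-matched controls,
# features, the three pairwise classifications, enrichment and positional
# analyses, ChIP metaprofiles, CTCF stratification, and the Hi-C/TAD stage,
# driven by one seed and summarized in a reproducible manifest.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic inputs (a run on
#'   user-supplied data passes a prebuilt bundle to [run_all()] instead).
#' @param seed run seed; defaults to the simulation seed.
#' @param n_controls control regions per class (default 60).
#' @param p_threshold motif-scan p-value threshold.
#' @param or_hi,or_lo odds-ratio call thresholds.
#' @param k_list top-k cutoffs for the CME sweep.
#' @param k_select top-k cutoff for discriminating-motif selection.
#' @param outdir optional output directory; stage outputs and checksums are
#'   written there when given.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), seed = sim$seed, n_controls = 60L,
                       p_threshold = 1e-4, or_hi = 2, or_lo = 0.5,
                       k_list = c(20, 25, 40, 50), k_select = 20L,
                       outdir = NULL) {
  structure(list(sim = sim, seed = as.integer(seed),
                 n_controls = as.integer(n_controls),
                 p_threshold = p_threshold, or_hi = or_hi, or_lo = or_lo,
                 k_list = k_list, k_select = as.integer(k_select),
                 outdir = outdir),
            class = "run_config")
}

#' Synthetic TF-partner interaction map
#'
#' Wires motifs to partner genes and defines a CME gene set such that a
#' chosen subset of motifs (typically the planted boundary-enriched ones) is
#' preferentially connected to CMEs.
#'
#' @param motif_ids all motif ids (gene namespace = motif namespace).
#' @param favored motif ids to wire preferentially.
#' @param p_favored,p_background probability of a CME link for favored /
#'   other motifs.
#' @param n_cme number of CME genes.
#' @param seed RNG seed.
#' @return an [interaction_map()].
#' @export
simulate_interaction_map <- function(motif_ids, favored = character(0),
                                     p_favored = 0.8, p_background = 0.2,
                                     n_cme = 20L, seed = 1L) {
  cme <- sprintf("CME%03d", seq_len(n_cme))
  other <- sprintf("OTH%03d", seq_len(n_cme))
  with_seed(seed, {
    rows <- lapply(motif_ids, function(m) {
      p <- if (m %in% favored) p_favored else p_background
      partner <- if (stats::runif(1) < p) sample(cme, 1) else sample(other, 1)
      data.frame(tf_gene = m, partner_gene = partner)
    })
    interaction_map(do.call(rbind, rows), cme)
  })
}

#' Validate a bundle of pipeline inputs
#'
#' Checks coordinate sanity and cross-file agreement; returns errors (fatal)
#' and warnings (stages that will be skipped) rather than stopping.
#'
#' @param bundle a `synthetic_bundle` or the list returned by
#'   [read_bundle()].
#' @return list with `errors`, `warnings`, `ok`.
#' @export
validate_bundle <- function(bundle) {
  errors <- character(0); warnings <- character(0)
  cs <- bundle$chrom_sizes
  check_gr <- function(gr, what) {
    if (is.null(gr) || !length(gr)) return(invisible())
    ch <- as.character(GenomeInfoDb::seqnames(gr))
    miss <- setdiff(unique(ch), names(cs))
    if (length(miss))
      errors <<- c(errors, sprintf("%s: chromosome '%s' absent from genome",
                                   what, miss[1]))
    over <- GenomicRanges::end(gr) > unname(cs[ch])
    over[is.na(over)] <- FALSE
    if (any(over))
      errors <<- c(errors, sprintf("%s: interval %d beyond chromosome end",
                                   what, which(over)[1]))
  }
  if (!setequal(names(bundle$genome), names(cs)))
    errors <- c(errors, "genome and chrom.sizes disagree on chromosomes")
  check_gr(bundle$blocks, "blocks")
  check_gr(bundle$tss, "tss")
  check_gr(bundle$cpg_islands, "cpg_islands")
  check_gr(bundle$tads, "tads")
  check_gr(bundle$ctcf_sites, "ctcf_sites")
  if (is.null(bundle$ctcf_sites) || !length(bundle$ctcf_sites))
    warnings <- c(warnings, "no CTCF sites; CTCF stage will be skipped")
  if (is.null(bundle$tads) || !length(bundle$tads))
    warnings <- c(warnings, "no TADs; TAD-proximity stage will be skipped")
  list(errors = errors, warnings = warnings, ok = length(errors) == 0)
}

#' Run the full boundary-characterization pipeline
#'
#' @param config a [run_config()].
#' @param bundle optional prebuilt input bundle; simulated from
#'   `config$sim` when `NULL`.
#' @return a `run_manifest`: config snapshot, per-stage counts, classifier
#'   reports, enrichment and CME tables, positional Z-scores, signal and
#'   chromatin-structure statistics, and (when `outdir` is set) output-file
#'   checksums.
#' @export
run_all <- function(config = run_config(), bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- "simulate"
  manifest <- list(config = unclass(config)[setdiff(names(config), "outdir")],
                   package_version = as.character(utils::packageVersion("hmboundary")))
  res <- try({
    if (is.null(bundle)) bundle <- simulate_bundle(config$sim)
    v <- validate_bundle(bundle)
    if (!v$ok) stopf("validation failed: %s", v$errors[1])
    manifest$validation_warnings <- v$warnings
    genome <- bundle$genome; cs <- bundle$chrom_sizes

    stage <- "regions"
    boundaries <- derive_boundaries(bundle$blocks, boundary_spec(), cs)
    boundaries$id <- sprintf("b%03d_%s", boundaries$block_id, boundaries$side)
    if (length(bundle$tss))
      boundaries_noTSS <- exclude_tss_overlaps(boundaries, bundle$tss)
    else boundaries_noTSS <- boundaries
    inside <- sample_controls(bundle$blocks, boundaries, "inside",
                              config$n_controls, 6000L,
                              seed = substream_seed(seed, 21), cs)
    outside <- sample_controls(bundle$blocks, boundaries, "outside",
                               config$n_controls, 6000L,
                               seed = substream_seed(seed, 22), cs)
    promoters <- if (length(bundle$tss)) derive_promoters(bundle$tss) else NULL
    if (!is.null(promoters)) {
      keep <- GenomicRanges::countOverlaps(promoters, boundaries,
                                           ignore.strand = TRUE) == 0
      promoters <- promoters[keep]
    }
    controls <- list(inside = inside, outside = outside)
    if (!is.null(promoters) && length(promoters) >= 10) {
      controls$promoter <- promoters
    }
    controls <- lapply(controls, function(g)
      gc_match(boundaries, g, genome, seed = substream_seed(seed, 23)))
    manifest$regions <- c(list(n_blocks = length(bundle$blocks),
                               n_boundaries = length(boundaries),
                               n_boundaries_no_tss = length(boundaries_noTSS)),
                          lapply(controls, length))

    stage <- "features"
    fm_case <- build_features(boundaries, bundle$motif_library,
                              bundle$cpg_islands, genome, config$p_threshold)
    fm_ctrl <- lapply(controls, function(g)
      build_features(g, bundle$motif_library, bundle$cpg_islands, genome,
                     config$p_threshold))
    manifest$features <- list(n_columns = ncol(fm_case$x),
                              n_rows = nrow(fm_case$x) +
                                sum(vapply(fm_ctrl, function(f) nrow(f$x), 0)))

    stage <- "classify"
    reports <- list(); ranks <- list(); enrich <- list(); selected <- list()
    for (ctl in names(fm_ctrl)) {
      fm <- rbind_features(fm_case, fm_ctrl[[ctl]])
      rep <- train_evaluate(fm, split_spec(seed = substream_seed(seed, 30)),
                            forest_spec())
      reports[[ctl]] <- rep
      ranks[[ctl]] <- rank_importances(rep, length(rep$importance))
      et <- enrichment_table(fm_case, fm_ctrl[[ctl]],
                             or_hi = config$or_hi, or_lo = config$or_lo)
      enrich[[ctl]] <- et
      sel <- select_discriminating(
        ranks[[ctl]][ranks[[ctl]] %in% fm_case$motif_ids], et, config$k_select)
      selected[[ctl]] <- as.character(sel)
    }
    manifest$classify <- lapply(reports, function(r)
      list(sensitivity = r$sensitivity, specificity = r$specificity,
           f_measure = r$f_measure, auc = r$auc, m = r$m))
    manifest$selected_motifs <- selected

    stage <- "positional"
    prof_motifs <- unique(c(selected$inside, selected$outside))
    if (length(prof_motifs)) {
      hits <- scan_regions(boundaries,
                           bundle$motif_library[vapply(bundle$motif_library,
                             `[[`, character(1), "id") %in% prof_motifs],
                           genome, config$p_threshold)
      profs <- positional_profiles(hits, boundaries, prof_motifs)
      manifest$positional <- lapply(profs, function(p)
        list(z = p$z_score, extreme_offset = p$extreme_offset))
    }

    stage <- "cme"
    imap <- simulate_interaction_map(fm_case$motif_ids,
                                     favored = bundle$truth$planted_motifs,
                                     seed = substream_seed(seed, 40))
    manifest$cme <- lapply(ranks, function(r)
      cme_sweep(r[r %in% fm_case$motif_ids], imap, fm_case$motif_ids,
                ks = config$k_list))

    stage <- "signal"
    mark <- names(bundle$chip_tracks)[1]
    norm <- normalize_track(bundle$chip_tracks[[mark]]$treatment,
                            bundle$chip_tracks[[mark]]$input)
    mp <- metaprofile(norm, boundaries)
    cmpo <- compare_sets(norm, boundaries, controls$outside)
    manifest$signal <- list(
      mark = mark,
      metaprofile_peak_offset = mp$offset[which.max(mp$mean)],
      boundary_mean = cmpo$mean_a, outside_mean = cmpo$mean_b,
      boundary_vs_outside_p = cmpo$p_value)
    if (length(bundle$ctcf_sites)) {
      strat <- ctcf_stratify(norm, boundaries, bundle$ctcf_sites)
      manifest$ctcf <- list(
        freq_boundary = strat$freq_with,
        freq_inside = site_frequency(controls$inside, bundle$ctcf_sites),
        freq_outside = site_frequency(controls$outside, bundle$ctcf_sites),
        mean_with = strat$mean_with, mean_without = strat$mean_without,
        p_value = strat$p_value)
    }

    stage <- "chromatin3d"
    sb <- c(); sr <- c(); d_obs <- c(); d_ctl <- c()
    for (c in names(bundle$hic)) {
      bl_c <- bundle$blocks[as.character(GenomeInfoDb::seqnames(bundle$blocks)) == c]
      if (length(bl_c) < 2) next
      sv <- try(strength_vs_random(bl_c, bundle$hic[[c]],
                                   seed = substream_seed(seed, 50)), silent = TRUE)
      if (!inherits(sv, "try-error")) {
        sb <- c(sb, sv$strength_blocks); sr <- c(sr, sv$strength_random)
      }
      tads_c <- bundle$tads[as.character(GenomeInfoDb::seqnames(bundle$tads)) == c]
      if (length(tads_c)) {
        tp <- tad_proximity(tads_c, bl_c, cs[[c]],
                            seed = substream_seed(seed, 51))
        d_obs <- c(d_obs, tp$distances); d_ctl <- c(d_ctl, tp$control_distances)
      }
    }
    manifest$hic <- if (length(sb) >= 2 && length(sr) >= 2)
      list(mean_blocks = mean(sb), mean_random = mean(sr),
           p_value = suppressWarnings(stats::wilcox.test(sb, sr)$p.value),
           n_blocks_used = length(sb))
    else list(skipped = TRUE)
    manifest$tad <- if (length(d_obs))
      list(median_obs = stats::median(d_obs),
           median_control = stats::median(d_ctl),
           mean_obs = mean(d_obs), mean_control = mean(d_ctl),
           p_value = suppressWarnings(stats::wilcox.test(d_obs, d_ctl)$p.value))
    else list(skipped = TRUE)

    stage <- "write"
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      write_bed(boundaries, file.path(config$outdir, "boundaries.bed"))
      write_features(rbind_features(fm_case, fm_ctrl[[1]]),
                     file.path(config$outdir, "features.tsv"))
      for (ctl in names(enrich))
        utils::write.table(enrich[[ctl]],
                           file.path(config$outdir,
                                     sprintf("enrichment_%s.tsv", ctl)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      outs <- list.files(config$outdir, full.names = TRUE)
      manifest$checksums <- stats::setNames(
        unname(tools::md5sum(outs)), basename(outs))
    }
    manifest
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stopf("pipeline aborted at stage '%s': %s", stage,
          attr(res, "condition")$message)
  structure(res, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline manifest\n")
  cat(sprintf("  blocks %d -> boundaries %d\n",
              x$regions$n_blocks, x$regions$n_boundaries))
  for (ctl in names(x$classify))
    cat(sprintf("  boundary vs %-9s AUC %.3f F %.3f\n", ctl,
                x$classify[[ctl]]$auc, x$classify[[ctl]]$f_measure))
  if (!is.null(x$hic$p_value))
    cat(sprintf("  Hi-C intra-block lift p = %.3g\n", x$hic$p_value))
  if (!is.null(x$tad$p_value))
    cat(sprintf("  TAD proximity p = %.3g\n", x$tad$p_value))
  invisible(x)
}
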