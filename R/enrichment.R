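# Fisher's exact tests: per-motif presence in boundaries vs a control class,
# and chromatin-modification-enzyme (CME) enrichment among the top
# discriminating motifs and their interaction partners.

#' Two-by-two contingency result
#'
#' @param a,b cases with / without the property.
#' @param c,d controls with / without the property.
#' @param or_hi,or_lo odds-ratio thresholds for calling enrichment/depletion
#'   (defaults 2 and 0.5).
#' @return list of class `contingency_result`: counts, sample odds ratio
#'   `ad/bc` (Haldane 0.5 correction when any cell is zero, with
#'   `haldane = TRUE` flag), two-sided Fisher `p_value`, and `call` in
#'   `{enriched, depleted, neutral}`.
#' @export
contingency <- function(a, b, c, d, or_hi = 2, or_lo = 0.5) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  haldane <- any(c(a, b, c, d) == 0)
  k <- if (haldane) 0.5 else 0
  odds_ratio <- ((a + k) * (d + k)) / ((b + k) * (c + k))
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  call <- if (odds_ratio > or_hi) "enriched"
          else if (odds_ratio < or_lo) "depleted" else "neutral"
  structure(list(a = a, b = b, c = c, d = d, odds_ratio = odds_ratio,
                 p_value = p, call = call, haldane = haldane),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 [%d %d / %d %d]  OR=%.3g%s  p=%.3g  %s\n", x$a, x$c, x$b,
              x$d, x$odds_ratio, if (x$haldane) " (Haldane)" else "",
              x$p_value, x$call))
  invisible(x)
}

motif_presence <- function(features, motif_id) {
  if (!motif_id %in% colnames(features$x)) stopf("unknown motif '%s'", motif_id)
  features$x[, motif_id] >= 1
}

#' Motif enrichment in cases vs controls
#'
#' Presence = at least one hit in the region.  `a` = cases with the motif,
#' `b` = cases without, `c`/`d` the same over controls; the call uses the
#' sample odds ratio thresholds (enriched above `or_hi`, depleted below
#' `or_lo`).
#'
#' @param features_case,features_control `feature_matrix` objects.
#' @param motif_id motif column to test.
#' @param or_hi,or_lo call thresholds (defaults 2, 0.5).
#' @return a [contingency()] result.
#' @export
motif_enrichment <- function(features_case, features_control, motif_id,
                             or_hi = 2, or_lo = 0.5) {
  if (!nrow(features_case$x) || !nrow(features_control$x))
    stopf("empty region set")
  pc <- motif_presence(features_case, motif_id)
  pk <- motif_presence(features_control, motif_id)
  contingency(sum(pc), sum(!pc), sum(pk), sum(!pk), or_hi, or_lo)
}

#' Enrichment table for a whole motif library
#' @inheritParams motif_enrichment
#' @param motif_ids motifs to test; default all count columns.
#' @return data.frame (motif, a, b, c, d, odds_ratio, p_value, p_adjust_bh,
#'   call).  BH-adjusted p-values are reported for transparency; calls use
#'   the odds-ratio thresholds only.
#' @export
enrichment_table <- function(features_case, features_control,
                             motif_ids = features_case$motif_ids,
                             or_hi = 2, or_lo = 0.5) {
  rows <- lapply(motif_ids, function(m) {
    r <- motif_enrichment(features_case, features_control, m, or_hi, or_lo)
    data.frame(motif = m, a = r$a, b = r$b, c = r$c, d = r$d,
               odds_ratio = r$odds_ratio, p_value = r$p_value, call = r$call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust_bh <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Filter top-ranked motifs to those enriched in the boundaries
#'
#' @param importance_rank motif ids ordered by importance (from
#'   [rank_importances()]).
#' @param enrichments data.frame from [enrichment_table()] covering every
#'   ranked motif.
#' @param k how many top motifs to consider.
#' @return character vector of enriched motifs among the top k; attribute
#'   `n_discarded` counts those dropped.
#' @export
select_discriminating <- function(importance_rank, enrichments, k) {
  top <- importance_rank[seq_len(min(k, length(importance_rank)))]
  miss <- setdiff(top, enrichments$motif)
  if (length(miss)) stopf("no enrichment computed for motif '%s'", miss[1])
  call <- enrichments$call[match(top, enrichments$motif)]
  out <- top[call == "enriched"]
  attr(out, "n_discarded") <- sum(call != "enriched")
  out
}

#' Interaction map between TFs and partner genes, with a CME gene set
#' @param map data.frame or two-column matrix (tf_gene, partner_gene).
#' @param cme_genes character vector of chromatin-modification-enzyme genes.
#' @return list of class `interaction_map`.
#' @export
interaction_map <- function(map, cme_genes) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  names(map)[1:2] <- c("tf_gene", "partner_gene")
  structure(list(partners = split(map$partner_gene, map$tf_gene),
                 cme = unique(as.character(cme_genes))),
            class = "interaction_map")
}

# TRUE when the gene is itself a CME or interacts with at least one CME.
cme_linked <- function(genes, imap) {
  vapply(genes, function(g)
    g %in% imap$cme || any(imap$partners[[g]] %in% imap$cme), logical(1))
}

#' CME enrichment among selected motifs
#'
#' Tests whether selected (top-discriminating) motifs are linked to chromatin
#' modification enzymes — being one or interacting with one — more often than
#' the remaining background motifs, by two-sided Fisher's exact test.
#'
#' @param selected character vector of selected motif ids.
#' @param interactions an [interaction_map()].
#' @param background all motif ids under consideration.
#' @param motif_to_gene named character vector mapping motif id to gene id;
#'   identity when `NULL`.  Motifs with no mapping are excluded (counted in
#'   attribute `n_unmapped`).
#' @return a [contingency()] result.
#' @export
cme_enrichment <- function(selected, interactions, background,
                           motif_to_gene = NULL) {
  to_gene <- function(m) {
    if (is.null(motif_to_gene)) return(m)
    unname(motif_to_gene[m])
  }
  rest <- setdiff(background, selected)
  gs <- to_gene(selected); gr <- to_gene(rest)
  n_unmapped <- sum(is.na(gs)) + sum(is.na(gr))
  gs <- gs[!is.na(gs)]; gr <- gr[!is.na(gr)]
  ps <- cme_linked(gs, interactions)
  pr <- cme_linked(gr, interactions)
  out <- contingency(sum(ps), sum(!ps), sum(pr), sum(!pr))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' CME-enrichment sweep over top-k cutoffs
#' @param importance_rank full importance-ordered motif list.
#' @param interactions an [interaction_map()].
#' @param background all motif ids.
#' @param ks cutoffs (default 20, 25, 40, 50).
#' @param motif_to_gene optional motif-to-gene mapping.
#' @return data.frame (k, odds_ratio, p_value, a, b, c, d).
#' @export
cme_sweep <- function(importance_rank, interactions, background,
                      ks = c(20, 25, 40, 50), motif_to_gene = NULL) {
  rows <- lapply(ks, function(k) {
    sel <- importance_rank[seq_len(min(k, length(importance_rank)))]
    r <- cme_enrichment(sel, interactions, background, motif_to_gene)
    data.frame(k = k, odds_ratio = r$odds_ratio, p_value = r$p_value,
               a = r$a, b = r$b, c = r$c, d = r$d)
  })
  do.call(rbind, rows)
}
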