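fake_features <- function(presence, motif = "M1") {
  x <- matrix(as.integer(presence), ncol = 1, dimnames = list(NULL, motif))
  structure(list(x = cbind(x, cpg_fraction = numeric(length(presence))),
                 labels = factor(rep("r", length(presence))),
                 region_ids = as.character(seq_along(presence)),
                 motif_ids = motif),
            class = "feature_matrix")
}

test_that("odds-ratio arithmetic and calls follow the 2 / 0.5 rule", {
  r <- contingency(8, 2, 2, 8)
  expect_equal(r$odds_ratio, 16)
  expect_equal(r$call, "enriched")
  r2 <- contingency(5, 5, 5, 5)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$call, "neutral")
  r3 <- contingency(2, 8, 8, 2)
  expect_equal(r3$odds_ratio, 1 / 16)
  expect_equal(r3$call, "depleted")
  # zero cells get the Haldane correction and a flag
  r4 <- contingency(10, 0, 0, 10)
  expect_true(r4$haldane)
  expect_true(is.finite(r4$odds_ratio))
})

test_that("two-sided Fisher p equals hypergeometric enumeration for all tables n <= 40", {
  # exhaustive over all tables with n = a+b+c+d <= 14
  for (n in 4:14)
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(contingency(a, b, c, d)$p_value, bf_fisher_p(a, b, c, d),
                   tolerance = 1e-9)
    }
  # random tables up to n = 40
  set.seed(13)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(15:40, 1), rep(0.25, 4)))
    expect_equal(do.call(contingency, as.list(cells))$p_value,
                 do.call(bf_fisher_p, as.list(cells)), tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under joint row+column swap; OR inverts under column swap", {
  set.seed(14)
  for (i in 1:20) {
    cl <- as.list(1 + as.vector(stats::rmultinom(1, 30, rep(0.25, 4))))
    r <- do.call(contingency, cl)
    swapped <- contingency(cl[[4]], cl[[3]], cl[[2]], cl[[1]])  # both axes
    expect_equal(r$p_value, swapped$p_value, tolerance = 1e-12)
    expect_equal(r$odds_ratio, swapped$odds_ratio, tolerance = 1e-12)
    colswap <- contingency(cl[[3]], cl[[4]], cl[[1]], cl[[2]])
    expect_equal(colswap$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
  }
})

test_that("motif enrichment counts presence (count >= 1) and p matches the 10+10 oracle", {
  case <- fake_features(c(3, 1, 2, 1, 1, 1, 0, 1, 2, 1))   # 9 present
  ctrl <- fake_features(c(0, 0, 1, 0, 0, 2, 0, 0, 0, 0))   # 2 present
  r <- motif_enrichment(case, ctrl, "M1")
  expect_equal(c(r$a, r$b, r$c, r$d), c(9, 1, 2, 8))
  expect_equal(r$p_value, bf_fisher_p(9, 1, 2, 8), tolerance = 1e-12)
  expect_error(motif_enrichment(fake_features(integer(0)), ctrl, "M1"),
               "empty")
})

test_that("discriminating-motif selection filters top-k to enriched calls", {
  enr <- data.frame(motif = paste0("M", 1:6),
                    call = c("enriched", "neutral", "enriched", "depleted",
                             "enriched", "neutral"))
  rank <- paste0("M", c(5, 2, 1, 4, 3, 6))
  sel <- select_discriminating(rank, enr, 4)
  expect_equal(as.character(sel), c("M5", "M1"))
  expect_equal(attr(sel, "n_discarded"), 2L)
  all_neutral <- transform(enr, call = "neutral")
  expect_length(select_discriminating(rank, all_neutral, 4), 0L)
  all_enr <- transform(enr, call = "enriched")
  expect_equal(as.character(select_discriminating(rank, all_enr, 4)), rank[1:4])
})

test_that("planted boundary motifs are recovered as enriched discriminators", {
  b <- default_bundle()
  f <- bundle_features()
  fm <- rbind_features(f$boundary, f$inside)
  rep <- train_evaluate(fm, split_spec(seed = 5))
  rk <- rank_importances(rep, length(rep$importance))
  rk <- rk[rk %in% f$boundary$motif_ids]
  et <- enrichment_table(f$boundary, f$inside)
  planted <- b$truth$planted_motifs
  sel <- select_discriminating(rk, et, 2 * length(planted))
  expect_gte(mean(planted %in% sel), 0.8)
})

test_that("CME enrichment is neutral under matched composition and flagged when degenerate", {
  imap <- interaction_map(
    data.frame(tf = sprintf("M%02d", 1:40),
               partner = rep(c("CME1", "X1"), 20)),
    cme_genes = "CME1")
  # selected set has the same CME-linkage composition as the background
  sel <- sprintf("M%02d", 1:10)
  r <- cme_enrichment(sel, imap, sprintf("M%02d", 1:40))
  expect_lt(abs(log(r$odds_ratio)), log(2))
  expect_gt(r$p_value, 0.5)
  # all selected linked, no background linked -> degenerate, Haldane-flagged
  imap2 <- interaction_map(
    data.frame(tf = sprintf("M%02d", 1:40),
               partner = c(rep("CME1", 10), rep("X1", 30))),
    cme_genes = "CME1")
  r2 <- cme_enrichment(sprintf("M%02d", 1:10), imap2, sprintf("M%02d", 1:40))
  expect_true(r2$haldane)
  expect_true(is.finite(r2$odds_ratio))
  expect_gt(r2$odds_ratio, 100)
})

test_that("CME odds ratio rises monotonically with wiring strength", {
  ids <- sprintf("M%03d", 1:200)
  favored <- ids[1:40]
  ors <- vapply(c(0.3, 0.55, 0.8), function(p) {
    imap <- simulate_interaction_map(ids, favored, p_favored = p,
                                     p_background = 0.2, seed = 77)
    cme_enrichment(favored, imap, ids)$odds_ratio
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
  expect_gt(ors[3], 1)
})

test_that("the k-sweep emits one row per cutoff with finite statistics", {
  ids <- sprintf("M%03d", 1:60)
  imap <- simulate_interaction_map(ids, ids[1:15], seed = 3)
  sw <- cme_sweep(ids, imap, ids, ks = c(20, 25, 40, 50))
  expect_equal(sw$k, c(20, 25, 40, 50))
  expect_true(all(is.finite(sw$odds_ratio)))
  expect_true(all(sw$p_value >= 0 & sw$p_value <= 1))
})
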