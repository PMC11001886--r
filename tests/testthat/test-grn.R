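make_metric_inputs <- function() {
  set.seed(20)
  n_mc <- 40
  pc2 <- seq(-20, 20, length.out = n_mc)
  pc1 <- rnorm(n_mc, 0, 2)
  agg_expr <- rbind(TFa = -pc2 / 10 + rnorm(n_mc, 0, 0.2),
                    TFb = rnorm(n_mc, 1, 0.5))
  agg_dev <- rbind(TFa = -pc2 / 10 + rnorm(n_mc, 0, 0.2),
                   TFb = rnorm(n_mc, 0, 1))
  groups <- rep(c("H", "LP", "M"), each = 10)
  bulk <- matrix(rnorm(60, 1, 0.05), 2, 30,
                 dimnames = list(c("TFa", "TFb"), sprintf("b%02d", 1:30)))
  bulk["TFa", groups == "H"] <- bulk["TFa", groups == "H"] + 4
  list(bulk = bulk, groups = groups, agg_expr = agg_expr, agg_dev = agg_dev,
       pc1 = pc1, pc2 = pc2)
}

test_that("TF metrics combine bulk contrast with oriented-axis correlations", {
  fx <- make_metric_inputs()
  expect_warning(
    tm <- tf_metric_table(c("TFa", "TFb", "TFmissing"), fx$bulk, fx$groups,
                          fx$agg_expr, fx$agg_dev, fx$pc1, fx$pc2),
    "absent")
  row <- tm[tm$tf == "TFa" & tm$state == "scH", ]
  # bulk log fold-change is the difference of log-scale group means
  expect_equal(row$bulk_lfc,
               mean(fx$bulk["TFa", fx$groups == "H"]) -
                 mean(fx$bulk["TFa", fx$groups != "H"]))
  # scH follows -PC2: a TF tracking -PC2 correlates positively
  expect_gt(row$expr_cor, 0.8)
  expect_gt(row$dev_cor, 0.8)
  expect_lt(row$expr_q, 0.001)
  # the same TF anti-correlates with the scLP (+PC2) axis
  expect_lt(tm$expr_cor[tm$tf == "TFa" & tm$state == "scLP"], -0.8)
  expect_identical(sort(unique(tm$state)), c("scH", "scLP", "scM"))
})

test_that("a TF at percentiles 0.9/0.8/1.0 scores a composite of 0.9", {
  cs <- composite_scores(metrics_with_known_percentiles())
  row <- cs[cs$tf == "T09", ]
  expect_equal(row$pct_bulk, 0.9)
  expect_equal(row$pct_expr, 0.8)
  expect_equal(row$pct_dev, 1.0)
  expect_identical(row$composite, (0.9 + 0.8 + 1.0) / 3)
  expect_equal(row$composite, 0.9)
})

test_that("composite scores depend on metric ranks only", {
  m <- metrics_with_known_percentiles()
  cs1 <- composite_scores(m)
  m2 <- m
  m2$bulk_lfc <- exp(m2$bulk_lfc)          # strictly monotone transforms
  m2$expr_cor <- m2$expr_cor^3
  cs2 <- composite_scores(m2)
  expect_identical(cs1$tf, cs2$tf)
  expect_identical(cs1$composite, cs2$composite)
})

test_that("strict mode demands significance on all three metrics", {
  m <- metrics_with_known_percentiles()
  m$dev_q[m$tf == "T09"] <- 0.2
  strict <- composite_scores(m)
  expect_false("T09" %in% strict$tf)
  lenient <- composite_scores(m, mode = "lenient")
  expect_true("T09" %in% lenient$tf)
  m$bulk_q <- m$expr_q <- m$dev_q <- 1
  expect_warning(composite_scores(m), "no significant")
})

test_that("peaks link to nearby genes by correlated accessibility", {
  set.seed(21)
  n_mc <- 30
  x <- rnorm(n_mc)
  mc_ids <- sprintf("mc%02d", seq_len(n_mc))
  genes <- c("G1", sprintf("N%02d", 1:20))
  agg_expr <- rbind(G1 = x,
                    matrix(rnorm(20 * n_mc), 20, dimnames = list(genes[-1], NULL)))
  colnames(agg_expr) <- mc_ids
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(110000, 110500, 9000000), width = 400))
  names(peaks) <- c("Pnear", "Panti", "Pfar")
  agg_atac <- rbind(Pnear = x + rnorm(n_mc, 0, 0.1),
                    Panti = -x + rnorm(n_mc, 0, 0.1),
                    Pfar = x)
  colnames(agg_atac) <- mc_ids
  tss <- data.frame(gene = genes, chrom = "chr1",
                    tss = c(100000, 1e6 * (20 + 1:20)))
  links <- peak_to_gene_links(agg_expr, agg_atac, tss, peaks,
                              var_quantile_cutoff = 0)
  near <- links[links$peak == "Pnear" & links$gene == "G1", ]
  expect_true(near$retained)
  expect_gt(near$correlation, 0.9)
  # a peak outside the window is never a candidate
  expect_false("Pfar" %in% links$peak)
  # anti-correlated links are rejected by default, kept in signed mode
  anti <- links[links$peak == "Panti" & links$gene == "G1", ]
  expect_false(anti$retained)
  signed <- peak_to_gene_links(agg_expr, agg_atac, tss, peaks,
                               var_quantile_cutoff = 0, signed = TRUE)
  expect_true(signed$retained[signed$peak == "Panti" & signed$gene == "G1"])
})

test_that("permuting metacells leaves almost no retained links (FDR control)", {
  set.seed(22)
  n_mc <- 30
  mc_ids <- sprintf("mc%02d", seq_len(n_mc))
  genes <- sprintf("G%02d", 1:50)
  agg_expr <- matrix(rnorm(50 * n_mc), 50, dimnames = list(genes, mc_ids))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1e6 * (1:50) + 10000,
                                                   width = 400))
  names(peaks) <- sprintf("P%02d", 1:50)
  agg_atac <- matrix(rnorm(50 * n_mc), 50,
                     dimnames = list(names(peaks), mc_ids))
  tss <- data.frame(gene = genes, chrom = "chr1", tss = 1e6 * (1:50))
  links <- peak_to_gene_links(agg_expr, agg_atac, tss, peaks)
  n_cand <- nrow(links)
  expect_gt(n_cand, 0)
  bound <- 0.01 + 3 * sqrt(0.01 * 0.99 / n_cand)
  expect_lte(mean(links$retained), bound)
})

test_that("target identification shrinks monotonically with stricter cutoffs", {
  g <- hb_grn_full()
  tf <- g$sim$truth$driver_tfs$tf[1]
  base <- identify_targets(tf, g$agg_expr, g$links,
                           g$sim$truth$motif_occupancy)
  tight_cor <- identify_targets(tf, g$agg_expr, g$links,
                                g$sim$truth$motif_occupancy, cor_min = 0.7)
  tight_q <- identify_targets(tf, g$agg_expr, g$links,
                              g$sim$truth$motif_occupancy, q_max = 1e-8)
  expect_true(all(tight_cor$gene %in% base$gene))
  expect_true(all(tight_q$gene %in% base$gene))
  expect_error(identify_targets("TFnone", g$agg_expr, g$links,
                                g$sim$truth$motif_occupancy), "absent")
  occ_none <- data.frame(tf = "other", peak = "p")
  expect_error(identify_targets(tf, g$agg_expr, g$links, occ_none), "motif")
})

test_that("module clustering recovers co-regulated TF blocks", {
  set.seed(23)
  n_mc <- 40
  f1 <- rnorm(n_mc); f2 <- rnorm(n_mc)
  mk <- function(f) f + rnorm(n_mc, 0, 0.2)
  agg_expr <- rbind(A1 = mk(f1), A2 = mk(f1), B1 = mk(f2), B2 = mk(f2),
                    tA1 = mk(f1), tA2 = mk(f1), tB1 = mk(f2), tB2 = mk(f2))
  tl <- list(
    A1 = data.frame(gene = c("tA1", "tA2"), correlation = c(0.9, 0.8)),
    A2 = data.frame(gene = c("tA2", "tA1"), correlation = c(0.9, 0.8)),
    B1 = data.frame(gene = c("tB1", "tB2"), correlation = c(0.9, 0.8)),
    B2 = data.frame(gene = c("tB2", "tB1"), correlation = c(0.9, 0.8)))
  bm <- build_modules(tl, agg_expr, n_modules = 2)
  expect_identical(bm$modules[["A1"]], bm$modules[["A2"]])
  expect_identical(bm$modules[["B1"]], bm$modules[["B2"]])
  expect_false(bm$modules[["A1"]] == bm$modules[["B1"]])
  # permuting TF input order leaves the partition unchanged
  bm2 <- build_modules(tl[c("B2", "A1", "B1", "A2")], agg_expr, n_modules = 2)
  for (pair in list(c("A1", "A2"), c("B1", "B2"), c("A1", "B1"))) {
    expect_identical(bm$modules[[pair[1]]] == bm$modules[[pair[2]]],
                     bm2$modules[[pair[1]]] == bm2$modules[[pair[2]]])
  }
  expect_error(build_modules(tl, agg_expr, n_modules = 10), "exceeds")
})

test_that("TFs order along PC2 by their smoothed activation peak", {
  set.seed(24)
  pc2 <- seq(-20, 20, length.out = 60)
  prof <- rbind(early = dnorm(pc2, -15, 4),
                mid = dnorm(pc2, 0, 4),
                late = dnorm(pc2, 15, 4)) +
    matrix(rnorm(180, 0, 0.001), 3)
  prof <- rbind(prof, flatTF = rep(1, 60))
  ord <- order_tf_activation(prof, pc2)
  expect_identical(ord$tf[ord$tf != "flatTF"], c("early", "mid", "late"))
  expect_true(ord$flat[ord$tf == "flatTF"])
  expect_equal(ord$position[ord$tf == "flatTF"], 30.5)
  # mirrored profiles land at opposite ends
  expect_gt(abs(ord$position[ord$tf == "late"] -
                  ord$position[ord$tf == "early"]), 30)
})
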