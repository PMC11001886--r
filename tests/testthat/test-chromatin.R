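test_that("peak consolidation merges overlaps and drops outlier widths", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  b <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                              IRanges::IRanges(c(150, 5000, 10),
                                               c(250, 5009, 30000)))
  out <- consolidate_peaks(list(a, b))
  # 100-250 merged; the 10 bp peak and the 30 kb peak removed
  expect_equal(length(out), 1)
  expect_equal(GenomicRanges::start(out), 100)
  expect_equal(GenomicRanges::end(out), 250)
  # the width filter applies after merging: two small abutting peaks survive
  c1 <- GenomicRanges::GRanges("chr3", IRanges::IRanges(c(1, 11), c(12, 25)))
  expect_equal(length(consolidate_peaks(c1)), 1)
})

test_that("planted accessible peaks are detected with attenuated log2 folds", {
  pg <- simulate_peak_groups(n_cells_per_group = 150, n_peaks = 120,
                             n_planted = 3, fold = 4, seed = 8)
  cells <- colnames(pg$counts)
  res <- differential_peaks(pg$counts, cells[pg$groups == "A"],
                            cells[pg$groups == "B"], seed = 8)
  planted <- res[res$peak %in% pg$planted, ]
  expect_true(all(planted$significant))
  expect_true(all(planted$direction == "up"))
  # the pseudo-count attenuates a 4-fold (log2 = 2) change slightly
  expect_true(all(planted$log2_fc > 1.5 & planted$log2_fc < 2.3))
  # the significance flag is exactly the documented conjunction
  expect_identical(res$significant, abs(res$log2_fc) >= 1 & res$fdr <= 1e-3)
  # deterministic given the seed
  res2 <- differential_peaks(pg$counts, cells[pg$groups == "A"],
                             cells[pg$groups == "B"], seed = 8)
  expect_identical(res, res2)
  expect_error(differential_peaks(pg$counts, character(0), cells[1:5]),
               "empty")
})

test_that("depth normalization prevents library size from driving folds", {
  set.seed(9)
  counts <- matrix(rpois(50 * 60, 5), 50,
                   dimnames = list(sprintf("p%02d", 1:50),
                                   sprintf("c%02d", 1:60)))
  # group A counts doubled everywhere: pure depth, no composition change
  counts[, 1:30] <- counts[, 1:30] * 2
  res <- differential_peaks(counts, colnames(counts)[1:30],
                            colnames(counts)[31:60])
  expect_false(any(res$significant))
  expect_lt(max(abs(res$log2_fc)), 0.5)
})

test_that("a composition-preserving differential set has unit enrichment", {
  all_peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 201, 401, 601, 801, 1001), width = 100))
  names(all_peaks) <- paste0("p", 1:6)
  states <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 601, 201, 801, 401, 1001), width = 100))
  states$state <- rep(c("promoter", "enhancer", "quiescent"), each = 2)
  diff_peaks <- all_peaks[1:3]   # one peak per state: fractions preserved
  out <- state_enrichment(diff_peaks, all_peaks, states)
  expect_identical(out$ratio, c(1, 1, 1))
  expect_error(state_enrichment(all_peaks[0], all_peaks, states), "empty")
})

test_that("states absent from the peak universe are undefined, not zero", {
  all_peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  states <- GenomicRanges::GRanges(c("chr1", "chr2"),
                                   IRanges::IRanges(c(1, 1), c(50, 50)))
  states$state <- c("covered", "elsewhere")
  out <- state_enrichment(all_peaks, all_peaks, states)
  expect_true(is.na(out$ratio[out$state == "elsewhere"]))
  expect_equal(out$ratio[out$state == "covered"], 1)
})

test_that("motif enrichment clips occurrences and reconciles motif versions", {
  all_peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 201, 401, 601), width = 100))
  diff_peaks <- all_peaks[1:2]
  occ <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10, 410, 90, 620), width = 20))
  occ$motif <- c("TFX_v1", "TFX_v1", "TFX_v2", "TFX_v2")
  occ$tf <- "TFX"
  out <- motif_enrichment(diff_peaks, all_peaks, occ)
  # v1: 20 bp in diff of 40 total in peaks; diff holds half the nucleotides
  expect_equal(out$ratio[out$motif == "TFX_v1"],
               (20 / 200) / (40 / 400))
  # v2: first occurrence extends past the peak edge -> clipped to 11 bp
  expect_equal(out$ratio[out$motif == "TFX_v2"],
               (11 / 200) / (31 / 400))
  # v1 (ratio 1) outranks v2 (< 1): the TF reports its best version
  by_tf <- attr(out, "by_tf")
  expect_identical(by_tf$motif[by_tf$tf == "TFX"], "TFX_v1")
  expect_error(motif_enrichment(diff_peaks[0], all_peaks, occ), "empty")
})

test_that("shuffle enrichment has the +1-corrected empirical floor", {
  uni <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(seq(1, 50000, 1000), width = 200))
  names(uni) <- paste0("u", seq_along(uni))
  q <- uni[1:10]
  out <- interval_overlap_enrichment(q, q, uni, n_shuffles = 200, seed = 1)
  expect_equal(out$observed, 10)
  expect_equal(out$p_value, 1 / 201)
  disjoint <- uni[30:40]
  out2 <- interval_overlap_enrichment(q, disjoint, uni, n_shuffles = 200,
                                      seed = 1)
  expect_equal(out2$observed, 0)
  expect_gte(out2$p_value, 0.5)
  expect_warning(interval_overlap_enrichment(q, q, uni, n_shuffles = 50),
                 "coarse")
  refs <- list(self = q, other = disjoint)
  out3 <- interval_overlap_enrichment(q, refs, uni, n_shuffles = 200, seed = 1)
  expect_identical(out3$reference, c("self", "other"))
  expect_true(all(out3$q_value >= out3$p_value - 1e-12))
})

test_that("motif deviations are calibrated on homogeneous null data", {
  set.seed(10)
  counts <- matrix(rpois(200 * 300, 2), 200,
                   dimnames = list(sprintf("p%03d", 1:200),
                                   sprintf("c%03d", 1:300)))
  occ <- list(m1 = rownames(counts)[1:30],
              m2 = rownames(counts)[101:130])
  z <- motif_deviations(counts, occ, seed = 2)
  expect_identical(dim(z), c(300L, 2L))
  expect_lt(max(abs(colMeans(z))), 0.3)
  expect_true(all(apply(z, 2, sd) > 0.6 & apply(z, 2, sd) < 1.4))
  expect_error(motif_deviations(counts, list(m = "nope")), "unknown peak")
  expect_error(motif_deviations(counts, list(m = character(0))), "zero peaks")
})

test_that("footprints normalize flanks to one and resolve a central dip", {
  ins <- data.frame(chrom = "chr1", pos = 1:20000, count = 3)
  centers <- data.frame(chrom = "chr1", pos = c(5000, 10000, 15000))
  fp <- footprint_profile(ins, centers)
  # constant insertion rate: every normalized position is exactly 1
  expect_true(all(fp$normalized == 1))
  expect_equal(nrow(fp), 501)
  ins2 <- ins
  for (p in centers$pos) ins2$count[abs(ins2$pos - p) <= 10] <- 0
  fp2 <- footprint_profile(ins2, centers)
  expect_lt(fp2$smoothed[fp2$position == 0], 0.5)
  expect_gt(mean(fp2$smoothed[abs(fp2$position) > 200]), 0.9)
  expect_error(footprint_profile(ins, centers, flank = 50, flank_norm = 50),
               "flank_norm")
  expect_error(footprint_profile(ins, centers[0, ]), "motif site")
})

test_that("occupancy-derived motif sites sit at peak centers", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  names(peaks) <- "p1"
  occ <- data.frame(motif = "m1", tf = "TFX", peak = "p1")
  gr <- motif_sites_from_occupancy(occ, peaks, width = 10)
  expect_equal(GenomicRanges::start(gr), 145)   # center 150, width 10
  expect_equal(GenomicRanges::width(gr), 10)
  expect_identical(gr$tf, "TFX")
  expect_error(motif_sites_from_occupancy(data.frame(motif = "m", peak = "x"),
                                          peaks), "unknown peak")
})
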