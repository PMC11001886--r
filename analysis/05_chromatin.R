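# Chromatin accessibility: differential peaks between differentiation
# states, enrichment statistics and motif deviations.
#
# Tests scLP against scH nuclei peak by peak (Wilcoxon on depth-normalized
# counts, BH FDR, |log2FC| >= 1 and FDR <= 1e-3), checks how the
# differential set redistributes across the planted peak classes with the
# nucleotide-ratio statistic, scores per-nucleus motif deviations for the
# driver TFs, and runs the shuffle-based overlap enrichment of the
# differential set against each peak class.
# Writes results/differential_peaks.tsv, results/state_enrichment.tsv,
# results/motif_deviation_summary.tsv and results/overlap_enrichment.tsv.

source("analysis/00_common.R")

scH_cells <- tumor_cells[state == "scH"]
scLP_cells <- tumor_cells[state == "scLP"]
dp <- differential_peaks(sim$atac[, tumor_cells], scLP_cells, scH_cells)
message(sprintf("%d of %d peaks differential between scLP and scH",
                sum(dp$significant), nrow(dp)))
write_tsv(dp[dp$significant, ], "differential_peaks.tsv")

# nucleotide-ratio enrichment of the differential set across peak classes
ann <- sim$peaks
ann_states <- GRanges(seqnames(ann), ranges(ann))
ann_states$state <- sim$truth$peak_kind$kind
diff_gr <- sim$peaks[names(sim$peaks) %in% dp$peak[dp$significant]]
enr <- state_enrichment(diff_gr, sim$peaks, ann_states)
write_tsv(enr, "state_enrichment.tsv")
print(enr, row.names = FALSE)

# per-nucleus motif deviations for driver TFs, summarized per state
drivers <- sim$truth$driver_tfs
occ <- sim$truth$motif_occupancy
occ_drivers <- split(occ$peak, occ$tf)[drivers$tf]
z <- motif_deviations(sim$atac[, tumor_cells], occ_drivers, seed = 3)
dev_summary <- do.call(rbind, lapply(drivers$tf, function(tf) {
  data.frame(tf = tf, driver_state = drivers$state[drivers$tf == tf],
             mean_z_scH = mean(z[state == "scH", tf]),
             mean_z_scLP = mean(z[state == "scLP", tf]),
             mean_z_scM = mean(z[state == "scM", tf]))
}))
write_tsv(dev_summary, "motif_deviation_summary.tsv")

# shuffle-based overlap of the differential set with each peak class
refs <- lapply(split(names(sim$peaks), sim$truth$peak_kind$kind),
               function(ids) sim$peaks[ids])
ov <- interval_overlap_enrichment(diff_gr, refs, sim$peaks,
                                  n_shuffles = 1000, seed = 4)
write_tsv(ov, "overlap_enrichment.tsv")
print(ov, row.names = FALSE)
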