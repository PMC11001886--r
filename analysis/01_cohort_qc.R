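# Cohort overview and quality control.
#
# Applies the standard nuclei filters (> 1000 UMIs, > 500 detected genes,
# < 5% mitochondrial reads — all strict; the simulator emits no
# mitochondrial genes, so that filter is inert here) and tabulates the
# cohort composition. Writes results/cohort_summary.tsv and
# results/qc_report.tsv.

source("analysis/00_common.R")

qc <- qc_filter(sim$rna)
qc_report <- data.frame(
  metric = c("cells_in", "cells_out", "removed_low_umi",
             "removed_few_genes", "removed_high_mito",
             "genes_in", "genes_out"),
  value = unlist(qc$report[c("cells_in", "cells_out", "removed_umi",
                             "removed_genes_detected", "removed_mito",
                             "genes_in", "genes_out")]))
write_tsv(qc_report, "qc_report.tsv")

composition <- as.data.frame(table(sample = truth$sample,
                                   subclone = truth$subclone))
composition <- composition[composition$Freq > 0, ]
write_tsv(composition, "cohort_summary.tsv")

message(sprintf("QC kept %d of %d nuclei and %d of %d genes",
                qc$report$cells_out, qc$report$cells_in,
                qc$report$genes_out, qc$report$genes_in))
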