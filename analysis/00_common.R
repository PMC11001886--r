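# Shared setup for the analysis scripts: simulate the study cohort once and
# derive the objects every downstream step needs (normalized expression,
# oriented embedding, state labels). Sourced by the numbered scripts.
#
# The cohort layout: three tumor samples of two genetic subclones each
# (500 cells per subclone), plus 200 normal reference nuclei. Sample S1
# carries a truncal copy-neutral LOH; the last sample is mesenchymal.

suppressPackageStartupMessages({
  library(hbmultiome)
  library(Matrix)
  library(GenomicRanges)
})

# run the scripts from the repository root: Rscript analysis/01_....R
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

write_tsv <- function(df, name) {
  path <- file.path(results_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}

message("simulating cohort (seed 7) ...")
sim <- simulate_multiome(sim_config(seed = 7))
truth <- sim$truth$cells
tumor_cells <- truth$cell_id[truth$tumor]

norm <- log_normalize(sim$rna)[, tumor_cells]
mb <- sim$truth$marker_blocks
emb <- compute_embedding(norm,
                         m_score = signature_score(norm, mb$M),
                         lp_score = signature_score(norm, mb$LP))
# thresholds in per-axis SD units: the printed raw cutoffs of the original
# scale do not transfer across datasets, the +/-0.5 SD band does
state <- classify_states(emb, pc2_low = -0.5, pc2_high = 0.5, units = "sd")
names(state) <- tumor_cells
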