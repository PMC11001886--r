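# Clonal architecture: mapping nuclei to genetic subclones and contrasting
# their phenotypes.
#
# Genotypes the branch mutation sets in single nuclei (>= 1 ALT read),
# assigns each nucleus to the unique subclone branch it carries reads for,
# backs the sparse mutation evidence with virtual CNA clusters, and
# compares the differentiation (PC2), cycling, CSC and DNA-repair
# phenotypes between subclones of the same sample.
# Writes results/subclone_assignment.tsv, results/subclone_phenotypes.tsv
# and results/subclone_tests.tsv.

source("analysis/00_common.R")

det <- detect_mutations(sim$allele_counts, sim$truth$branch_mutations,
                        cell_ids = truth$cell_id)
sub_branches <- grep("[.]cl", names(sim$truth$branch_mutations), value = TRUE)

# virtual CNA profiles give every nucleus a (coarse) genetic signal; clusters
# that map cleanly onto one branch rescue nuclei without informative reads
cna <- smooth_virtual_cna(sim$rna, sim$gene_coords,
                          truth$cell_id[!truth$tumor])
cl <- cluster_cna_profiles(cna$profile[, tumor_cells],
                           k = length(sub_branches))
informative <- rowSums(det$calls[, sub_branches, drop = FALSE]) == 1
maj <- vapply(split(names(cl), cl), function(cells) {
  cells <- cells[informative[cells]]
  if (!length(cells)) return(NA_character_)
  hits <- det$calls[cells, sub_branches, drop = FALSE]
  votes <- colSums(hits)
  # only clusters dominated by one branch are trusted for the fallback
  if (max(votes) / sum(votes) >= 0.9) names(votes)[which.max(votes)]
  else NA_character_
}, "")

asg <- assign_cells_to_subclones(det$calls, sub_branches,
                                 cna_clusters = cl, cluster_to_branch = maj)
asg <- asg[asg$cell_id %in% tumor_cells, ]
write_tsv(asg, "subclone_assignment.tsv")
message(sprintf("mutation evidence: %.1f%% of tumor nuclei; after CNA fallback: %.1f%% assigned",
                100 * mean(asg$evidence == "mutation"),
                100 * mean(asg$branch %in% sub_branches)))

# phenotype contrasts between subclones
pc2 <- stats::setNames(emb$scores[, 2], tumor_cells)
cyc_genes <- union(mb$cycling[1:20], mb$cycling[21:40])
cyc_score <- signature_score(norm, cyc_genes)
set.seed(1)
cyc_cutoff <- mean(sort(stats::kmeans(cyc_score, 2, nstart = 5)$centers))
cycling <- stats::setNames(flag_cycling(norm, mb$cycling[1:20],
                                        mb$cycling[21:40],
                                        cutoff = cyc_cutoff), tumor_cells)
csc <- stats::setNames(as.vector(norm["PROM1", ] > 0 | norm["EPCAM", ] > 0),
                       tumor_cells)
dnr <- stats::setNames(signature_score(norm, mb$dna_repair), tumor_cells)

cmp <- compare_subclone_phenotypes(asg, pc2, cycling, csc, dnr)
write_tsv(cmp$summary, "subclone_phenotypes.tsv")
write_tsv(cmp$tests, "subclone_tests.tsv")
print(cmp$summary[, c("branch", "n", "pc2_median", "cycling_fraction",
                      "csc_fraction")], row.names = FALSE)
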