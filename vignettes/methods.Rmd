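---
title: "Methods: differentiation states, clonal architecture and regulatory networks from single-nucleus multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiation states, clonal architecture and regulatory networks from single-nucleus multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hbmultiome` implements a joint RNA + ATAC single-nucleus analysis of a
pediatric liver tumor cohort in which three questions are entangled:

1. **Where does each tumor nucleus sit on the differentiation landscape?**
   The tumors contain epithelial nuclei spanning a liver-progenitor (LP) to
   hepatocyte (H) continuum plus a distinct mesenchymal (M) population.
2. **Which genetic subclone does each nucleus belong to**, and do subclones
   differ in phenotype? Genetic evidence comes from three independent and
   individually sparse sources: phased germline SNPs (copy-neutral loss of
   heterozygosity), somatic point mutations captured in reads, and virtual
   copy-number profiles smoothed from expression.
3. **Which transcription factors organize the LP-to-H axis**, and through
   which peaks and target genes?

The package also ships a synthetic multiome generator with full ground
truth (states, subclones, LOH segment, planted regulons, motif occupancy),
so every stage can be validated quantitatively without patient data. The
vignette walks through the model behind each stage and the rationale for
the defaults; the `analysis/` scripts in the source repository run the
full workflow end to end.

```{r load}
library(hbmultiome)
```

# Synthetic cohort

`simulate_multiome()` draws a cohort from `sim_config()`: by default 3,200
nuclei across a reference liver sample and three tumor samples, 2,000 genes
with genomic coordinates, 1,200 ATAC peaks on two chromosomes, 20 phased
heterozygous SNPs inside an LOH segment, a two-branch subclone tree per
tumor sample, and a planted regulon (driver TFs, motif-bearing peaks,
target genes) for each of the three states. Counts are Poisson around
state- and clone-specific rates; ATAC fragment counts respond to the state
through peak classes (scH-specific, scLP-specific, scM-specific,
background). Effect sizes are study conditions fixed once in
`sim_config()`; they were not adjusted against test outcomes.

```{r simulate}
sim <- simulate_multiome(sim_config(seed = 7))
names(sim)
```

# Expression states

After `qc_filter()` (UMI, detected-gene and mitochondrial-fraction
cutoffs, strict inequalities at the boundary) and `log_normalize()`
(counts-per-10k, `log1p`), `compute_embedding()` builds a PCA on the
top-variable genes and **orients** it: PC1 is sign-fixed to correlate
positively with the mesenchymal signature and PC2 with the LP signature.
Orientation matters because classification thresholds are applied to
signed scores.

`classify_states()` assigns `scM` above a PC1 cutoff, and splits the rest
into `scH` (PC2 below the low threshold), `scLP` (above the high
threshold) and the intermediate `scH-LP` band, inclusive at both
boundaries. Two threshold conventions are supported: raw score units
(default +/-15) and SD units of the PC2 scores (+/-0.5), selected by
`units`. The PC1 cutoff defaults to the **largest gap** in the sorted PC1
scores, which is robust to the relative sizes of the epithelial and
mesenchymal compartments; a fixed cutoff can be passed instead.

Cycling nuclei are flagged by `flag_cycling()` from two phase signatures
(inclusive at the cutoff). The default cutoff of 0.15 is a contract value
on the package's score scale; an on-scale alternative (midpoint of a 1-d
2-means) is shown in the analysis scripts.

`build_metacells()` groups transcriptionally adjacent nuclei (k-means on
the embedding, seeded) and `aggregate_by_metacell()` averages any matrix
over the grouping; 100 metacells for ~3,000 nuclei keeps enough axis
resolution while lifting per-gene counts out of the dropout regime.

# Copy-neutral LOH

Heterozygous SNPs are phased against the bulk tumor B-allele frequency:
paternal is the B allele where bulk BAF > 0.65 and the A allele where
BAF < 0.35, both strict; SNPs in between are uninformative and dropped
(`phase_snps()`). `count_parental_reads()` sums paternal and maternal
reads per nucleus across the phased SNPs.

Under retained heterozygosity each read is paternal with probability 1/2,
so `call_loh()` uses the exact binomial upper tail at p = 1/2,
`binom_tail_half(k, n) = P(X >= k), X ~ Binom(n, 1/2)`, computed by
log-scale summation of the binomial mass for numerical safety. A nucleus
is called `LOH` when the tail probability is below 0.05, `normal` when
not significant **and** at least 3 maternal reads are observed (otherwise
`unknown`: absence of evidence at low coverage is not evidence of
retention). P-values are reported unadjusted — the call is a per-nucleus
classifier with a calibrated per-cell error rate, not a discovery list —
and a BH column is provided for users who want the FDR view.

The sample-level `sample_pseudo_baf()` is the pooled paternal fraction
`sum(pat) / sum(pat + mat)`; under the null it concentrates at 50%. At
the cohort's coverage (about 10 informative reads per nucleus) the
analytic detection sensitivity for a true LOH nucleus is
`1 - ppois(4, 10)` (about 97%), because `0.5^n < 0.05` exactly when
`n >= 5`.

# Somatic genotyping and subclones

`detect_mutations()` genotypes branch mutation sets per nucleus: a branch
is carried when at least one ALT read supports any of its mutations.
Mutations observed in fewer than 3 nuclei are *flagged*, not silently
dropped, and the flag-filtered call matrix is returned alongside the raw
one. `assign_cells_to_subclones()` maps each nucleus to the unique
subclone branch it has evidence for; nuclei with reads for multiple
branches are `ambiguous`, and nuclei with no informative reads can be
rescued through virtual-CNA clusters whose membership maps cleanly
(>= 90% majority in the analysis scripts) onto one branch.

`smooth_virtual_cna()` produces the CNA signal: depth-normalize, log2
ratio against the reference-cell mean per gene, per-cell centering, then
a 101-gene moving average along the genome with shrinking windows at
chromosome edges, clamped at 3 SD of the reference profiles by default.
The data-driven clamp is intentionally tight when reference profiles are
nearly noiseless; an explicit clamp can be supplied.
`cluster_cna_profiles()` clusters the smoothed profiles, and
`compare_subclone_phenotypes()` contrasts differentiation score, cycling
fraction, stem-marker fraction and a DNA-repair signature between
branches (Wilcoxon and Fisher tests, binomial CIs, tiny-branch warnings).

`assign_mutations_to_branches()` places bulk mutations on the clonal tree
from cancer-cell fractions (`ccf_from_vaf()` assuming diploid
heterozygous events): trunk at CCF >= 0.8 in all samples, a branch when
present (>= 0.3, inclusive) where expected and absent (< 0.05, strict)
elsewhere.

# Chromatin

`differential_peaks()` depth-normalizes to counts-per-10k, tests each
peak with a two-sided Wilcoxon rank-sum test, adjusts by BH, and computes
log2 fold changes with pseudo-count 1 on the mean normalized counts. The
pseudo-count attenuates fold changes (a planted 4-fold effect reports
around 1.9 at these count levels), which is why significance pairs the
fold-change threshold (|lfc| >= 1) with a stringent FDR (1e-3) rather
than relying on either alone.

Enrichment of a peak set against an annotation is measured at
**nucleotide resolution**: `state_enrichment()` compares, per annotation
class, the fraction of the query's base pairs in that class to the same
fraction in the universe. A composition-preserving query therefore has
ratio exactly 1 in every class — the identity the acceptance fixture
checks. `motif_enrichment()` applies the same ratio to motif site
intervals, clipping sites to the peak universe; when a TF has several
motif versions, the per-TF reconciliation keeps the version with the
largest ratio. `interval_overlap_enrichment()` is the complementary
shuffle test: query intervals are placed uniformly at random within the
universe, and the empirical p uses the +1 correction, so the floor with
1,000 shuffles is 1/1001.

`motif_deviations()` is a chromVAR-style statistic: for each TF, the
observed per-cell fraction of fragments in its motif-bearing peaks is
compared to 50 background peak sets matched on mean accessibility bins,
yielding a z-like deviation whose null distribution is centered near 0
with SD near 1 (verified on pure-Poisson data). `footprint_profile()`
aggregates insertion counts around motif sites, normalizes by the outer
flanks (250 bp flank, 50 bp normalization edge, 5 bp smoothing) so a
uniform insertion rate gives a flat profile at exactly 1 and protection
appears as a central dip.

# Gene regulatory network

`tf_metric_table()` scores every TF in each state on three evidence
streams: the bulk expression contrast (group-mean log fold change), the
correlation of metacell expression with the state's oriented axis (scH:
-PC2, scLP: +PC2, scM: +PC1), and the same correlation for the motif
deviation. Each metric is BH-adjusted within its state.
`composite_scores()` (strict mode) requires all three q-values <= 0.05
and averages the three within-state percentile ranks, so the composite
is scale-free: any monotone transform of a metric leaves it unchanged.

`peak_to_gene_links()` correlates metacell accessibility with metacell
expression for every peak within 250 kb of a gene, keeping positive links
with correlation > 0.4 and FDR <= 0.01 among peaks above the 0.25
variability quantile. `identify_targets()` then requires a correlated
expression profile (cor > 0.5, q <= 0.001) plus a retained link through a
motif-bearing peak — an expression-only correlate without a chromatin
path is not a target. `build_modules()` clusters TF target-overlap
profiles (Pearson distance, Ward linkage) and `order_tf_activation()`
places each TF at the smoothed argmax of its expression along the LP-H
axis, flagging flat profiles instead of ranking them spuriously.

# Variance decomposition

`pc_regression_r2()` regresses each of the first k = 5 principal
components on categorical covariates and
`weighted_variance_explained()` averages the per-component R-squared
weighted by the component variances. Singular designs are refused with
the collinear terms named, because a silently dropped column would make
nested comparisons incoherent. In cohorts where a sample coincides
exactly with a state (a mesenchymal-only sample), the joint
state + sample model is fit on the epithelial subset where both vary.

# Numerical and design notes

* All thresholds quoted above are the package defaults, chosen once; the
  analysis scripts pass them explicitly where a dataset-scale choice is
  clearer.
* Frozen constants in the test suite (e.g. `log(11)` for the normalized
  value of 10 counts at depth 10,000, `binom_tail_half(10, 10) == 2^-10`)
  are derived by hand, not read back from the implementation.
* Randomized procedures (metacells, deviations, shuffles, subsampling)
  take explicit seeds and are deterministic given them.
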