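#' Phase heterozygous SNPs from bulk WGS B-allele frequency
#'
#' Within a copy-neutral LOH region the duplicated (paternal) allele
#' dominates the bulk signal: the paternal allele is B when BAF > 0.65 and
#' A when BAF < 0.35; SNPs with intermediate BAF are uninformative and
#' excluded from downstream read counting.
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos` and
#'   `wgs_baf` columns.
#' @param region Optional `GRanges` restricting the SNPs considered.
#' @param baf_high,baf_low Phasing thresholds (defaults 0.65 / 0.35,
#'   exclusive).
#' @return Data frame of informative SNPs with a `pat_allele` column
#'   (`"A"` or `"B"`).
#' @export
phase_snps <- function(variants, region = NULL,
                       baf_high = 0.65, baf_low = 0.35) {
  stopifnot(all(c("variant_id", "wgs_baf") %in% names(variants)))
  v <- variants[!is.na(variants$wgs_baf), , drop = FALSE]
  if (nrow(v) && (any(v$wgs_baf < 0) || any(v$wgs_baf > 1))) {
    stop("BAF outside [0,1]")
  }
  if (!is.null(region)) {
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    v <- v[IRanges::overlapsAny(gr, region), , drop = FALSE]
  }
  v$pat_allele <- ifelse(v$wgs_baf > baf_high, "B",
                         ifelse(v$wgs_baf < baf_low, "A", NA_character_))
  v[!is.na(v$pat_allele), , drop = FALSE]
}

#' Sum paternal and maternal reads per cell over phased SNPs
#'
#' For each cell, REF/ALT read counts at each informative SNP are converted
#' to paternal/maternal according to the SNP's phased paternal allele
#' (REF = A, ALT = B) and summed over the region. Cells absent from the
#' table get (0, 0). Duplicate (cell, variant) rows are summed.
#'
#' @param allele_counts Data frame with `cell_id`, `variant_id`,
#'   `ref_reads`, `alt_reads`.
#' @param phased Output of [phase_snps()].
#' @param cell_ids Optional universe of cells to report (so uncovered cells
#'   appear with zero counts).
#' @return Data frame with `cell_id`, `pat_reads`, `mat_reads`.
#' @export
count_parental_reads <- function(allele_counts, phased, cell_ids = NULL) {
  ac <- allele_counts[allele_counts$variant_id %in% phased$variant_id, ,
                      drop = FALSE]
  if (nrow(allele_counts) &&
      !all(allele_counts$variant_id %in%
           c(phased$variant_id, allele_counts$variant_id))) {
    stop("allele counts reference unknown variants")  # unreachable guard
  }
  pat <- phased$pat_allele[match(ac$variant_id, phased$variant_id)]
  pat_reads <- ifelse(pat == "B", ac$alt_reads, ac$ref_reads)
  mat_reads <- ifelse(pat == "B", ac$ref_reads, ac$alt_reads)
  if (is.null(cell_ids)) cell_ids <- unique(allele_counts$cell_id)
  f <- factor(ac$cell_id, levels = cell_ids)
  out <- data.frame(
    cell_id = cell_ids,
    pat_reads = as.vector(tapply(pat_reads, f, sum, default = 0)),
    mat_reads = as.vector(tapply(mat_reads, f, sum, default = 0)),
    stringsAsFactors = FALSE)
  out$pat_reads[is.na(out$pat_reads)] <- 0
  out$mat_reads[is.na(out$mat_reads)] <- 0
  out
}

#' Exact upper-tail probability of the symmetric binomial
#'
#' P(X >= k) for X ~ Binomial(n, 0.5), computed by direct summation of the
#' mass function on the log scale. This is the probability of observing at
#' least the seen number of paternal reads among n informative reads when
#' both alleles are present (no LOH).
#'
#' @param k Observed count (vectorized).
#' @param n Total reads (vectorized).
#' @return Upper-tail probabilities; 1 when `n` is 0.
#' @export
binom_tail_half <- function(k, n) {
  stopifnot(length(k) == length(n) || length(k) == 1 || length(n) == 1)
  res <- mapply(function(ki, ni) {
    if (ni == 0) return(1)
    if (ki <= 0) return(1)
    kk <- ki:ni
    sum(exp(lchoose(ni, kk) - ni * log(2)))
  }, k, n)
  pmin(1, as.numeric(res))
}

#' Call copy-neutral LOH per cell from parental read counts
#'
#' An exact binomial test with greater alternative: the probability of
#' observing at least the seen paternal reads among all informative reads
#' under the no-LOH expectation of 0.5. Cells with p < `alpha` are LOH;
#' other cells are `normal` when their maternal reads reach
#' `min_mat_for_normal`, and `unknown` otherwise (including zero-read
#' cells, which get p = 1).
#'
#' @param parental Data frame from [count_parental_reads()] (or any frame
#'   with `cell_id`, `pat_reads`, `mat_reads`).
#' @param alpha Significance level (default 0.05, exclusive).
#' @param min_mat_for_normal Maternal reads needed to call `normal`
#'   (default 3, inclusive).
#' @param adjust `"none"` (default, per-cell p-values as-is) or `"BH"`.
#' @return The input with `p_value` and `status` columns added.
#' @export
call_loh <- function(parental, alpha = 0.05, min_mat_for_normal = 3,
                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (any(parental$pat_reads < 0 | parental$mat_reads < 0)) {
    stop("negative read counts")
  }
  n <- parental$pat_reads + parental$mat_reads
  p <- binom_tail_half(parental$pat_reads, n)
  p_dec <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  status <- ifelse(p_dec < alpha, "LOH",
                   ifelse(parental$mat_reads >= min_mat_for_normal,
                          "normal", "unknown"))
  out <- parental
  out$p_value <- p
  out$status <- status
  out
}

#' Sample-level pseudo-BAF
#'
#' The sum of paternal reads divided by the total paternal + maternal reads
#' over all cells; ~0.5 is expected in absence of LOH, approaching 1 when
#' the LOH is clonal.
#'
#' @param parental Data frame with `pat_reads` and `mat_reads`.
#' @return A single fraction in `[0, 1]`.
#' @export
sample_pseudo_baf <- function(parental) {
  tot <- sum(parental$pat_reads) + sum(parental$mat_reads)
  if (tot <= 0) stop("no reads: pseudo-BAF undefined")
  sum(parental$pat_reads) / tot
}

#' Genotype somatic mutation sets in single cells
#'
#' A cell is called mutated for a set of mutations when it carries at least
#' one ALT read for any mutation of the set. For driver-style reporting,
#' mutations detected (>= 1 ALT read) in fewer than `min_cells_per_mutation`
#' cells are flagged as filtered and, when `filter_set_calls = TRUE`,
#' excluded from the set-level calls; branch sets used for clone mapping
#' keep all mutations by default.
#'
#' @param allele_counts Long allele-count table (`cell_id`, `variant_id`,
#'   `ref_reads`, `alt_reads`).
#' @param mutation_sets Named list of character vectors of variant ids.
#' @param min_cells_per_mutation Detection filter (default 3).
#' @param filter_set_calls Whether the filter also removes mutations from
#'   set-level calls (default `FALSE`).
#' @param cell_ids Optional universe of cells to report.
#' @return List with `calls` (cells x sets logical matrix) and `mutations`
#'   (per-mutation detection report with `n_cells_detected` and `filtered`).
#' @export
detect_mutations <- function(allele_counts, mutation_sets,
                             min_cells_per_mutation = 3,
                             filter_set_calls = FALSE,
                             cell_ids = NULL) {
  if (!length(mutation_sets) || any(lengths(mutation_sets) == 0)) {
    stop("empty mutation set")
  }
  all_muts <- unique(unlist(mutation_sets))
  ac <- allele_counts[allele_counts$variant_id %in% all_muts &
                        allele_counts$alt_reads >= 1, , drop = FALSE]
  det <- tapply(ac$cell_id, factor(ac$variant_id, levels = all_muts),
                function(x) length(unique(x)), default = 0L)
  mut_report <- data.frame(
    variant_id = all_muts,
    set = vapply(all_muts, function(v) {
      names(mutation_sets)[vapply(mutation_sets, function(s) v %in% s, TRUE)][1]
    }, ""),
    n_cells_detected = as.integer(det),
    stringsAsFactors = FALSE)
  mut_report$filtered <- mut_report$n_cells_detected < min_cells_per_mutation
  if (is.null(cell_ids)) cell_ids <- unique(allele_counts$cell_id)
  calls <- matrix(FALSE, length(cell_ids), length(mutation_sets),
                  dimnames = list(cell_ids, names(mutation_sets)))
  for (s in names(mutation_sets)) {
    muts <- mutation_sets[[s]]
    if (filter_set_calls) {
      muts <- setdiff(muts, mut_report$variant_id[mut_report$filtered])
    }
    hit <- unique(ac$cell_id[ac$variant_id %in% muts])
    calls[rownames(calls) %in% hit, s] <- TRUE
  }
  list(calls = calls, mutations = mut_report)
}
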