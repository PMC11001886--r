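#' Simulation configuration for the synthetic multiome generator
#'
#' Builds a validated configuration list for [simulate_multiome()]. Defaults
#' describe a small cohort that mirrors the structure of a pediatric liver
#' tumor multiome series: several samples, each composed of genetic subclones,
#' with tumor cells spread along a continuous liver-progenitor (LP) to
#' hepatocyte (H) differentiation axis, one mesenchymal sample occupying a
#' second (M) axis, a copy-neutral LOH region with heterozygous phased SNPs,
#' branch-specific somatic mutations, state-specific accessible peaks carrying
#' TF motifs, and planted TF-to-target co-expression modules.
#'
#' @param n_samples Number of tumor samples. The last sample is mesenchymal
#'   (high M-axis); the others are epithelial and spread along the LP-H axis.
#' @param subclones_per_sample Genetic subclones per sample.
#' @param cells_per_subclone Cells simulated per subclone. May be a single
#'   value or a vector of length `n_samples * subclones_per_sample`.
#' @param n_genes Total genes (marker blocks, TFs and targets included).
#' @param n_peaks Total ATAC peaks.
#' @param n_ref_cells Normal reference cells (no CNA, hepatocyte-like) used as
#'   the reference population for virtual copy-number profiles.
#' @param state_axis_params Optional data frame with one row per subclone and
#'   columns `sample`, `subclone`, `mean_z`, `sd_z`, `mean_m`, `sd_m` giving
#'   the latent axis distributions; a default layout is built when `NULL`.
#' @param marker_block_sizes Named vector of genes per signature block
#'   (`H`, `LP`, `M`, `epi`, `cycling`, `dna_repair`, `csc`).
#' @param marker_fold Peak fold-change of a marker block between its state
#'   and the opposite pole.
#' @param nb_dispersion Negative-binomial overdispersion of RNA counts
#'   (`size = 1/nb_dispersion`).
#' @param depth_lognormal_params `c(meanlog, sdlog)` of per-cell RNA library
#'   size.
#' @param atac_depth_lognormal_params Same for per-cell ATAC fragment totals.
#' @param snp_count Informative heterozygous SNPs in the LOH region.
#' @param n_uninformative_snps SNPs with ambiguous bulk BAF (excluded by
#'   phasing).
#' @param snp_coverage_mean Mean informative reads per cell over the region.
#' @param loh_error_rate Probability that a read from an LOH cell reports the
#'   lost (maternal) allele; 0 by default.
#' @param loh_samples Indices of samples whose tumor cells carry the cnLOH
#'   (truncal); defaults to sample 1.
#' @param mutation_count_per_branch Somatic mutations per tree branch.
#' @param mutation_coverage Mean covering reads per cell per mutation.
#' @param n_tfs Number of transcription factors (each with one motif).
#' @param drivers_per_state Driver TFs planted per state (H, LP, M).
#' @param targets_per_tf Planted target genes per driver TF.
#' @param tf_axis_loading,tf_private_loading Loadings of a driver TF's latent
#'   activity on the state axis and on its private factor; the private factor
#'   is what its targets share beyond the state program.
#' @param state_peaks_per_state Accessible peaks planted per state.
#' @param peak_fold Accessibility fold-change of a state peak in its state.
#' @param cna_fold Expression fold of gained copy-number segments.
#' @param cna_segment_genes Genes per planted CNA segment.
#' @param seed Integer seed; all draws flow from one generator.
#' @return A list of class `hb_sim_config`.
#' @export
sim_config <- function(n_samples = 3,
                       subclones_per_sample = 2,
                       cells_per_subclone = 500,
                       n_genes = 2000,
                       n_peaks = 1000,
                       n_ref_cells = 200,
                       state_axis_params = NULL,
                       marker_block_sizes = c(H = 40, LP = 40, M = 40, epi = 40,
                                              cycling = 40, dna_repair = 40, csc = 10),
                       marker_fold = 6,
                       nb_dispersion = 0.5,
                       depth_lognormal_params = c(meanlog = log(2000), sdlog = 0.3),
                       atac_depth_lognormal_params = c(meanlog = log(1500), sdlog = 0.3),
                       snp_count = 20,
                       n_uninformative_snps = 4,
                       snp_coverage_mean = 10,
                       loh_error_rate = 0,
                       loh_samples = 1,
                       mutation_count_per_branch = 25,
                       mutation_coverage = 0.008,
                       n_tfs = 60,
                       drivers_per_state = 4,
                       targets_per_tf = 6,
                       tf_axis_loading = 0.65,
                       tf_private_loading = 0.76,
                       state_peaks_per_state = 120,
                       peak_fold = 6,
                       cna_fold = 1.5,
                       cna_segment_genes = 150,
                       seed = 1L) {
  cfg <- as.list(environment())
  n_sub <- n_samples * subclones_per_sample
  if (length(cfg$cells_per_subclone) == 1L) {
    cfg$cells_per_subclone <- rep(cfg$cells_per_subclone, n_sub)
  }
  stopifnot(length(cfg$cells_per_subclone) == n_sub)
  counts <- c(n_samples, subclones_per_sample, n_genes, n_peaks,
              snp_count, mutation_count_per_branch, n_tfs)
  if (any(counts < 1)) stop("configuration error: all counts must be >= 1")
  if (any(cfg$cells_per_subclone < 0)) {
    stop("configuration error: cells_per_subclone must be >= 0")
  }
  if (nb_dispersion <= 0) stop("configuration error: nb_dispersion must be > 0")
  if (loh_error_rate < 0 || loh_error_rate > 1) {
    stop("configuration error: loh_error_rate must be in [0,1]")
  }
  if (is.null(state_axis_params)) {
    cfg$state_axis_params <- default_axis_params(n_samples, subclones_per_sample)
  } else {
    cfg$state_axis_params <- state_axis_params
  }
  need <- sum(marker_block_sizes) + n_tfs +
    drivers_per_state * 3 * targets_per_tf
  if (n_genes < need + 100) {
    stop("configuration error: n_genes too small for the requested blocks (need > ",
         need + 100, ")")
  }
  class(cfg) <- "hb_sim_config"
  cfg
}

# Default latent-axis layout: epithelial samples spread subclones along the
# LP-H axis; the last sample is mesenchymal.
default_axis_params <- function(n_samples, subclones_per_sample) {
  rows <- list()
  for (s in seq_len(n_samples)) {
    mesen <- (s == n_samples && n_samples > 1)
    if (subclones_per_sample == 1) {
      zmeans <- 0
    } else {
      zmeans <- seq(-1.8, 1.8, length.out = subclones_per_sample)
    }
    for (k in seq_len(subclones_per_sample)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paste0("S", s), subclone = paste0("S", s, ".cl", k),
        mean_z = if (mesen) 0 else zmeans[k],
        sd_z = 0.6,
        mean_m = if (mesen) 3 else 0,
        sd_m = if (mesen) 0.3 else 0.2)
    }
  }
  do.call(rbind, rows)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a paired single-nucleus RNA + ATAC dataset with ground truth
#'
#' Generates sparse RNA and ATAC count matrices, a peak set, phased-SNP and
#' somatic-mutation allele count tables, and a ground-truth object recording
#' each cell's sample, subclone, latent axis positions, state label, LOH
#' status and cycling status, plus the planted TF regulon (edge list), peak
#' state activities, motif occupancy, branch mutation sets and CNA segments.
#'
#' RNA counts are gamma-Poisson (negative binomial) with gene means driven by
#' the latent axis positions through marker-block loadings; ATAC counts are
#' Poisson with peak rates elevated in cells whose state matches the peak's
#' planted state; LOH cells emit paternal-only SNP reads (up to the error
#' rate), non-LOH cells emit reads as Binomial(coverage, 0.5); each somatic
#' mutation's ALT reads appear only in cells of carrying branches.
#'
#' @param config A configuration from [sim_config()].
#' @return A list of class `hb_sim` with elements `rna` (genes x cells
#'   dgCMatrix), `atac` (peaks x cells), `peaks` (`GRanges`), `gene_coords`
#'   (data frame with TSS), `variants`, `allele_counts`, `bulk` (a small bulk
#'   RNA cohort with group labels), `truth` and `config`.
#' @export
simulate_multiome <- function(config = sim_config()) {
  stopifnot(inherits(config, "hb_sim_config"))
  set.seed(config$seed)
  ax <- config$state_axis_params
  n_sub <- nrow(ax)
  ncell <- config$cells_per_subclone

  ## ---- cells and latent axes ----
  cell_sub <- rep(seq_len(n_sub), times = ncell)
  n_tumor <- length(cell_sub)
  z <- stats::rnorm(n_tumor, ax$mean_z[cell_sub], ax$sd_z[cell_sub])
  m <- stats::rnorm(n_tumor, ax$mean_m[cell_sub], ax$sd_m[cell_sub])
  n_ref <- config$n_ref_cells
  # reference nuclei: normal hepatocytes (H-like, no CNA, no LOH)
  z <- c(z, stats::rnorm(n_ref, -1.8, 0.3))
  m <- c(m, stats::rnorm(n_ref, 0, 0.2))
  n_cells <- n_tumor + n_ref
  cell_id <- sprintf("cell%05d", seq_len(n_cells))
  sample_of <- c(ax$sample[cell_sub], rep("REF", n_ref))
  subclone_of <- c(ax$subclone[cell_sub], rep("REF", n_ref))
  is_tumor <- c(rep(TRUE, n_tumor), rep(FALSE, n_ref))

  act_H <- stats::plogis(-2 * z)
  act_LP <- stats::plogis(2 * z)
  act_M <- stats::plogis(4 * (m - 1.5))
  act_epi <- 1 - act_M
  state <- ifelse(m > 1.5, "scM",
                  ifelse(z < -1, "scH", ifelse(z > 1, "scLP", "scH/LP")))
  state[!is_tumor] <- "normal"
  cycling <- stats::rbinom(n_cells, 1, 0.05 + 0.20 * act_LP) == 1
  cycling[!is_tumor] <- FALSE

  ## ---- gene catalogue ----
  mb <- config$marker_block_sizes
  gene_names <- character(0)
  block_of <- character(0)
  add_block <- function(prefix, n, block) {
    nm <- sprintf("%s%03d", prefix, seq_len(n))
    gene_names <<- c(gene_names, nm)
    block_of <<- c(block_of, rep(block, n))
    nm
  }
  g_H <- add_block("Hmk", mb[["H"]], "H")
  g_LP <- add_block("LPmk", mb[["LP"]], "LP")
  g_M <- add_block("Mmk", mb[["M"]], "M")
  g_epi <- add_block("EPI", mb[["epi"]], "epi")
  g_cyc <- add_block("CYC", mb[["cycling"]], "cycling")
  g_dnr <- add_block("DNR", mb[["dna_repair"]], "dna_repair")
  stopifnot(mb[["csc"]] >= 2)
  g_csc <- c("PROM1", "EPCAM",
             sprintf("CSC%03d", seq_len(mb[["csc"]] - 2)))
  gene_names <- c(gene_names, g_csc)
  block_of <- c(block_of, rep("csc", mb[["csc"]]))
  tf_names <- add_block("TF", config$n_tfs, "tf")
  n_drivers <- config$drivers_per_state * 3
  tg_names <- add_block("TG", n_drivers * config$targets_per_tf, "target")
  n_bg <- config$n_genes - length(gene_names)
  g_bg <- add_block("G", n_bg, "background")

  ## ---- driver TF latent activities ----
  driver_state <- rep(c("scH", "scLP", "scM"), each = config$drivers_per_state)
  drivers <- tf_names[seq_len(n_drivers)]
  s_coord <- cbind(scH = -z / 1.5, scLP = z / 1.5, scM = (m - 1.5) / 1.5)
  u <- matrix(stats::rnorm(n_cells * n_drivers), n_cells, n_drivers)
  tf_act <- config$tf_axis_loading * s_coord[, driver_state, drop = FALSE] +
    config$tf_private_loading * u
  colnames(tf_act) <- drivers
  edges <- data.frame(
    tf = rep(drivers, each = config$targets_per_tf),
    target = tg_names, stringsAsFactors = FALSE)

  ## ---- genome layout ----
  # one gene per 1 Mb slot over 4 chromosomes; gene order randomized so
  # marker blocks scatter and CNA segments are the only contiguous signals
  n_genes <- config$n_genes
  chrs <- paste0("chr", 1:4)
  per_chr <- ceiling(n_genes / 4)
  slot_chr <- rep(chrs, each = per_chr)[seq_len(n_genes)]
  slot_pos <- (rep(seq_len(per_chr), 4)[seq_len(n_genes)]) * 1e6
  ord <- sample.int(n_genes)
  gene_coords <- data.frame(
    gene = gene_names[ord], chrom = slot_chr, tss = slot_pos,
    stringsAsFactors = FALSE)
  gene_coords <- gene_coords[order(match(gene_coords$gene, gene_names)), ]
  rownames(gene_coords) <- NULL

  ## ---- CNA segments (contiguous in genome order, disjoint) ----
  genome_order <- order(match(gene_coords$chrom, chrs), gene_coords$tss)
  seg_len <- config$cna_segment_genes
  n_seg_needed <- n_sub + config$n_samples   # one per subclone + one trunk/sample
  cna_segments <- list()
  seg_start <- 1L
  for (i in seq_len(n_seg_needed)) {
    if (seg_start + seg_len - 1L > n_genes) break
    cna_segments[[i]] <- genome_order[seg_start:(seg_start + seg_len - 1L)]
    seg_start <- seg_start + seg_len + 50L
  }
  cna_mult <- matrix(1, n_genes, n_cells)
  seg_table <- list()
  si <- 0L
  for (s in unique(ax$sample)) {
    si <- si + 1L
    if (si > length(cna_segments)) break
    idx <- cna_segments[[si]]
    carriers <- is_tumor & sample_of == s
    cna_mult[idx, carriers] <- config$cna_fold
    seg_table[[length(seg_table) + 1L]] <- data.frame(
      branch = paste0(s, ".trunk"), segment = si,
      chrom = gene_coords$chrom[idx[1]],
      start = min(gene_coords$tss[idx]), end = max(gene_coords$tss[idx]),
      fold = config$cna_fold)
  }
  for (k in seq_len(n_sub)) {
    si <- si + 1L
    if (si > length(cna_segments)) break
    idx <- cna_segments[[si]]
    carriers <- is_tumor & subclone_of == ax$subclone[k]
    cna_mult[idx, carriers] <- config$cna_fold
    seg_table[[length(seg_table) + 1L]] <- data.frame(
      branch = ax$subclone[k], segment = si,
      chrom = gene_coords$chrom[idx[1]],
      start = min(gene_coords$tss[idx]), end = max(gene_coords$tss[idx]),
      fold = config$cna_fold)
  }
  cna_segments_df <- do.call(rbind, seg_table)

  ## ---- RNA expression model ----
  F <- config$marker_fold
  w <- stats::rlnorm(n_genes, 0, 1)
  # regulon genes (TFs and their targets) get a moderate expression floor:
  # planted networks among genes lost to dropout would not be recoverable by
  # any method, nor are key regulators typically in the lowest expression tail
  reg <- block_of %in% c("tf", "target")
  w[reg] <- w[reg] + 1
  logfold <- matrix(0, n_genes, n_cells)
  gidx <- function(g) match(g, gene_names)
  addf <- function(genes, mult) {
    logfold[gidx(genes), ] <<- logfold[gidx(genes), ] +
      matrix(log(mult), length(genes), n_cells, byrow = TRUE)
  }
  addf(g_H,   1 + (F - 1) * act_H)
  addf(g_LP,  1 + (F - 1) * act_LP)
  addf(g_M,   1 + (F - 1) * act_M)
  addf(g_epi, 1 + (F - 1) * act_epi)
  addf(g_cyc, ifelse(cycling, 8, 1))
  addf(g_dnr, exp(0.4 * act_LP))
  addf(g_csc, 1 + 6 * act_LP)
  for (j in seq_len(n_drivers)) {
    a <- tf_act[, j]
    logfold[gidx(drivers[j]), ] <- logfold[gidx(drivers[j]), ] + 0.5 * a
    tgt <- edges$target[edges$tf == drivers[j]]
    logfold[gidx(tgt), ] <- logfold[gidx(tgt), ] +
      matrix(0.5 * a, length(tgt), n_cells, byrow = TRUE)
  }
  p <- w * exp(logfold) * cna_mult
  p <- sweep(p, 2, colSums(p), "/")
  lib <- stats::rlnorm(n_cells, config$depth_lognormal_params[["meanlog"]],
                       config$depth_lognormal_params[["sdlog"]])
  mu <- sweep(p, 2, lib, "*")
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = size),
                   n_genes, n_cells)
  dimnames(counts) <- list(gene_names, cell_id)
  rna <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  ## ---- ATAC peaks ----
  n_peaks <- config$n_peaks
  n_target_peaks <- nrow(edges)
  n_state_peaks <- 3L * config$state_peaks_per_state
  n_bg_peaks <- n_peaks - n_target_peaks - n_state_peaks
  if (n_bg_peaks < 0) stop("configuration error: n_peaks too small for planted peaks")
  peak_kind <- c(rep("target", n_target_peaks),
                 rep(c("scH", "scLP", "scM"), each = config$state_peaks_per_state),
                 rep("background", n_bg_peaks))
  # target peaks sit 10 kb from their gene's TSS; others mid-gap (>= 250 kb
  # from every TSS) so planted peak-gene links are unambiguous
  tcoord <- gene_coords[match(edges$target, gene_coords$gene), ]
  bg_slots <- sample(which(!duplicated(paste(gene_coords$chrom, gene_coords$tss))),
                     n_state_peaks + n_bg_peaks, replace = TRUE)
  peak_chrom <- c(tcoord$chrom, gene_coords$chrom[bg_slots])
  peak_start <- c(tcoord$tss + 10000, gene_coords$tss[bg_slots] + 500000)
  peak_width <- 400L
  peak_id <- sprintf("peak%05d", seq_len(n_peaks))
  peaks <- GenomicRanges::GRanges(
    peak_chrom, IRanges::IRanges(peak_start, width = peak_width))
  names(peaks) <- peak_id
  peaks$kind <- peak_kind

  v <- stats::rlnorm(n_peaks, 0, 0.5)
  plogfold <- matrix(0, n_peaks, n_cells)
  PF <- config$peak_fold
  state_act <- cbind(scH = act_H, scLP = act_LP, scM = act_M)
  for (st in c("scH", "scLP", "scM")) {
    rows <- which(peak_kind == st)
    plogfold[rows, ] <- matrix(log(1 + (PF - 1) * state_act[, st]),
                               length(rows), n_cells, byrow = TRUE)
  }
  for (j in seq_len(n_drivers)) {
    rows <- which(peak_kind == "target")[edges$tf == drivers[j]]
    plogfold[rows, ] <- matrix(0.8 * tf_act[, j], length(rows), n_cells,
                               byrow = TRUE)
  }
  pr <- v * exp(plogfold)
  pr <- sweep(pr, 2, colSums(pr), "/")
  atac_lib <- stats::rlnorm(n_cells,
                            config$atac_depth_lognormal_params[["meanlog"]],
                            config$atac_depth_lognormal_params[["sdlog"]])
  amu <- sweep(pr, 2, atac_lib, "*")
  acounts <- matrix(stats::rpois(n_peaks * n_cells, amu), n_peaks, n_cells)
  dimnames(acounts) <- list(peak_id, cell_id)
  atac <- methods::as(Matrix::Matrix(acounts, sparse = TRUE), "CsparseMatrix")

  ## ---- motif occupancy (one motif per TF) ----
  motif_names <- paste0("motif_", tf_names)
  occ <- list()
  for (j in seq_along(tf_names)) {
    if (j <= n_drivers) {
      pk <- peak_id[peak_kind == "target"][edges$tf == drivers[j]]
    } else {
      pk <- sample(peak_id[peak_kind == "background"],
                   min(6L, n_bg_peaks))
    }
    occ[[j]] <- data.frame(motif = motif_names[j], tf = tf_names[j], peak = pk,
                           stringsAsFactors = FALSE)
  }
  motif_occupancy <- do.call(rbind, occ)

  ## ---- phased SNPs and LOH allele counts ----
  loh_sample_ids <- paste0("S", config$loh_samples)
  loh_status <- is_tumor & sample_of %in% loh_sample_ids
  n_snp <- config$snp_count
  pat_is_B <- stats::rbinom(n_snp, 1, 0.5) == 1
  snp_baf <- ifelse(pat_is_B, stats::runif(n_snp, 0.70, 0.80),
                    stats::runif(n_snp, 0.20, 0.30))
  n_unin <- config$n_uninformative_snps
  snp_id <- sprintf("snp%03d", seq_len(n_snp + n_unin))
  baf <- c(snp_baf, stats::runif(n_unin, 0.40, 0.60))
  snp_pos <- sort(sample.int(2800000L, n_snp + n_unin))
  variants_snp <- data.frame(
    variant_id = snp_id, chrom = "chr11", pos = snp_pos,
    ref = "A", alt = "B", type = "phased_snp", branch = NA_character_,
    wgs_baf = baf, stringsAsFactors = FALSE)
  # reads per cell over informative SNPs only (uninformative SNPs are not
  # covered in this simulation; they exist to exercise phasing exclusion)
  tot_reads <- stats::rpois(n_cells, config$snp_coverage_mean)
  ac_rows <- vector("list", n_cells)
  eps <- config$loh_error_rate
  for (c0 in which(tot_reads > 0)) {
    per_snp <- stats::rmultinom(1, tot_reads[c0], rep(1 / n_snp, n_snp))[, 1]
    cov_snp <- which(per_snp > 0)
    if (!length(cov_snp)) next
    p_pat <- if (loh_status[c0]) 1 - eps else 0.5
    pat_reads <- stats::rbinom(length(cov_snp), per_snp[cov_snp], p_pat)
    mat_reads <- per_snp[cov_snp] - pat_reads
    # translate parental reads into REF(A)/ALT(B) read counts per SNP
    b_reads <- ifelse(pat_is_B[cov_snp], pat_reads, mat_reads)
    a_reads <- per_snp[cov_snp] - b_reads
    ac_rows[[c0]] <- data.frame(
      cell_id = cell_id[c0], variant_id = snp_id[cov_snp],
      ref_reads = a_reads, alt_reads = b_reads, stringsAsFactors = FALSE)
  }
  allele_counts_snp <- do.call(rbind, ac_rows[!vapply(ac_rows, is.null, TRUE)])

  ## ---- somatic mutations on tree branches ----
  branches <- c(paste0(unique(ax$sample), ".trunk"), ax$subclone)
  mut_rows <- list()
  mvar_rows <- list()
  mid <- 0L
  for (b in branches) {
    smp <- sub("\\.(trunk|cl[0-9]+)$", "", b)
    smp <- sub("\\..*$", "", b)
    carriers <- if (grepl("\\.trunk$", b)) {
      is_tumor & sample_of == smp
    } else {
      is_tumor & subclone_of == b
    }
    for (i in seq_len(config$mutation_count_per_branch)) {
      mid <- mid + 1L
      vid <- sprintf("mut%04d", mid)
      mvar_rows[[mid]] <- data.frame(
        variant_id = vid, chrom = sample(chrs, 1),
        pos = sample.int(per_chr * 1000000L, 1), ref = sample(c("A", "C", "G", "T"), 1),
        alt = sample(c("A", "C", "G", "T"), 1), type = "somatic",
        branch = b, wgs_baf = NA_real_, stringsAsFactors = FALSE)
      ncov <- stats::rpois(n_cells, config$mutation_coverage)
      cov_cells <- which(ncov > 0)
      if (!length(cov_cells)) next
      alt <- integer(length(cov_cells))
      car <- carriers[cov_cells]
      alt[car] <- stats::rbinom(sum(car), ncov[cov_cells][car], 0.5)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        cell_id = cell_id[cov_cells], variant_id = vid,
        ref_reads = ncov[cov_cells] - alt, alt_reads = alt,
        stringsAsFactors = FALSE)
    }
  }
  variants <- rbind(variants_snp, do.call(rbind, mvar_rows))
  allele_counts <- rbind(allele_counts_snp, do.call(rbind, mut_rows))
  rownames(allele_counts) <- NULL
  branch_mutations <- split(variants$variant_id[variants$type == "somatic"],
                            variants$branch[variants$type == "somatic"])

  ## ---- small bulk RNA cohort (H / LP / M groups) ----
  bulk_groups <- rep(c("H", "LP", "M"), each = 10)
  bulk_z <- c(rep(-2, 10), rep(2, 10), rep(0, 10))
  bulk_m <- c(rep(0, 20), rep(3, 10))
  bulk <- matrix(0, n_genes, 30, dimnames = list(gene_names, sprintf("bulk%02d", 1:30)))
  bH <- stats::plogis(-2 * bulk_z); bLP <- stats::plogis(2 * bulk_z)
  bM <- stats::plogis(4 * (bulk_m - 1.5)); bepi <- 1 - bM
  for (i in 1:30) {
    lf <- numeric(n_genes)
    lf[gidx(g_H)] <- log(1 + (F - 1) * bH[i])
    lf[gidx(g_LP)] <- log(1 + (F - 1) * bLP[i])
    lf[gidx(g_M)] <- log(1 + (F - 1) * bM[i])
    lf[gidx(g_epi)] <- log(1 + (F - 1) * bepi[i])
    for (j in seq_len(n_drivers)) {
      a <- config$tf_axis_loading *
        switch(driver_state[j], scH = -bulk_z[i] / 1.5, scLP = bulk_z[i] / 1.5,
               scM = (bulk_m[i] - 1.5) / 1.5)
      lf[gidx(drivers[j])] <- lf[gidx(drivers[j])] + 0.5 * a
      lf[gidx(edges$target[edges$tf == drivers[j]])] <-
        lf[gidx(edges$target[edges$tf == drivers[j]])] + 0.5 * a
    }
    bulk[, i] <- log2(w * exp(lf)) + stats::rnorm(n_genes, 0, 0.3)
  }

  truth <- list(
    cells = data.frame(
      cell_id = cell_id, sample = sample_of, subclone = subclone_of,
      tumor = is_tumor, state = state, z = z, m = m, loh = loh_status,
      cycling = cycling, stringsAsFactors = FALSE),
    edges = edges,
    driver_tfs = data.frame(tf = drivers, state = driver_state,
                            stringsAsFactors = FALSE),
    tf_names = tf_names,
    motif_occupancy = motif_occupancy,
    peak_kind = data.frame(peak = peak_id, kind = peak_kind,
                           stringsAsFactors = FALSE),
    branch_mutations = branch_mutations,
    cna_segments = cna_segments_df,
    marker_blocks = list(H = g_H, LP = g_LP, M = g_M, epi = g_epi,
                         cycling = g_cyc, dna_repair = g_dnr, csc = g_csc))

  structure(list(rna = rna, atac = atac, peaks = peaks,
                 gene_coords = gene_coords, variants = variants,
                 allele_counts = allele_counts,
                 bulk = list(matrix = bulk, groups = bulk_groups),
                 truth = truth, config = config),
            class = "hb_sim")
}

#' Simulate a null allele-count table (no LOH)
#'
#' Each cell receives `n ~ Poisson(coverage_mean)` informative reads over a
#' single phased SNP whose paternal allele is the ALT (B) allele; the paternal
#' read count is Binomial(n, 0.5), the expectation in absence of LOH. Used to
#' calibrate the LOH caller and the sample pseudo-BAF.
#'
#' @param n_cells Number of cells (>= 1).
#' @param coverage_mean Mean informative reads per cell (> 0).
#' @param seed Integer seed.
#' @return A data frame with columns `cell_id`, `variant_id`, `ref_reads`
#'   (maternal) and `alt_reads` (paternal); zero-read cells are retained.
#' @export
simulate_null_allele_table <- function(n_cells, coverage_mean, seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (coverage_mean <= 0) stop("coverage_mean must be > 0")
  set.seed(seed)
  n <- stats::rpois(n_cells, coverage_mean)
  pat <- stats::rbinom(n_cells, n, 0.5)
  data.frame(cell_id = sprintf("cell%05d", seq_len(n_cells)),
             variant_id = "nullSNP",
             ref_reads = n - pat, alt_reads = pat,
             stringsAsFactors = FALSE)
}

#' Simulate a two-group peak count matrix with planted accessible peaks
#'
#' A calibration generator for the differential-accessibility test: two cell
#' groups with negative-binomial peak counts, a subset of peaks more
#' accessible in group A by a fixed fold.
#'
#' @param n_cells_per_group Cells per group.
#' @param n_peaks Total peaks.
#' @param n_planted Peaks with elevated accessibility in group A (0 for a
#'   null simulation).
#' @param fold Accessibility fold of planted peaks.
#' @param base_mu Mean count per cell of an unplanted peak.
#' @param dispersion NB overdispersion.
#' @param seed Integer seed.
#' @return List with `counts` (peaks x cells dgCMatrix), `groups` (factor)
#'   and `planted` (peak ids).
#' @export
simulate_peak_groups <- function(n_cells_per_group = 500, n_peaks = 200,
                                 n_planted = 4, fold = 4, base_mu = 5,
                                 dispersion = 0.3, seed = 1L) {
  set.seed(seed)
  n_cells <- 2L * n_cells_per_group
  groups <- factor(rep(c("A", "B"), each = n_cells_per_group))
  mu <- matrix(base_mu, n_peaks, n_cells)
  planted <- integer(0)
  if (n_planted > 0) {
    planted <- seq_len(n_planted)
    mu[planted, groups == "A"] <- base_mu * fold
  }
  counts <- matrix(stats::rnbinom(n_peaks * n_cells, mu = mu,
                                  size = 1 / dispersion), n_peaks, n_cells)
  dimnames(counts) <- list(sprintf("peak%05d", seq_len(n_peaks)),
                           sprintf("cell%05d", seq_len(n_cells)))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       groups = groups,
       planted = rownames(counts)[planted])
}

#' Write a simulated dataset to plain-text files
#'
#' Writes cellranger-style MTX triplets for the RNA and ATAC matrices, a BED
#' file for peaks (0-based half-open), and TSV tables for variants, allele
#' counts and ground truth. Round-trips losslessly through the package
#' readers.
#'
#' @param sim An `hb_sim` object from [simulate_multiome()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "hb_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  files <- c(files, write_mtx_triplet(sim$rna, file.path(out_dir, "rna")))
  files <- c(files, write_mtx_triplet(sim$atac, file.path(out_dir, "atac")))
  bed <- file.path(out_dir, "peaks.bed")
  write_bed(sim$peaks, bed)
  files <- c(files, bed)
  tsv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(files, tsv(sim$variants, "variants.tsv"))
  files <- c(files, tsv(sim$allele_counts, "allele_counts.tsv"))
  files <- c(files, tsv(sim$gene_coords, "gene_coords.tsv"))
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  files <- c(files, tsv(sim$truth$cells, "truth/cells.tsv"))
  files <- c(files, tsv(sim$truth$edges, "truth/edges.tsv"))
  files <- c(files, tsv(sim$truth$motif_occupancy, "truth/motif_occupancy.tsv"))
  invisible(files)
}
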