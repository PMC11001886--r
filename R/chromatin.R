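#' Consolidate per-group peak sets into one peak universe
#'
#' Union-merges intersecting intervals per chromosome, then removes outlier
#' peaks narrower than `min_width` or wider than `max_width` (the width
#' filter applies after merging). Output is sorted.
#'
#' @param peak_lists A `GRanges` or list of `GRanges` (one per group).
#' @param min_width,max_width Width bounds in bp (inclusive interval kept;
#'   defaults 20 and 10000).
#' @return A sorted `GRanges`.
#' @export
consolidate_peaks <- function(peak_lists, min_width = 20, max_width = 10000) {
  if (is.list(peak_lists)) {
    gr <- do.call(c, lapply(peak_lists, function(g) {
      GenomicRanges::granges(g)
    }))
  } else {
    gr <- GenomicRanges::granges(peak_lists)
  }
  merged <- GenomicRanges::reduce(gr)
  w <- GenomicRanges::width(merged)
  GenomicRanges::sort(merged[w >= min_width & w <= max_width])
}

#' Differential accessibility between two cell groups
#'
#' Each group is subsampled to at most `max_cells` cells (seeded), peak
#' counts are depth-normalized per cell to a common scale, and each peak is
#' tested with a two-sided Wilcoxon rank-sum test; p-values are BH-adjusted
#' across peaks. The log2 fold-change is computed on the group means with a
#' pseudo-count, which slightly attenuates large folds when means are small.
#'
#' @param peak_matrix Peaks x cells count matrix.
#' @param group_a,group_b Cell ids of the two groups.
#' @param max_cells Per-group subsampling bound (default 1000).
#' @param scale_factor Depth-normalization scale (default 1e4).
#' @param pseudo_count Pseudo-count for the fold-change (default 1).
#' @param lfc_min,fdr_max Significance thresholds (defaults 1 and 1e-3).
#' @param seed Subsampling seed.
#' @return Data frame with `peak`, `log2_fc` (A over B), `p_value`, `fdr`,
#'   `direction` and `significant`; attribute `seed` records the
#'   subsampling seed.
#' @export
differential_peaks <- function(peak_matrix, group_a, group_b,
                               max_cells = 1000, scale_factor = 1e4,
                               pseudo_count = 1, lfc_min = 1,
                               fdr_max = 1e-3, seed = 1L) {
  group_a <- intersect(group_a, colnames(peak_matrix))
  group_b <- intersect(group_b, colnames(peak_matrix))
  if (!length(group_a) || !length(group_b)) stop("empty cell group")
  set.seed(seed)
  if (length(group_a) > max_cells) group_a <- sample(group_a, max_cells)
  if (length(group_b) > max_cells) group_b <- sample(group_b, max_cells)
  sub <- peak_matrix[, c(group_a, group_b), drop = FALSE]
  depth <- Matrix::colSums(sub)
  if (any(depth == 0)) stop("cell(s) with zero total counts")
  norm <- sweep(as.matrix(sub), 2, scale_factor / depth, "*")
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  pv <- apply(norm, 1, function(x) {
    stats::wilcox.test(x[ia], x[ib], exact = FALSE)$p.value
  })
  pv[is.na(pv)] <- 1
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  lfc <- log2((mean_a + pseudo_count) / (mean_b + pseudo_count))
  fdr <- stats::p.adjust(pv, "BH")
  out <- data.frame(peak = rownames(peak_matrix), log2_fc = lfc,
                    p_value = pv, fdr = fdr,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    significant = abs(lfc) >= lfc_min & fdr <= fdr_max,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

bp_overlap <- function(query, subject) {
  sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(query), GenomicRanges::reduce(subject),
    ignore.strand = TRUE)))
}

#' Chromatin-state enrichment of differential peaks
#'
#' For each annotation state, the ratio between the proportion of
#' nucleotides in that state within the differential peak set and the same
#' proportion within the full peak set. A ratio of 1 means the differential
#' set has the background composition. States absent from the full peak set
#' are undefined (`NA`), not 0.
#'
#' @param diff_peaks `GRanges` of differential peaks (non-empty).
#' @param all_peaks `GRanges` of the full peak set.
#' @param states `GRanges` of annotation intervals with a state label in
#'   `names()` or a `state` metadata column.
#' @return Data frame with `state`, `prop_diff`, `prop_all`, `ratio`.
#' @export
state_enrichment <- function(diff_peaks, all_peaks, states) {
  if (!length(diff_peaks)) stop("empty differential peak set")
  lab <- if (!is.null(states$state)) states$state else names(states)
  if (is.null(lab)) stop("state annotation needs names or a `state` column")
  tot_diff <- sum(GenomicRanges::width(GenomicRanges::reduce(diff_peaks)))
  tot_all <- sum(GenomicRanges::width(GenomicRanges::reduce(all_peaks)))
  out <- do.call(rbind, lapply(unique(lab), function(st) {
    ann <- states[lab == st]
    pd <- bp_overlap(diff_peaks, ann) / tot_diff
    pa <- bp_overlap(all_peaks, ann) / tot_all
    data.frame(state = st, prop_diff = pd, prop_all = pa,
               ratio = if (pa > 0) pd / pa else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' TF motif enrichment of differential peaks
#'
#' The same nucleotide-ratio statistic as [state_enrichment()], computed on
#' motif occurrence footprints clipped to peak boundaries. When a TF has
#' several motif versions, the version with the highest enrichment ratio is
#' reported for the TF.
#'
#' @param diff_peaks,all_peaks Peak `GRanges`.
#' @param occurrences Motif occurrence `GRanges` with a `motif` metadata
#'   column and optionally a `tf` column grouping motif versions.
#' @return Data frame per motif (`motif`, `ratio`, ...); when a `tf` column
#'   is present, attribute `by_tf` holds the max-ratio version per TF.
#' @export
motif_enrichment <- function(diff_peaks, all_peaks, occurrences) {
  if (!length(diff_peaks)) stop("empty differential peak set")
  if (is.null(occurrences$motif)) stop("occurrences need a `motif` column")
  clip_all <- GenomicRanges::pintersect(
    IRanges::findOverlapPairs(occurrences, GenomicRanges::reduce(all_peaks)))
  tot_diff <- sum(GenomicRanges::width(GenomicRanges::reduce(diff_peaks)))
  tot_all <- sum(GenomicRanges::width(GenomicRanges::reduce(all_peaks)))
  motifs <- unique(occurrences$motif)
  out <- do.call(rbind, lapply(motifs, function(mo) {
    occ <- clip_all[clip_all$motif == mo]
    if (!length(occ)) {
      return(data.frame(motif = mo, prop_diff = NA_real_, prop_all = NA_real_,
                        ratio = NA_real_, stringsAsFactors = FALSE))
    }
    pd <- bp_overlap(diff_peaks, occ) / tot_diff
    pa <- bp_overlap(all_peaks, occ) / tot_all
    data.frame(motif = mo, prop_diff = pd, prop_all = pa,
               ratio = if (isTRUE(pa > 0)) pd / pa else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(occurrences$tf)) {
    tf_of <- occurrences$tf[match(out$motif, occurrences$motif)]
    keep <- !is.na(out$ratio)
    sp <- split(out[keep, ], tf_of[keep])
    by_tf <- do.call(rbind, lapply(names(sp), function(tf) {
      b <- sp[[tf]][which.max(sp[[tf]]$ratio), ]
      cbind(data.frame(tf = tf, stringsAsFactors = FALSE), b)
    }))
    rownames(by_tf) <- NULL
    attr(out, "by_tf") <- by_tf
  }
  out
}

#' Shuffle-based overlap enrichment between a query and a reference set
#'
#' Counts query peaks overlapping the reference and compares against a null
#' obtained by repeatedly sampling the same number of peaks from a shuffle
#' universe (for example, the full peak set). Empirical p-values use the
#' +1 correction; with a list of reference sets, q-values are BH-adjusted
#' across references.
#'
#' @param query `GRanges` of query peaks (a subset of the universe).
#' @param reference A `GRanges` or named list of `GRanges`.
#' @param universe `GRanges` the null draws from.
#' @param n_shuffles Number of null draws (default 1000; < 100 warns).
#' @param seed Seed.
#' @return Data frame with `reference`, `observed`, `expected`, `fold`,
#'   `p_value` and `q_value`.
#' @export
interval_overlap_enrichment <- function(query, reference, universe,
                                        n_shuffles = 1000, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (n_shuffles < 100) warning("fewer than 100 shuffles: p-values are coarse")
  refs <- if (inherits(reference, "GRanges")) list(reference = reference) else reference
  set.seed(seed)
  nq <- length(query)
  draws <- replicate(n_shuffles, sample.int(length(universe), nq),
                     simplify = FALSE)
  out <- do.call(rbind, lapply(names(refs), function(nm) {
    ref <- refs[[nm]]
    obs <- sum(IRanges::overlapsAny(query, ref))
    null <- vapply(draws, function(i) {
      sum(IRanges::overlapsAny(universe[i], ref))
    }, 0L)
    data.frame(reference = nm, observed = obs, expected = mean(null),
               fold = obs / max(mean(null), .Machine$double.eps),
               p_value = (1 + sum(null >= obs)) / (n_shuffles + 1),
               stringsAsFactors = FALSE)
  }))
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' chromVAR-style per-cell motif accessibility deviations
#'
#' For each motif and cell, the raw deviation is the observed fragment
#' count in the motif's peaks minus the expectation from the cell's depth
#' and the motif peaks' overall accessibility fraction, divided by that
#' expectation. Deviations are z-scored against `n_background` seeded
#' background peak sets matched on total accessibility (quantile bins), so
#' that homogeneous data yields mean ~0 / SD ~1 per motif.
#'
#' @param peak_matrix Peaks x cells count matrix.
#' @param occupancy Named list mapping motif -> peak ids, or a data frame
#'   with `motif` and `peak` columns.
#' @param n_background Background sets (default 50).
#' @param n_bins Accessibility-matching bins (default 10).
#' @param seed Seed.
#' @return Cells x motifs z-score matrix; attribute `degenerate` lists
#'   motifs whose background has zero variance (z set to 0).
#' @export
motif_deviations <- function(peak_matrix, occupancy, n_background = 50,
                             n_bins = 10, seed = 1L) {
  if (is.data.frame(occupancy)) {
    occupancy <- split(occupancy$peak, occupancy$motif)
  }
  if (!length(occupancy) || any(lengths(occupancy) == 0)) {
    stop("motif with zero peaks")
  }
  miss <- setdiff(unique(unlist(occupancy)), rownames(peak_matrix))
  if (length(miss)) stop("occupancy references unknown peak(s)")
  set.seed(seed)
  depth <- Matrix::colSums(peak_matrix)
  grand <- sum(depth)
  peak_tot <- Matrix::rowSums(peak_matrix)
  bins <- cut(rank(peak_tot, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  by_bin <- split(seq_len(nrow(peak_matrix)), bins)
  dev_for <- function(idx) {
    f <- sum(peak_tot[idx]) / grand
    obs <- Matrix::colSums(peak_matrix[idx, , drop = FALSE])
    expc <- depth * f
    as.numeric((obs - expc) / pmax(expc, .Machine$double.eps))
  }
  z <- matrix(NA_real_, ncol(peak_matrix), length(occupancy),
              dimnames = list(colnames(peak_matrix), names(occupancy)))
  degenerate <- character(0)
  for (mo in names(occupancy)) {
    idx <- match(occupancy[[mo]], rownames(peak_matrix))
    d0 <- dev_for(idx)
    bg <- sapply(seq_len(n_background), function(b) {
      sampled <- vapply(idx, function(i) {
        pool <- by_bin[[as.character(bins[i])]]
        pool[sample.int(length(pool), 1)]
      }, 0L)
      dev_for(sampled)
    })
    mu <- rowMeans(bg)
    sdv <- apply(bg, 1, stats::sd)
    zi <- (d0 - mu) / sdv
    if (any(!is.finite(zi))) {
      degenerate <- c(degenerate, mo)
      zi[!is.finite(zi)] <- 0
    }
    z[, mo] <- zi
  }
  attr(z, "degenerate") <- degenerate
  z
}

#' Aggregate transposase insertion footprint around motif sites
#'
#' Sums per-base insertion counts over +/-`flank` bp around motif centers,
#' normalizes by the mean of the outermost `flank_norm` positions on each
#' side (so flank edges sit at ~1), and smooths with a centered moving
#' average. Profiles are bias-uncorrected: no transposase sequence-bias
#' subtraction is applied.
#'
#' @param insertions Data frame with `chrom`, `pos` (1-based) and `count`.
#' @param motif_centers Data frame with `chrom` and `pos` of site centers.
#' @param flank Half-window in bp (default 250).
#' @param flank_norm Positions per edge used for normalization (default 50;
#'   must be < `flank`).
#' @param smooth_window Moving-average width in positions (default 5).
#' @return Data frame with `position` (-flank..flank), `raw`, `normalized`
#'   and `smoothed`.
#' @export
footprint_profile <- function(insertions, motif_centers, flank = 250,
                              flank_norm = 50, smooth_window = 5) {
  if (flank_norm >= flank) stop("flank_norm must be < flank")
  if (!nrow(motif_centers)) stop("need at least one motif site")
  offsets <- -flank:flank
  prof <- numeric(length(offsets))
  ins_key <- paste(insertions$chrom, insertions$pos)
  for (i in seq_len(nrow(motif_centers))) {
    pos <- motif_centers$pos[i] + offsets
    hit <- match(paste(motif_centers$chrom[i], pos), ins_key)
    found <- !is.na(hit)
    prof[found] <- prof[found] + insertions$count[hit[found]]
  }
  edge <- c(seq_len(flank_norm), length(offsets) - flank_norm + seq_len(flank_norm))
  norm_level <- mean(prof[edge])
  if (norm_level == 0) norm_level <- 1
  normalized <- prof / norm_level
  w <- smooth_window
  if (w %% 2 == 0) w <- w + 1
  smoothed <- as.numeric(stats::filter(normalized, rep(1 / w, w), sides = 2))
  smoothed[is.na(smoothed)] <- normalized[is.na(smoothed)]
  data.frame(position = offsets, raw = prof, normalized = normalized,
             smoothed = smoothed)
}

#' Build motif occurrence intervals from a motif-peak occupancy table
#'
#' Places one fixed-width occurrence at the center of each occupied peak;
#' a convenience for occupancy-only inputs (real occurrence coordinates can
#' be supplied directly to [motif_enrichment()]).
#'
#' @param occupancy Data frame with `motif`, `peak` and optionally `tf`.
#' @param peaks Named `GRanges` of peaks.
#' @param width Occurrence width in bp (default 10).
#' @return `GRanges` with `motif` (and `tf`) metadata.
#' @export
motif_sites_from_occupancy <- function(occupancy, peaks, width = 10) {
  idx <- match(occupancy$peak, names(peaks))
  if (anyNA(idx)) stop("occupancy references unknown peak(s)")
  center <- (GenomicRanges::start(peaks)[idx] +
               GenomicRanges::end(peaks)[idx]) %/% 2
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks)[idx],
    IRanges::IRanges(center - width %/% 2, width = width))
  gr$motif <- occupancy$motif
  if (!is.null(occupancy$tf)) gr$tf <- occupancy$tf
  gr
}
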