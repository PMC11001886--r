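# Independent brute-force oracles used to cross-check package statistics.

# enumerate every (chrom, base) covered by the reduced ranges
bp_set <- function(gr) {
  gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  if (!length(gr)) return(character(0))
  unlist(lapply(seq_along(gr), function(i) {
    paste(as.character(GenomicRanges::seqnames(gr)[i]),
          GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i])
  }))
}

# nucleotide-ratio enrichment by literal per-base counting
oracle_state_ratio <- function(diff_peaks, all_peaks, annotation) {
  d <- bp_set(diff_peaks)
  a <- bp_set(all_peaks)
  s <- bp_set(annotation)
  (sum(d %in% s) / length(d)) / (sum(a %in% s) / length(a))
}

# same, with occurrences clipped to the peak universe first
oracle_motif_ratio <- function(diff_peaks, all_peaks, occurrences) {
  d <- bp_set(diff_peaks)
  a <- bp_set(all_peaks)
  s <- intersect(bp_set(occurrences), a)
  (sum(d %in% s) / length(d)) / (sum(a %in% s) / length(a))
}

# brute-force weighted variance decomposition via explicit OLS
oracle_weighted_r2 <- function(scores, covariates, k) {
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  r2 <- vapply(seq_len(k), function(i) {
    y <- scores[, i]
    beta <- qr.solve(X, y)
    1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  }, 0)
  v <- apply(scores[, seq_len(k), drop = FALSE], 2, stats::var)
  list(weighted_r2 = sum(r2 * v) / sum(v), r2 = r2)
}

# a 10-TF metric table where TF "T09" sits at metric percentiles
# 0.9 (bulk), 0.8 (expression) and 1.0 (deviation)
metrics_with_known_percentiles <- function() {
  expr <- (1:10) / 20
  expr[c(8, 9)] <- expr[c(9, 8)]    # T09 ranks 8th on expression
  dev <- (1:10) / 30
  dev[c(9, 10)] <- dev[c(10, 9)]    # T09 ranks 10th on deviation
  data.frame(tf = sprintf("T%02d", 1:10), state = "scH",
             bulk_lfc = (1:10) / 10,  # T09 ranks 9th on bulk
             bulk_q = 0.01, expr_cor = expr, expr_q = 0.01,
             dev_cor = dev, dev_q = 0.01, stringsAsFactors = FALSE)
}
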