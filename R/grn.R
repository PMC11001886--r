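#' Per-TF association metrics for each differentiation state
#'
#' Computes, for every TF and state, the three evidence streams behind the
#' composite key-TF score: (i) differential expression in bulk RNA-seq
#' between the state's molecular group and the rest (log fold-change of
#' log-scale means, Welch t-test); (ii) Pearson correlation of the TF's
#' aggregated single-nucleus expression with the state's oriented axis;
#' (iii) the same correlation for the TF's aggregated motif deviation.
#' q-values are BH-adjusted within each metric and state. State
#' directionality: scM follows +PC1, sc-epi -PC1, scLP +PC2, scH -PC2.
#'
#' @param tf_list TFs to score.
#' @param bulk Genes x samples log-scale bulk matrix.
#' @param bulk_groups Molecular group (`"H"`, `"LP"`, `"M"`) per bulk sample.
#' @param agg_expr Genes x metacells aggregated expression.
#' @param agg_dev TFs x metacells aggregated motif deviations (rownames are
#'   TF ids).
#' @param pc1,pc2 Per-metacell axis scores (same order as the matrices).
#' @param states State definitions; defaults to scH/scLP/scM (and sc-epi if
#'   both H and LP groups exist). Each entry: `group` (bulk group(s)),
#'   `axis` (`"PC1"`/`"PC2"`), `dir` (+1/-1).
#' @return Data frame of class `hb_tf_metrics`: one row per TF x state with
#'   `bulk_lfc`, `bulk_q`, `expr_cor`, `expr_q`, `dev_cor`, `dev_q`. TFs
#'   absent from a matrix or constant are dropped with a warning.
#' @export
tf_metric_table <- function(tf_list, bulk, bulk_groups, agg_expr, agg_dev,
                            pc1, pc2, states = NULL) {
  if (is.null(states)) {
    states <- list(
      scH = list(group = "H", axis = "PC2", dir = -1),
      scLP = list(group = "LP", axis = "PC2", dir = 1),
      scM = list(group = "M", axis = "PC1", dir = 1))
  }
  present <- tf_list %in% rownames(bulk) & tf_list %in% rownames(agg_expr) &
    tf_list %in% rownames(agg_dev)
  if (any(!present)) {
    warning(sum(!present), " TF(s) absent from an input matrix dropped")
  }
  tfs <- tf_list[present]
  const <- apply(agg_expr[tfs, , drop = FALSE], 1, stats::sd) == 0 |
    apply(agg_dev[tfs, , drop = FALSE], 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant TF(s) dropped")
    tfs <- tfs[!const]
  }
  if (!length(tfs)) stop("no usable TFs")
  cor_with_p <- function(x, y) {
    ct <- stats::cor.test(x, y)
    c(ct$estimate, ct$p.value)
  }
  out <- list()
  for (st in names(states)) {
    def <- states[[st]]
    axis <- def$dir * (if (def$axis == "PC1") pc1 else pc2)
    in_g <- bulk_groups %in% def$group
    res <- t(vapply(tfs, function(tf) {
      a <- bulk[tf, in_g]; b <- bulk[tf, !in_g]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      blfc <- mean(a) - mean(b)
      bp <- if (is.null(tt)) 1 else tt$p.value
      ec <- cor_with_p(as.numeric(agg_expr[tf, ]), axis)
      dc <- cor_with_p(as.numeric(agg_dev[tf, ]), axis)
      c(blfc, bp, ec, dc)
    }, numeric(6)))
    df <- data.frame(tf = tfs, state = st,
                     bulk_lfc = res[, 1], bulk_p = res[, 2],
                     expr_cor = res[, 3], expr_p = res[, 4],
                     dev_cor = res[, 5], dev_p = res[, 6],
                     stringsAsFactors = FALSE)
    df$bulk_q <- stats::p.adjust(df$bulk_p, "BH")
    df$expr_q <- stats::p.adjust(df$expr_p, "BH")
    df$dev_q <- stats::p.adjust(df$dev_p, "BH")
    out[[st]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hb_tf_metrics", class(res))
  res
}

percentile_rank <- function(x) rank(x, ties.method = "average") / length(x)

#' Composite TF scores per state
#'
#' Within each state, TFs significant at `q_max` are ranked on each metric
#' in the favorable direction (higher bulk log fold-change, higher oriented
#' expression and deviation correlations); the percentile is rank/N among
#' the significant TFs (ties share the mean rank) and the composite score
#' is the mean of the three percentiles. In the default strict mode a TF
#' must be significant on all three metrics; the lenient mode requires any
#' one, with non-significant metrics still contributing their percentile.
#'
#' @param metrics An `hb_tf_metrics` table.
#' @param q_max Significance cutoff (default 0.05, inclusive).
#' @param n_top TFs reported per state (default 20).
#' @param mode `"strict"` or `"lenient"`.
#' @return Data frame with per-metric percentiles, `composite` and
#'   `top_n` flag, ordered by state then decreasing composite.
#' @export
composite_scores <- function(metrics, q_max = 0.05, n_top = 20,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  out <- list()
  for (st in unique(metrics$state)) {
    m <- metrics[metrics$state == st, , drop = FALSE]
    sig <- if (mode == "strict") {
      m$bulk_q <= q_max & m$expr_q <= q_max & m$dev_q <= q_max
    } else {
      m$bulk_q <= q_max | m$expr_q <= q_max | m$dev_q <= q_max
    }
    if (!any(sig)) {
      warning("no significant TF for state ", st)
      next
    }
    s <- m[sig, , drop = FALSE]
    s$pct_bulk <- percentile_rank(s$bulk_lfc)
    s$pct_expr <- percentile_rank(s$expr_cor)
    s$pct_dev <- percentile_rank(s$dev_cor)
    s$composite <- (s$pct_bulk + s$pct_expr + s$pct_dev) / 3
    s <- s[order(-s$composite, s$tf), ]
    s$top_n <- seq_len(nrow(s)) <= n_top
    out[[st]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

cor_test_p <- function(r, n) {
  # two-sided p for a Pearson correlation via the t transform
  t <- r * sqrt(pmax(n - 2, 1)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Link peaks to genes by expression-accessibility correlation
#'
#' Candidate pairs are peaks within +/-`window` of a gene's TSS. Genes and
#' peaks below the `var_quantile_cutoff` variance quantile (across
#' metacells) are excluded; remaining pairs are scored by Pearson
#' correlation with BH FDR across all candidates, and retained when the
#' correlation exceeds `cor_cutoff` and the FDR is at most `fdr_cutoff`.
#' Only positive (activating) correlations are retained by default.
#'
#' @param agg_expr Genes x metacells aggregated expression.
#' @param agg_atac Peaks x metacells aggregated accessibility.
#' @param tss Data frame with `gene`, `chrom`, `tss`.
#' @param peaks Named `GRanges` matching `rownames(agg_atac)`.
#' @param window Linking window in bp (default 250000).
#' @param cor_cutoff,fdr_cutoff Retention thresholds (0.4, 0.01).
#' @param var_quantile_cutoff Variance-quantile filter (default 0.25).
#' @param signed Keep negative correlations too (default `FALSE`).
#' @return Data frame with `peak`, `gene`, `correlation`, `fdr`,
#'   `retained`; only candidates are listed.
#' @export
peak_to_gene_links <- function(agg_expr, agg_atac, tss, peaks,
                               window = 250000, cor_cutoff = 0.4,
                               fdr_cutoff = 0.01,
                               var_quantile_cutoff = 0.25,
                               signed = FALSE) {
  shared <- intersect(colnames(agg_expr), colnames(agg_atac))
  if (!length(shared)) stop("no shared metacells between the matrices")
  e <- as.matrix(agg_expr[, shared, drop = FALSE])
  a <- as.matrix(agg_atac[, shared, drop = FALSE])
  ve <- apply(e, 1, stats::var)
  va <- apply(a, 1, stats::var)
  keep_g <- ve >= stats::quantile(ve, var_quantile_cutoff)
  keep_p <- va >= stats::quantile(va, var_quantile_cutoff)
  tss <- tss[tss$gene %in% rownames(e)[keep_g], , drop = FALSE]
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(pmax(1, tss$tss - window), tss$tss + window))
  pk <- peaks[names(peaks) %in% rownames(a)[keep_p]]
  ov <- GenomicRanges::findOverlaps(pk, tss_gr)
  if (!length(ov)) {
    return(data.frame(peak = character(0), gene = character(0),
                      correlation = numeric(0), fdr = numeric(0),
                      retained = logical(0)))
  }
  pid <- names(pk)[S4Vectors::queryHits(ov)]
  gid <- tss$gene[S4Vectors::subjectHits(ov)]
  n <- length(shared)
  r <- vapply(seq_along(pid), function(i) {
    stats::cor(a[pid[i], ], e[gid[i], ])
  }, 0)
  p <- cor_test_p(r, n)
  fdr <- stats::p.adjust(p, "BH")
  passed <- if (signed) abs(r) > cor_cutoff else r > cor_cutoff
  data.frame(peak = pid, gene = gid, correlation = r, fdr = fdr,
             retained = passed & fdr <= fdr_cutoff & !is.na(r),
             stringsAsFactors = FALSE)
}

#' Identify the target genes of a TF
#'
#' A gene is a target when (i) its aggregated expression correlates with
#' the TF's above `cor_min` with BH q-value at most `q_max` (across all
#' tested genes), and (ii) it has at least one retained peak-to-gene link
#' to a peak bearing the TF's binding motif.
#'
#' @param tf TF gene id (must be in `agg_expr` and in the motif table).
#' @param agg_expr Genes x metacells aggregated expression.
#' @param links Output of [peak_to_gene_links()].
#' @param motif_occupancy Data frame with `tf` and `peak` columns.
#' @param cor_min Correlation threshold (default 0.5, exclusive).
#' @param q_max q-value threshold (default 0.001, inclusive).
#' @return Data frame of targets with `gene`, `correlation`, `q_value`.
#' @export
identify_targets <- function(tf, agg_expr, links, motif_occupancy,
                             cor_min = 0.5, q_max = 0.001) {
  if (!tf %in% rownames(agg_expr)) stop("TF absent from expression matrix")
  motif_peaks <- motif_occupancy$peak[motif_occupancy$tf == tf]
  if (!length(motif_peaks)) stop("TF has no motif annotation")
  x <- as.numeric(agg_expr[tf, ])
  genes <- setdiff(rownames(agg_expr), tf)
  r <- as.numeric(stats::cor(x, Matrix::t(agg_expr[genes, , drop = FALSE])))
  q <- stats::p.adjust(cor_test_p(r, length(x)), "BH")
  linked <- unique(links$gene[links$retained & links$peak %in% motif_peaks])
  ok <- !is.na(r) & r > cor_min & q <= q_max & genes %in% linked
  out <- data.frame(gene = genes[ok], correlation = r[ok], q_value = q[ok],
                    stringsAsFactors = FALSE)
  out[order(-out$correlation), , drop = FALSE]
}

#' Build TF-target modules by hierarchical clustering
#'
#' Keeps each TF's top `n_top_targets` targets by correlation, builds the
#' TF x target correlation matrix from aggregated expression, and clusters
#' the TFs on their correlation profiles using Pearson distance
#' (1 - correlation) with Ward linkage, cut into `n_modules`. Module
#' activity is the mean member-TF expression per state when state labels
#' are supplied.
#'
#' @param target_lists Named list (per TF) of target data frames from
#'   [identify_targets()].
#' @param agg_expr Genes x metacells aggregated expression.
#' @param n_top_targets Targets kept per TF (default 2).
#' @param n_modules Modules to cut (default 4).
#' @param metacell_states Optional state label per metacell.
#' @return List with `modules` (TF -> module id), `targets` (kept
#'   targets per TF), `cor_matrix` and `activity` (module x state means,
#'   when labels are given).
#' @export
build_modules <- function(target_lists, agg_expr, n_top_targets = 2,
                          n_modules = 4, metacell_states = NULL) {
  tfs <- names(target_lists)
  if (length(tfs) < 2) stop("need >= 2 TFs")
  if (n_modules > length(tfs)) stop("n_modules exceeds number of TFs")
  top <- lapply(target_lists, function(df) {
    utils::head(df$gene[order(-df$correlation)], n_top_targets)
  })
  targets <- unique(unlist(top))
  if (!length(targets)) stop("no targets to cluster on")
  cm <- stats::cor(t(as.matrix(agg_expr[tfs, , drop = FALSE])),
                   t(as.matrix(agg_expr[targets, , drop = FALSE])))
  d <- stats::as.dist(1 - stats::cor(t(cm)))
  hc <- stats::hclust(d, method = "ward.D")
  modules <- stats::cutree(hc, k = n_modules)
  activity <- NULL
  if (!is.null(metacell_states)) {
    sts <- sort(unique(metacell_states))
    activity <- t(vapply(seq_len(n_modules), function(k) {
      members <- tfs[modules == k]
      vapply(sts, function(s) {
        mean(as.matrix(agg_expr[members, metacell_states == s, drop = FALSE]))
      }, 0)
    }, numeric(length(sts))))
    dimnames(activity) <- list(paste0("module", seq_len(n_modules)), sts)
  }
  list(modules = modules, targets = top, cor_matrix = cm,
       dendrogram = hc, activity = activity)
}

#' Order TFs by their activation position along the LP-H axis
#'
#' Metacells are sorted by PC2; each TF's aggregated expression profile is
#' smoothed by a centered running mean over `smoothing_span` metacells and
#' the activation position is the argmax of the smoothed profile. TFs are
#' returned sorted by position (ties break by TF id); flat profiles get the
#' midpoint and are flagged.
#'
#' @param agg_expr TFs x metacells aggregated expression.
#' @param pc2 Per-metacell PC2 values.
#' @param smoothing_span Running-mean width (default 5).
#' @return Data frame with `tf`, `position` (1..n metacells along PC2),
#'   `pc2_at_peak` and `flat`, sorted by activation.
#' @export
order_tf_activation <- function(agg_expr, pc2, smoothing_span = 5) {
  ord <- order(pc2)
  m <- as.matrix(agg_expr[, ord, drop = FALSE])
  w <- smoothing_span
  if (w %% 2 == 0) w <- w + 1
  k <- rep(1 / w, w)
  n <- ncol(m)
  res <- do.call(rbind, lapply(rownames(m), function(tf) {
    x <- m[tf, ]
    if (stats::sd(x) == 0) {
      return(data.frame(tf = tf, position = (n + 1) / 2,
                        pc2_at_peak = stats::median(pc2), flat = TRUE,
                        stringsAsFactors = FALSE))
    }
    sm <- as.numeric(stats::filter(x, k, sides = 2))
    sm[is.na(sm)] <- x[is.na(sm)]
    pos <- which.max(sm)
    data.frame(tf = tf, position = pos, pc2_at_peak = sort(pc2)[pos],
               flat = FALSE, stringsAsFactors = FALSE)
  }))
  res <- res[order(res$position, res$tf), ]
  rownames(res) <- NULL
  res
}
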