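#' Quality-control filtering of a UMI count matrix
#'
#' Removes low-quality nuclei, then lowly detected genes. A nucleus is kept
#' when it has strictly more than `min_umi` UMIs, strictly more than
#' `min_genes` detected genes, and strictly less than `max_mito_fraction`
#' of its UMIs in mitochondrial genes. Genes detected in fewer than
#' `min_cells_per_gene` of the surviving nuclei are then dropped.
#'
#' @param counts Genes x cells sparse count matrix.
#' @param min_umi UMI threshold (exclusive; default 1000).
#' @param min_genes Detected-gene threshold (exclusive; default 500).
#' @param max_mito_fraction Mitochondrial fraction threshold (exclusive;
#'   default 0.05).
#' @param min_cells_per_gene Detection threshold for genes (inclusive;
#'   default 3).
#' @param mito_genes Explicit mitochondrial gene ids, or `NULL` to use
#'   `mito_prefix`.
#' @param mito_prefix Prefix identifying mitochondrial genes (default
#'   `"MT-"`).
#' @return List with `counts` (filtered matrix) and `report` (cells/genes
#'   removed per criterion).
#' @export
qc_filter <- function(counts, min_umi = 1000, min_genes = 500,
                      max_mito_fraction = 0.05, min_cells_per_gene = 3,
                      mito_genes = NULL, mito_prefix = "MT-") {
  stopifnot(min_umi >= 0, min_genes >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  if (is.null(mito_genes)) {
    mito_genes <- grep(paste0("^", mito_prefix), rownames(counts), value = TRUE)
  }
  umi <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) /
      pmax(umi, 1)
  } else {
    rep(0, ncol(counts))
  }
  keep_umi <- umi > min_umi
  keep_genes <- ngene > min_genes
  keep_mito <- mito < max_mito_fraction
  keep_cell <- keep_umi & keep_genes & keep_mito
  if (!any(keep_cell)) {
    stop("QC removed every cell (UMI fail: ", sum(!keep_umi),
         ", gene fail: ", sum(!keep_genes),
         ", mito fail: ", sum(!keep_mito), ")")
  }
  out <- counts[, keep_cell, drop = FALSE]
  detected <- Matrix::rowSums(out > 0)
  keep_gene <- detected >= min_cells_per_gene
  out <- out[keep_gene, , drop = FALSE]
  list(counts = out,
       report = list(
         cells_in = ncol(counts), cells_out = ncol(out),
         removed_umi = sum(!keep_umi),
         removed_genes_detected = sum(!keep_genes),
         removed_mito = sum(!keep_mito),
         removed_cells = sum(!keep_cell),
         genes_in = nrow(counts), genes_out = nrow(out),
         removed_low_detection_genes = sum(!keep_gene)))
}

#' Log-normalize a count matrix
#'
#' Each cell's counts are divided by its total, multiplied by
#' `scale_factor` (10,000) and natural-log transformed with a pseudo-count
#' of 1: `ln(1 + scale_factor * c / C)`. Zeros map to zero, so sparsity is
#' preserved.
#'
#' @param counts Genes x cells sparse count matrix; all cell totals must be
#'   positive.
#' @param scale_factor Scale factor (default 1e4).
#' @return A sparse matrix of normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot <= 0)) {
    stop("zero-total cell(s) at column(s) ",
         paste(utils::head(which(tot <= 0)), collapse = ", "),
         "; run qc_filter first")
  }
  m <- methods::as(counts, "CsparseMatrix")
  fac <- scale_factor / tot
  j <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * fac[j])
  m
}

#' Mean-signature score per cell
#'
#' The mean log-normalized expression of a gene set in each cell.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param gene_set Character vector of gene ids.
#' @return Numeric vector of per-cell scores with attribute `coverage`
#'   (fraction of the set present in the matrix).
#' @export
signature_score <- function(normalized, gene_set) {
  present <- intersect(gene_set, rownames(normalized))
  if (!length(present)) {
    stop("none of the ", length(gene_set), " signature genes are in the matrix")
  }
  s <- Matrix::colMeans(normalized[present, , drop = FALSE])
  attr(s, "coverage") <- length(present) / length(gene_set)
  s
}

#' Derive marker gene sets from grouped profiles by log fold-change
#'
#' For each group, ranks genes by the log fold-change of the group's mean
#' (normalized) expression against the mean of all other groups, with a
#' pseudo-count guarding against zero means, and returns the top `n_top`
#' genes. Ties at the rank boundary break by gene-id lexical order.
#'
#' @param normalized Genes x samples (or cells) matrix.
#' @param group_labels Group label per column (>= 2 groups).
#' @param n_top Markers per group (default 100).
#' @param pseudo_count Added to both means (default 0.01).
#' @return Named list of character vectors, one per group.
#' @export
derive_bulk_markers <- function(normalized, group_labels, n_top = 100,
                                pseudo_count = 0.01) {
  groups <- unique(as.character(group_labels))
  if (length(groups) < 2) stop("need >= 2 groups")
  if (n_top > nrow(normalized)) {
    warning("n_top exceeds gene count; returning all genes")
    n_top <- nrow(normalized)
  }
  out <- list()
  for (g in groups) {
    in_g <- group_labels == g
    lfc <- log((Matrix::rowMeans(normalized[, in_g, drop = FALSE]) + pseudo_count) /
               (Matrix::rowMeans(normalized[, !in_g, drop = FALSE]) + pseudo_count))
    ord <- order(-lfc, rownames(normalized))
    out[[g]] <- rownames(normalized)[ord[seq_len(n_top)]]
  }
  out
}

#' Principal-component embedding oriented by signature scores
#'
#' PCA on the per-gene standardized (clipped at +/-`clip`) top-variance
#' genes. The two leading components are then matched and sign-oriented
#' against the mesenchymal (M) and liver-progenitor (LP) signature scores:
#' of PC1/PC2, the component better correlated (in absolute value) with the
#' M score becomes the M axis (reported as PC1) with positive correlation,
#' and the other becomes the LP-H axis (PC2) with positive LP correlation.
#' This removes the sign/order indeterminacy of PCA so that fixed numeric
#' thresholds on PC1/PC2 are meaningful.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param m_score,lp_score Per-cell signature scores used for orientation;
#'   when `NULL` the axes keep their PCA order and arbitrary signs.
#' @param n_hvg Number of highly variable genes (default 3000, capped at the
#'   gene count).
#' @param n_components Number of components to return (default 10).
#' @param clip Standardization clip bound (default 10).
#' @return List of class `hb_embedding` with `scores` (cells x components),
#'   `loadings`, `sdev`, and the orientation correlations.
#' @export
compute_embedding <- function(normalized, m_score = NULL, lp_score = NULL,
                              n_hvg = 3000, n_components = 10, clip = 10) {
  n_hvg <- min(n_hvg, nrow(normalized))
  v <- rowVars_sparse(normalized)
  if (all(v == 0)) stop("degenerate matrix: all genes constant")
  hvg <- order(-v)[seq_len(n_hvg)]
  hvg <- hvg[v[hvg] > 0]
  x <- as.matrix(Matrix::t(normalized[hvg, , drop = FALSE]))
  x <- scale(x)
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  n_components <- min(n_components, ncol(x), nrow(x) - 1)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- pc$x
  loadings <- pc$rotation
  sdev <- pc$sdev[seq_len(n_components)]
  cor_m <- cor_lp <- NA_real_
  if (!is.null(m_score) && !is.null(lp_score) && n_components >= 2) {
    c1 <- c(stats::cor(scores[, 1], m_score), stats::cor(scores[, 1], lp_score))
    c2 <- c(stats::cor(scores[, 2], m_score), stats::cor(scores[, 2], lp_score))
    # match axes: the leading component most correlated with M is the M axis
    if (abs(c2[1]) > abs(c1[1])) {
      scores[, 1:2] <- scores[, 2:1]
      loadings[, 1:2] <- loadings[, 2:1]
      sdev[1:2] <- sdev[2:1]
    }
    s1 <- sign(stats::cor(scores[, 1], m_score))
    s2 <- sign(stats::cor(scores[, 2], lp_score))
    if (s1 < 0) { scores[, 1] <- -scores[, 1]; loadings[, 1] <- -loadings[, 1] }
    if (s2 < 0) { scores[, 2] <- -scores[, 2]; loadings[, 2] <- -loadings[, 2] }
    cor_m <- stats::cor(scores[, 1], m_score)
    cor_lp <- stats::cor(scores[, 2], lp_score)
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- colnames(normalized)
  structure(list(scores = scores, loadings = loadings, sdev = sdev,
                 cor_m = cor_m, cor_lp = cor_lp),
            class = "hb_embedding")
}

rowVars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}

#' Classify tumor nuclei into differentiation states
#'
#' Cells with PC1 above `pc1_m_cutoff` are mesenchymal (`scM`). The
#' remaining epithelial cells are split along PC2: below `pc2_low` is `scH`,
#' above `pc2_high` is `scLP`, and the inclusive band in between is the
#' intermediate `scH/LP`. Thresholds may be given in raw score units
#' (`units = "raw"`) or in per-axis standard deviations (`units = "sd"`).
#' The PC1 cutoff defaults to the largest gap in the PC1 distribution, the
#' data-driven reading of "high PC1" when no printed value exists.
#'
#' @param embedding An oriented `hb_embedding`.
#' @param pc2_low,pc2_high PC2 thresholds (defaults -15 / +15, raw units).
#' @param pc1_m_cutoff PC1 cutoff for `scM`, or `NULL` for the largest-gap
#'   default.
#' @param units `"raw"` or `"sd"`.
#' @return Factor of labels `scH`, `scH/LP`, `scLP`, `scM`, one per cell.
#' @export
classify_states <- function(embedding, pc2_low = -15, pc2_high = 15,
                            pc1_m_cutoff = NULL, units = c("raw", "sd")) {
  units <- match.arg(units)
  if (ncol(embedding$scores) < 2) stop("embedding must have at least 2 components")
  if (pc2_low >= pc2_high) stop("pc2_low must be < pc2_high")
  pc1 <- embedding$scores[, 1]
  pc2 <- embedding$scores[, 2]
  if (units == "sd") {
    pc2_low <- pc2_low * stats::sd(pc2)
    pc2_high <- pc2_high * stats::sd(pc2)
    if (!is.null(pc1_m_cutoff)) pc1_m_cutoff <- pc1_m_cutoff * stats::sd(pc1)
  }
  if (is.null(pc1_m_cutoff)) pc1_m_cutoff <- largest_gap_cutoff(pc1)
  lab <- ifelse(pc1 > pc1_m_cutoff, "scM",
                ifelse(pc2 < pc2_low, "scH",
                       ifelse(pc2 > pc2_high, "scLP", "scH/LP")))
  factor(lab, levels = c("scH", "scH/LP", "scLP", "scM"))
}

# Midpoint of the widest gap between consecutive sorted values, restricted
# to the upper half of the range so a multimodal lower tail cannot hijack
# the cutoff.
largest_gap_cutoff <- function(x) {
  s <- sort(x)
  gaps <- diff(s)
  upper <- s[-length(s)] > stats::median(x)
  if (!any(upper)) return(max(x) + 1)
  i <- which(upper)[which.max(gaps[upper])]
  (s[i] + s[i + 1]) / 2
}

#' Flag cycling cells
#'
#' A cell is cycling when the mean normalized expression over the union of
#' the G2/M and S phase gene sets reaches `cutoff` (inclusive).
#'
#' @param normalized Genes x cells normalized matrix.
#' @param g2m_set,s_set Phase marker gene sets.
#' @param cutoff Inclusive score cutoff (default 0.15).
#' @return Logical vector, one per cell.
#' @export
flag_cycling <- function(normalized, g2m_set, s_set, cutoff = 0.15) {
  union_set <- union(g2m_set, s_set)
  s <- signature_score(normalized, union_set)
  as.vector(s >= cutoff)
}

#' Aggregate cells into metacells
#'
#' Partitions cells into small transcriptionally homogeneous groups by
#' k-means on the leading principal components, then averages any per-cell
#' quantity within groups. Aggregation reduces the dropout-driven sparsity
#' of single-cell profiles.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param embedding Optional precomputed `hb_embedding`; computed (unoriented)
#'   when `NULL`.
#' @param target_count Number of metacells (default ~1 per 100 cells, at
#'   least 2).
#' @param n_pcs Components used for clustering.
#' @param seed Seed for k-means.
#' @return List with `map` (metacell id per cell), `profiles` (genes x
#'   metacells mean matrix) and `sizes`.
#' @export
build_metacells <- function(normalized, embedding = NULL, target_count = NULL,
                            n_pcs = 20, seed = 1L) {
  n_cells <- ncol(normalized)
  if (is.null(target_count)) target_count <- max(2L, round(n_cells / 100))
  if (target_count > n_cells) stop("target_count exceeds number of cells")
  if (is.null(embedding)) {
    embedding <- compute_embedding(normalized, n_components = n_pcs)
  }
  x <- embedding$scores[, seq_len(min(n_pcs, ncol(embedding$scores))), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(x, centers = target_count, iter.max = 100, nstart = 5)
  map <- km$cluster
  names(map) <- colnames(normalized)
  profiles <- aggregate_by_metacell(normalized, map)
  list(map = map, profiles = profiles,
       sizes = as.vector(table(map)))
}

#' Average a matrix or per-cell vector over a metacell map
#'
#' @param x Genes x cells matrix or a per-cell numeric vector.
#' @param map Metacell id per cell (named or in column order).
#' @return Genes x metacells matrix, or a per-metacell vector.
#' @export
aggregate_by_metacell <- function(x, map) {
  f <- factor(map)
  if (is.null(dim(x))) {
    tapply(x, f, mean)
  } else {
    ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                                dims = c(length(f), nlevels(f)))
    ind <- ind %*% Matrix::Diagonal(x = 1 / Matrix::colSums(ind))
    out <- as.matrix(x %*% ind)
    colnames(out) <- levels(f)
    out
  }
}
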