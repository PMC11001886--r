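#' Assign mutations to tree branches from per-sample cancer cell fractions
#'
#' A mutation is truncal when its CCF reaches `trunk_ccf_min` in every
#' sample; it belongs to the subclone of sample k when its CCF reaches
#' `presence_min` in sample k and stays below `absence_max` in every other
#' sample. Mutations matching neither pattern are reported unassigned.
#'
#' @param ccf Data frame with columns `mutation` and one CCF column per
#'   sample, or a matrix with mutations in rows and samples in columns.
#' @param trunk_ccf_min Trunk threshold (default 0.8).
#' @param presence_min Presence threshold (default 0.3).
#' @param absence_max Absence threshold (default 0.05).
#' @return Data frame with `mutation` and `branch` (`"trunk"`,
#'   `"subclone-<sample>"` or `"unassigned"`).
#' @export
assign_mutations_to_branches <- function(ccf, trunk_ccf_min = 0.8,
                                         presence_min = 0.3,
                                         absence_max = 0.05) {
  if (is.data.frame(ccf)) {
    if (!"mutation" %in% names(ccf)) stop("missing `mutation` column")
    m <- as.matrix(ccf[setdiff(names(ccf), "mutation")])
    rownames(m) <- ccf$mutation
  } else {
    m <- as.matrix(ccf)
  }
  if (ncol(m) < 1) stop("missing sample column")
  if (any(m < 0 | m > 1.25, na.rm = TRUE)) {
    stop("CCF outside the tolerated [0, 1.25] range")
  }
  branch <- apply(m, 1, function(x) {
    if (all(x >= trunk_ccf_min)) return("trunk")
    present <- x >= presence_min
    absent <- x < absence_max
    if (sum(present) == 1 && all(absent[!present])) {
      return(paste0("subclone-", colnames(m)[present]))
    }
    "unassigned"
  })
  data.frame(mutation = rownames(m), branch = unname(branch),
             stringsAsFactors = FALSE)
}

#' Approximate CCF from VAF for diploid heterozygous sites
#'
#' `ccf = min(1, 2 * VAF / purity)`. Approximate: assumes a diploid,
#' copy-number-neutral heterozygous site; do not use inside CNAs.
#'
#' @param vaf Variant allele fraction.
#' @param purity Tumor purity in (0, 1].
#' @return Approximate cancer cell fractions.
#' @export
ccf_from_vaf <- function(vaf, purity) {
  stopifnot(purity > 0, purity <= 1)
  pmin(1, 2 * vaf / purity)
}

#' Virtual copy-number profiles from raw expression counts
#'
#' A deliberately minimal re-implementation of expression-based CNA
#' inference: genes with mean raw count > `min_ref_mean` in the reference
#' cells are kept; per-cell log2 ratios against the reference mean are
#' centered per cell, smoothed by a centered moving average over `window`
#' genome-ordered genes within each chromosome, and clamped.
#'
#' @param counts Genes x cells raw count matrix.
#' @param gene_coords Data frame with `gene`, `chrom`, `tss`.
#' @param reference_cells Cell ids of the diploid reference population.
#' @param window Moving-average width in genes (odd; default 101).
#' @param clamp Clamp bound in log2 units, or `NULL` to use 3x the SD of the
#'   reference cells' smoothed profiles.
#' @param min_ref_mean Reference-mean expression filter (default 0.1,
#'   exclusive).
#' @return List with `profile` (kept genes x cells smoothed log2-ratio
#'   matrix, genome-ordered) and `genes` (their coordinates).
#' @export
smooth_virtual_cna <- function(counts, gene_coords, reference_cells,
                               window = 101, clamp = NULL,
                               min_ref_mean = 0.1) {
  if (window < 1) stop("window must be >= 1")
  ref <- intersect(reference_cells, colnames(counts))
  if (!length(ref)) stop("no reference cells present in the matrix")
  ref_mean <- Matrix::rowMeans(counts[, ref, drop = FALSE])
  keep <- ref_mean > min_ref_mean
  gc <- gene_coords[match(rownames(counts)[keep], gene_coords$gene), ]
  ord <- order(gc$chrom, gc$tss)
  genes <- rownames(counts)[keep][ord]
  gc <- gc[ord, ]
  # library-size normalize so depth differences don't mimic CNAs
  depth <- Matrix::colSums(counts)
  norm <- sweep(as.matrix(counts[genes, , drop = FALSE]), 2,
                mean(depth) / depth, "*")
  ref_norm_mean <- rowMeans(norm[, ref, drop = FALSE])
  lr <- log2(norm + 1) - log2(ref_norm_mean + 1)
  lr <- sweep(lr, 2, colMeans(lr), "-")
  smoothed <- lr
  for (ch in unique(gc$chrom)) {
    idx <- which(gc$chrom == ch)
    w <- min(window, length(idx))
    if (w %% 2 == 0) w <- w - 1
    if (w >= 3) {
      k <- rep(1 / w, w)
      sm <- apply(lr[idx, , drop = FALSE], 2, function(x) {
        as.numeric(stats::filter(x, k, sides = 2))
      })
      # shrink the window near chromosome edges instead of dropping to NA
      half <- (w - 1) / 2
      cs <- apply(lr[idx, , drop = FALSE], 2, cumsum)
      ni <- length(idx)
      for (i in seq_len(ni)) {
        if (is.na(sm[i, 1])) {
          lo <- max(1, i - half); hi <- min(ni, i + half)
          lower <- if (lo > 1) cs[lo - 1, ] else 0
          sm[i, ] <- (cs[hi, ] - lower) / (hi - lo + 1)
        }
      }
      smoothed[idx, ] <- sm
    }
  }
  if (is.null(clamp)) {
    clamp <- 3 * stats::sd(smoothed[, ref])
  }
  smoothed[smoothed > clamp] <- clamp
  smoothed[smoothed < -clamp] <- -clamp
  list(profile = smoothed, genes = gc, clamp = clamp)
}

#' Cluster virtual CNA profiles
#'
#' Hierarchical clustering on correlation distance (1 - Pearson) with
#' Ward linkage, cut into `k` clusters. Deterministic given the input.
#'
#' @param profile Genes x cells smoothed profile matrix.
#' @param k Number of clusters.
#' @param linkage Linkage method (default `"ward.D2"`).
#' @return Named integer vector of cluster ids per cell; attribute
#'   `degenerate` flags an (arbitrary but deterministic) split of identical
#'   profiles.
#' @export
cluster_cna_profiles <- function(profile, k = 2, linkage = "ward.D2") {
  n <- ncol(profile)
  if (n < 2) stop("need >= 2 cells")
  if (k > n) stop("k exceeds number of cells")
  cc <- suppressWarnings(stats::cor(profile))
  degenerate <- any(!is.finite(cc))
  cc[!is.finite(cc)] <- 1
  d <- stats::as.dist(1 - cc)
  cl <- stats::cutree(stats::hclust(d, method = linkage), k = k)
  names(cl) <- colnames(profile)
  attr(cl, "degenerate") <- degenerate || all(d < 1e-12)
  cl
}

#' Map cells to subclones from branch mutations and CNA clusters
#'
#' A cell with ALT reads from exactly one subclone branch is assigned to
#' that subclone; reads from more than one mutually exclusive branch mark
#' it ambiguous; a cell with no subclone-branch reads falls back to its CNA
#' cluster when the cluster maps uniquely to a branch, and is unassigned
#' otherwise.
#'
#' @param branch_calls Cells x branches logical matrix from
#'   [detect_mutations()] (subclone branches only; trunk columns are
#'   ignored for assignment).
#' @param subclone_branches Character vector naming the mutually exclusive
#'   subclone branch columns.
#' @param cna_clusters Optional named cluster vector from
#'   [cluster_cna_profiles()].
#' @param cluster_to_branch Optional named character vector mapping CNA
#'   cluster ids to branch labels for the fallback.
#' @return Data frame with `cell_id`, `branch` (`"ambiguous"`/
#'   `"unassigned"` possible) and `evidence` (`"mutation"`, `"cna"`, or
#'   `"none"`).
#' @export
assign_cells_to_subclones <- function(branch_calls, subclone_branches,
                                      cna_clusters = NULL,
                                      cluster_to_branch = NULL) {
  miss <- setdiff(subclone_branches, colnames(branch_calls))
  if (length(miss)) {
    stop("tree spec references unknown branch(es): ",
         paste(miss, collapse = ", "))
  }
  bc <- branch_calls[, subclone_branches, drop = FALSE]
  nhit <- rowSums(bc)
  branch <- rep("unassigned", nrow(bc))
  evidence <- rep("none", nrow(bc))
  one <- nhit == 1
  branch[one] <- subclone_branches[apply(bc[one, , drop = FALSE], 1, which.max)]
  evidence[one] <- "mutation"
  branch[nhit > 1] <- "ambiguous"
  evidence[nhit > 1] <- "mutation"
  if (!is.null(cna_clusters) && !is.null(cluster_to_branch)) {
    fb <- which(nhit == 0)
    cl <- cna_clusters[rownames(bc)[fb]]
    mapped <- cluster_to_branch[as.character(cl)]
    ok <- !is.na(mapped)
    branch[fb[ok]] <- mapped[ok]
    evidence[fb[ok]] <- "cna"
  }
  data.frame(cell_id = rownames(bc), branch = branch, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Compare phenotypes between genetic subclones
#'
#' For each subclone: the PC2 distribution, the cycling and cancer-stem-cell
#' (CSC) fractions with 95% exact binomial confidence intervals, and the
#' mean DNA-repair signature score. Pairwise two-sided tests: Wilcoxon
#' rank-sum for PC2 and the DNA-repair score, Fisher's exact test on 2x2
#' tables for the cycling and CSC proportions. Subclones with fewer than 2
#' cells are excluded with a warning.
#'
#' @param assignment Data frame with `cell_id` and `branch`.
#' @param pc2 Named per-cell PC2 scores.
#' @param cycling Named per-cell logical cycling flags.
#' @param csc Named per-cell logical CSC flags.
#' @param dna_repair Named per-cell DNA-repair signature scores.
#' @return List with `summary` (one row per subclone) and `tests` (one row
#'   per subclone pair and phenotype).
#' @export
compare_subclone_phenotypes <- function(assignment, pc2, cycling, csc,
                                        dna_repair) {
  keep <- !assignment$branch %in% c("ambiguous", "unassigned")
  asg <- assignment[keep, , drop = FALSE]
  sizes <- table(asg$branch)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("subclone(s) with < 2 cells excluded: ",
            paste(small, collapse = ", "))
    asg <- asg[!asg$branch %in% small, , drop = FALSE]
  }
  branches <- sort(unique(asg$branch))
  if (length(branches) < 2) stop("need >= 2 subclones with >= 2 cells")
  by_branch <- split(asg$cell_id, asg$branch)
  ci <- function(x, n) {
    if (n == 0) return(c(NA, NA))
    stats::binom.test(x, n)$conf.int
  }
  summ <- do.call(rbind, lapply(branches, function(b) {
    cells <- by_branch[[b]]
    n <- length(cells)
    cyc <- sum(cycling[cells]); cs <- sum(csc[cells])
    ci_c <- ci(cyc, n); ci_s <- ci(cs, n)
    data.frame(branch = b, n = n,
               pc2_median = stats::median(pc2[cells]),
               cycling_fraction = cyc / n,
               cycling_ci_lo = ci_c[1], cycling_ci_hi = ci_c[2],
               csc_fraction = cs / n,
               csc_ci_lo = ci_s[1], csc_ci_hi = ci_s[2],
               dna_repair_mean = mean(dna_repair[cells]),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(branches, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- by_branch[[pr[1]]]; b <- by_branch[[pr[2]]]
    w_pc2 <- stats::wilcox.test(pc2[a], pc2[b])$p.value
    w_dnr <- stats::wilcox.test(dna_repair[a], dna_repair[b])$p.value
    f_cyc <- stats::fisher.test(matrix(c(sum(cycling[a]), sum(!cycling[a]),
                                         sum(cycling[b]), sum(!cycling[b])),
                                       2))$p.value
    f_csc <- stats::fisher.test(matrix(c(sum(csc[a]), sum(!csc[a]),
                                         sum(csc[b]), sum(!csc[b])),
                                       2))$p.value
    data.frame(branch_a = pr[1], branch_b = pr[2],
               p_pc2 = w_pc2, p_cycling = f_cyc, p_csc = f_csc,
               p_dna_repair = w_dnr, stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
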