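test_that("CCF patterns route mutations to trunk, subclone or unassigned", {
  ccf <- data.frame(mutation = paste0("m", 1:5),
                    S1 = c(0.9, 0.80, 0.5, 0.04, 0.2),
                    S2 = c(1.0, 0.85, 0.04, 0.31, 0.2))
  out <- assign_mutations_to_branches(ccf)
  expect_identical(out$branch,
                   c("trunk", "trunk",          # 0.8 is inclusive for trunk
                     "subclone-S1",             # present S1, absent S2
                     "subclone-S2",             # 0.31 >= 0.3, 0.04 < 0.05
                     "unassigned"))             # present nowhere
  # a CCF at exactly the absence threshold is not absent (strict <)
  ccf2 <- data.frame(mutation = "m", S1 = 0.5, S2 = 0.05)
  expect_identical(assign_mutations_to_branches(ccf2)$branch, "unassigned")
  expect_error(assign_mutations_to_branches(
    data.frame(mutation = "m", S1 = 1.3)), "1.25")
  expect_error(assign_mutations_to_branches(data.frame(mutation = "m")),
               "sample")
})

test_that("CCF from VAF doubles the fraction, caps at 1 and scales by purity", {
  expect_equal(ccf_from_vaf(0.25, 1), 0.5)
  expect_equal(ccf_from_vaf(0.25, 0.5), 1)
  expect_equal(ccf_from_vaf(0.8, 1), 1)
  expect_error(ccf_from_vaf(0.2, 0), "purity")
})

cna_fixture <- function() {
  set.seed(41)
  n_genes <- 300; n_ref <- 20; n_tum <- 40
  genes <- sprintf("g%03d", seq_len(n_genes))
  cells <- c(sprintf("ref%02d", seq_len(n_ref)), sprintf("tum%02d", seq_len(n_tum)))
  lambda <- matrix(5, n_genes, n_ref + n_tum)
  seg <- 101:200
  lambda[seg, n_ref + seq_len(n_tum)] <- 10       # 2-fold gain in tumor cells
  counts <- matrix(rpois(length(lambda), lambda), n_genes,
                   dimnames = list(genes, cells))
  coords <- data.frame(gene = genes, chrom = "chr1", tss = seq_len(n_genes) * 1e6)
  list(counts = counts, coords = coords, ref = cells[seq_len(n_ref)],
       tum = cells[n_ref + seq_len(n_tum)], seg = seg)
}

test_that("virtual CNA profiles recover a planted gain against reference cells", {
  fx <- cna_fixture()
  cna <- smooth_virtual_cna(fx$counts, fx$coords, fx$ref, window = 51,
                            clamp = 1.5)
  prof <- cna$profile
  in_seg <- cna$genes$gene %in% rownames(fx$counts)[fx$seg]
  tum_in <- mean(prof[in_seg, fx$tum])
  tum_out <- mean(prof[!in_seg, fx$tum])
  expect_gt(tum_in - tum_out, 0.5)
  # reference cells carry no signal anywhere
  expect_lt(max(abs(colMeans(prof[, fx$ref]))), 0.05)
  expect_lt(mean(abs(prof[in_seg, fx$ref])), 0.1)
  # the data-driven default clamp bounds the profile at 3 reference SDs
  cna0 <- smooth_virtual_cna(fx$counts, fx$coords, fx$ref, window = 51)
  expect_equal(cna0$clamp, 3 * stats::sd(cna$profile[, fx$ref]),
               tolerance = 1e-10)
  expect_lte(max(abs(cna0$profile)), cna0$clamp + 1e-12)
  expect_error(smooth_virtual_cna(fx$counts, fx$coords, "nope"), "reference")
})

test_that("wider smoothing windows reduce profile noise on null data", {
  set.seed(42)
  counts <- matrix(rpois(200 * 30, 5), 200,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:30)))
  coords <- data.frame(gene = rownames(counts), chrom = "chr1",
                       tss = seq_len(200) * 1e6)
  ref <- colnames(counts)[1:10]
  narrow <- smooth_virtual_cna(counts, coords, ref, window = 5, clamp = 10)
  wide <- smooth_virtual_cna(counts, coords, ref, window = 75, clamp = 10)
  expect_lt(stats::var(as.numeric(wide$profile)),
            stats::var(as.numeric(narrow$profile)))
})

test_that("CNA clustering separates carrier cells from reference cells", {
  fx <- cna_fixture()
  cna <- smooth_virtual_cna(fx$counts, fx$coords, fx$ref, window = 51,
                            clamp = 1.5)
  cl <- cluster_cna_profiles(cna$profile, k = 2)
  expect_false(attr(cl, "degenerate"))
  tab <- table(cl[fx$tum])
  expect_gte(max(tab) / sum(tab), 0.95)
  expect_false(names(which.max(table(cl[fx$tum]))) ==
                 names(which.max(table(cl[fx$ref]))))
  # identical profiles are flagged degenerate
  flat <- matrix(rep(c(1, 2, 3), 4), 3, 4,
                 dimnames = list(NULL, paste0("c", 1:4)))
  cl2 <- cluster_cna_profiles(flat, k = 2)
  expect_true(attr(cl2, "degenerate"))
  expect_error(cluster_cna_profiles(cna$profile, k = 1000), "exceeds")
})

test_that("cells map to subclones by exclusive reads with a CNA fallback", {
  calls <- matrix(FALSE, 5, 3,
                  dimnames = list(paste0("c", 1:5), c("trunk", "b1", "b2")))
  calls["c1", "b1"] <- TRUE
  calls["c2", "b2"] <- TRUE
  calls["c3", c("b1", "b2")] <- TRUE
  calls[, "trunk"] <- TRUE                    # trunk reads never disambiguate
  asg <- assign_cells_to_subclones(calls, c("b1", "b2"),
                                   cna_clusters = c(c4 = 1, c5 = 2),
                                   cluster_to_branch = c("1" = "b1"))
  expect_identical(asg$branch, c("b1", "b2", "ambiguous", "b1", "unassigned"))
  expect_identical(asg$evidence, c("mutation", "mutation", "mutation",
                                   "cna", "none"))
  expect_error(assign_cells_to_subclones(calls, c("b1", "b9")), "b9")
})

test_that("phenotype comparison contrasts subclones with exact and rank tests", {
  set.seed(43)
  cells <- sprintf("c%03d", 1:61)
  asg <- data.frame(cell_id = cells,
                    branch = c(rep("b1", 30), rep("b2", 30), "tiny"))
  pc2 <- stats::setNames(c(rnorm(30, -5), rnorm(30, 5), 0), cells)
  cycling <- stats::setNames(c(rep(TRUE, 3), rep(FALSE, 27),
                               rep(TRUE, 15), rep(FALSE, 15), FALSE), cells)
  csc <- stats::setNames(rep(c(FALSE, TRUE), c(31, 30)), cells)
  dnr <- stats::setNames(c(rnorm(30, 0), rnorm(30, 1), 0), cells)
  expect_warning(res <- compare_subclone_phenotypes(asg, pc2, cycling, csc, dnr),
                 "tiny")
  s <- res$summary
  expect_identical(s$branch, c("b1", "b2"))
  expect_equal(s$cycling_fraction, c(0.1, 0.5))
  # the exact binomial CI brackets the observed fraction
  expect_true(all(s$cycling_ci_lo <= s$cycling_fraction &
                    s$cycling_fraction <= s$cycling_ci_hi))
  t <- res$tests
  expect_lt(t$p_pc2, 1e-6)
  expect_lt(t$p_csc, 1e-6)
  expect_lt(t$p_cycling, 0.01)
  expect_true(all(t[, c("p_pc2", "p_cycling", "p_csc", "p_dna_repair")] >= 0 &
                    t[, c("p_pc2", "p_cycling", "p_csc", "p_dna_repair")] <= 1))
})
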