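# Shared simulated fixtures, built once per test run and cached.

.hb_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .hb_cache, inherits = FALSE)) {
    assign(key, expr, envir = .hb_cache)
  }
  get(key, envir = .hb_cache, inherits = FALSE)
}

# full-size cohort: 6 subclones x 500 cells + 200 reference nuclei
hb_sim_full <- function() {
  with_cache("sim_full", simulate_multiome(sim_config(seed = 7)))
}

# small cohort for structural tests
hb_sim_small <- function() {
  with_cache("sim_small", simulate_multiome(
    sim_config(seed = 2, cells_per_subclone = 30, n_genes = 900,
               n_peaks = 500, n_ref_cells = 30)))
}

# expression-state chain on the full cohort (tumor cells only)
hb_states_full <- function() {
  with_cache("states_full", {
    sim <- hb_sim_full()
    tr <- sim$truth$cells
    tum <- tr$cell_id[tr$tumor]
    norm <- log_normalize(sim$rna)[, tum]
    mb <- sim$truth$marker_blocks
    emb <- compute_embedding(norm,
                             m_score = signature_score(norm, mb$M),
                             lp_score = signature_score(norm, mb$LP))
    labels <- classify_states(emb, pc2_low = -0.5, pc2_high = 0.5,
                              units = "sd")
    list(sim = sim, tumor_cells = tum, norm = norm, emb = emb,
         labels = labels, truth = tr[match(tum, tr$cell_id), ])
  })
}

# GRN chain on the full cohort (metacells, deviations, metrics, links)
hb_grn_full <- function() {
  with_cache("grn_full", {
    st <- hb_states_full()
    sim <- st$sim
    mc <- build_metacells(st$norm, embedding = st$emb, target_count = 100,
                          seed = 2)
    occ <- split(sim$truth$motif_occupancy$peak, sim$truth$motif_occupancy$tf)
    z <- motif_deviations(sim$atac[, st$tumor_cells], occ, seed = 3)
    agg_expr <- aggregate_by_metacell(st$norm, mc$map)
    agg_dev <- aggregate_by_metacell(t(z), mc$map)
    agg_atac <- aggregate_by_metacell(log1p(sim$atac[, st$tumor_cells]), mc$map)
    pc1 <- aggregate_by_metacell(st$emb$scores[, 1], mc$map)
    pc2 <- aggregate_by_metacell(st$emb$scores[, 2], mc$map)
    links <- peak_to_gene_links(agg_expr, agg_atac, sim$gene_coords, sim$peaks)
    list(sim = sim, st = st, mc = mc, deviations = z, agg_expr = agg_expr,
         agg_dev = agg_dev, agg_atac = agg_atac, pc1 = pc1, pc2 = pc2,
         links = links)
  })
}

# a tiny hand-made embedding for threshold tests
fake_embedding <- function(pc1, pc2) {
  structure(list(scores = cbind(PC1 = pc1, PC2 = pc2),
                 loadings = NULL, sdev = c(2, 1),
                 cor_m = 1, cor_lp = 1),
            class = "hb_embedding")
}
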