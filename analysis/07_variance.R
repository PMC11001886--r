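# Variance decomposition: how much of the leading expression structure the
# differentiation state and the sample of origin explain.
#
# Regresses each of the first five principal components on categorical
# covariates and reports the variance-weighted R-squared; the difference
# between the nested models is the share attributable to the sample.
# Writes results/variance.tsv.

source("analysis/00_common.R")

covars <- data.frame(
  state = as.character(state),
  sample = truth$sample[match(tumor_cells, truth$cell_id)])

# Full-cohort caveat: the mesenchymal sample coincides exactly with scM, so
# a joint state + sample fit is singular there (pc_regression_r2 refuses
# the collinear design). Single-covariate models use the whole cohort; the
# nested comparison runs on the epithelial samples, where states vary
# within each sample.
v_state <- weighted_variance_explained(emb$scores, covars["state"], k = 5)
v_sample <- weighted_variance_explained(emb$scores, covars["sample"], k = 5)

epi <- covars$sample %in% c("S1", "S2")
v_epi_state <- weighted_variance_explained(emb$scores[epi, ],
                                           covars[epi, "state", drop = FALSE],
                                           k = 5)
v_epi_both <- weighted_variance_explained(emb$scores[epi, ],
                                          covars[epi, ], k = 5)

out <- data.frame(
  model = c("state (all nuclei)", "sample (all nuclei)",
            "state (epithelial)", "state + sample (epithelial)",
            "sample added (epithelial)"),
  weighted_r2 = c(v_state$weighted_r2, v_sample$weighted_r2,
                  v_epi_state$weighted_r2, v_epi_both$weighted_r2,
                  v_epi_both$weighted_r2 - v_epi_state$weighted_r2))
write_tsv(out, "variance.tsv")
print(out, row.names = FALSE)

percomp <- data.frame(component = paste0("PC", 1:5),
                      variance = v_state$variances,
                      r2_state = v_state$r2, r2_sample = v_sample$r2)
write_tsv(percomp, "variance_per_component.tsv")
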