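# Validation of one IRES-specific hit, MAPK3-style: efficiency-corrected
# qPCR relative expression (Pfaffl ratio, REST-style randomization test)
# and a secreted-protein ELISA compared with the equal-variance t-test.

source("analysis/00_config.R")

cfg <- screen_config()

# knockdown efficacy: target mRNA reduced to ~25% of control
qpcr <- simulate_qpcr(cfg, true_ratio = 0.25, efficiency = 2,
                      n_per_group = 6, ct_sd = 0.1,
                      target_gene = "HIT_KINASE", reference_gene = "ACTB")
utils::write.csv(qpcr, file.path(RESULTS_DIR, "qpcr.csv"), row.names = FALSE)
ratio <- rest_randomization(qpcr, n_iterations = 2000, seed = SCREEN_SEED)
message("target mRNA, relative to scrambled control, beta-actin reference:")
print(ratio)

# secreted protein under hypoxia: ~25% reduction on depletion of the hit
elisa <- simulate_elisa(cfg, control_mean = 100, percent_reduction = 0.25,
                        n_per_group = 6)
utils::write.csv(elisa, file.path(RESULTS_DIR, "elisa.csv"), row.names = FALSE)
tt <- t_test_equal_var(elisa$concentration[elisa$group == "treated"],
                       elisa$concentration[elisa$group == "control"])
change <- percent_change(tt$group_means[1], tt$group_means[2])
message(sprintf("ELISA: %.1f%% change in secreted protein (treated vs control)",
                100 * change))
print(tt)

validation <- data.frame(
  assay = c("qpcr_ratio", "qpcr_p", "elisa_change_pct", "elisa_p"),
  value = c(ratio$ratio, ratio$p_value, 100 * change, tt$p_value)
)
utils::write.csv(validation, file.path(RESULTS_DIR, "validation.csv"),
                 row.names = FALSE)
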