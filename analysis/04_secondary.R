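# Secondary screen of the primary hits: IRES-specificity against the
# cap-driven reporter and viability via the ATP channel.

source("analysis/00_config.R")

hits <- tibble::as_tibble(utils::read.csv(file.path(RESULTS_DIR, "hits.csv")))
truth <- utils::read.csv(file.path(DATA_DIR, "ground_truth.csv"))
cfg <- screen_config()

sec_sim <- simulate_secondary_screen(cfg, hits$gene_symbol[hits$hit])
sec <- run_secondary(hits, sec_sim$measurements, sec_sim$layouts,
                     cutoffs = cutoff_pair(), cap_tolerance = 0.25,
                     viability_floor = 0.70)
utils::write.csv(sec$results, file.path(RESULTS_DIR, "secondary.csv"),
                 row.names = FALSE)

message(sprintf("secondary: %d tested, %d confirmed, %d IRES-specific, %d specific + viable",
                sec$summary$tested, sec$summary$confirmed,
                sec$summary$ires_specific, sec$summary$specific_viable))
survivors <- sec$results$gene_symbol[sec$results$specific_hit]
expected <- truth$gene_symbol[truth$ires_specific & !truth$toxic]
message(sprintf("specific hits: %s (planted IRES-specific non-toxic set: %s)",
                paste(survivors, collapse = ", "),
                paste(expected, collapse = ", ")))
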