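# Simulate the primary screen and write its raw artifacts: the siRNA
# library, the plate layouts and the per-well luminescence table.

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

cfg <- screen_config()
print(cfg)
sim <- simulate_primary_screen(cfg)

write_library(sim$library, file.path(DATA_DIR, "library.csv"))
write_layouts(sim$layouts, file.path(DATA_DIR, "layout.csv"))
write_measurements(sim$measurements, file.path(DATA_DIR, "measurements.csv"))
utils::write.csv(sim$ground_truth, file.path(DATA_DIR, "ground_truth.csv"),
                 row.names = FALSE)

message(sprintf("library: %d reagents over %d genes (%d kinases, %d phosphatases)",
                nrow(sim$library), cfg$n_genes,
                sum(sim$library$gene_class == "kinase") / cfg$sirnas_per_gene,
                sum(sim$library$gene_class == "phosphatase") / cfg$sirnas_per_gene))
message(sprintf("plates: %d (each with %d scrambled + %d positive-control wells)",
                length(unique(sim$layouts$plate_id)),
                cfg$n_neg_controls_per_plate,
                cfg$n_fluc_controls_per_plate + cfg$n_plk1_controls_per_plate))
message(sprintf("measurements: %d wells", nrow(sim$measurements)))
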