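# Normalize raw luminescence to the percent-of-control scale (scrambled
# median = 100 per plate) and aggregate triplicates to per-siRNA scores.

source("analysis/00_config.R")

layouts <- read_layouts(file.path(DATA_DIR, "layout.csv"))
measurements <- read_measurements(file.path(DATA_DIR, "measurements.csv"))

normalized <- normalize_screen(measurements, layouts)
utils::write.csv(normalized, file.path(RESULTS_DIR, "normalized.csv"),
                 row.names = FALSE)

scores <- reaction_scores(normalized, layouts, min_replicates = 2)
utils::write.csv(scores, file.path(RESULTS_DIR, "reactions.csv"),
                 row.names = FALSE)

scr <- merge(normalized,
             layouts[layouts$content_type == "scrambled_control",
                     c("plate_id", "well")])
anchors <- tapply(scr$normalized_value, scr$plate_id, stats::median)
message(sprintf("scrambled-control anchor: median %.1f on all %d plates (range %.6g-%.6g)",
                stats::median(anchors), length(anchors),
                min(anchors), max(anchors)))
message(sprintf("reaction scores: %d (%d usable), median %.1f%% of control",
                nrow(scores), sum(scores$usable),
                stats::median(scores$score)))
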