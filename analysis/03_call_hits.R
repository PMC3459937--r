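# Call per-siRNA Up/Down directions at the 250/80 cut-offs and gene-level
# hits by >= 2-siRNA concordance; score recovery against the planted truth.

source("analysis/00_config.R")

scores <- tibble::as_tibble(
  utils::read.csv(file.path(RESULTS_DIR, "reactions.csv")))
library_tbl <- read_library(file.path(DATA_DIR, "library.csv"))
truth <- utils::read.csv(file.path(DATA_DIR, "ground_truth.csv"))

freq <- frequency_distribution(scores$score[scores$usable], bin_width = 20)
utils::write.csv(freq, file.path(RESULTS_DIR, "score_histogram.csv"),
                 row.names = FALSE)

cp <- cutoff_pair(up_cutoff = 250, down_cutoff = 80)
print(cp)
calls <- call_reactions(scores, cp)
hits <- call_genes(calls, library_tbl)
utils::write.csv(calls, file.path(RESULTS_DIR, "calls.csv"), row.names = FALSE)
utils::write.csv(hits, file.path(RESULTS_DIR, "hits.csv"), row.names = FALSE)

summ <- summarize_screen(calls, hits)
jsonlite::write_json(summ, file.path(RESULTS_DIR, "screen_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("affected genes (>= 1 reaction beyond a cut-off): %d",
                summ$n_affected))
message(sprintf("concordant hits: %d (%s) - %d negative, %d positive regulators",
                summ$n_hits,
                paste(sprintf("%s: %d", names(summ$hits_by_class),
                              unlist(summ$hits_by_class)), collapse = ", "),
                summ$n_negative_regulators, summ$n_positive_regulators))
message(sprintf("hit rates: %.2f%% of reactions, %.2f%% of genes",
                100 * summ$reaction_call_rate, 100 * summ$gene_hit_rate))

planted <- truth[truth$true_sign != "none", ]
merged <- merge(planted, hits, by = "gene_symbol", all.x = TRUE)
sens <- mean(merged$hit & merged$regulator_sign == merged$true_sign,
             na.rm = TRUE)
message(sprintf("planted-regulator recovery: %.0f%% of %d, correctly signed",
                100 * sens, nrow(planted)))
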