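# End-to-end driver: simulate (or load) -> normalize -> call -> secondary
# -> annotate, writing every tabular artifact, a JSON summary and a
# plain-text report with the score histogram.

render_histogram <- function(freq, width = 50L) {
  scale <- max(freq$count, 1L)
  bars <- vapply(freq$count, function(n) {
    paste(rep("#", max(0L, round(width * n / scale))), collapse = "")
  }, character(1))
  sprintf("  [%7.1f, %7.1f) %6d %s", freq$bin_lo, freq$bin_hi,
          freq$count, bars)
}

pipeline_stage <- function(stage, expr) {
  message("[", stage, "] starting")
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full screen analysis pipeline
#'
#' Simulates a primary and secondary screen from `config`, normalizes,
#' calls per-siRNA directions and gene-level concordance hits, filters
#' hits for IRES specificity and viability, annotates hit genes, and
#' writes all artifacts under `output_dir`: `library.csv`, `layout.csv`,
#' `measurements.csv`, `normalized.csv`, `reactions.csv`, `calls.csv`,
#' `hits.csv`, `secondary.csv`, `summary.json` and `report.txt` (with the
#' frequency-distribution histogram and every threshold used). Identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [simulation_config()] object or the path to a YAML file
#'   readable by [read_config()].
#' @param output_dir Directory for the artifacts (created if needed).
#' @param cutoffs A [cutoff_pair()]; default the fixed 250/80 pair.
#' @param calibrate If `TRUE`, ignore `cutoffs` and calibrate from the
#'   score distribution via [calibrate_cutoffs()] at `target_hit_rate`.
#' @param target_hit_rate Hit-rate budget for calibration (default 0.10).
#' @param cap_tolerance,viability_floor Secondary-screen thresholds, see
#'   [evaluate_secondary()].
#' @param min_replicates Minimum replicates per usable reaction (default 2).
#' @param term_map Optional gene-to-group mapping for [assign_group()];
#'   when `NULL` all hit genes are reported as `unknown`.
#' @param bin_width Histogram bin width for the report (default 20).
#' @return Invisibly, a list with every intermediate table and the summary.
#' @export
run_pipeline <- function(config, output_dir,
                         cutoffs = cutoff_pair(), calibrate = FALSE,
                         target_hit_rate = 0.10,
                         cap_tolerance = 0.25, viability_floor = 0.70,
                         min_replicates = 2L, term_map = NULL,
                         bin_width = 20) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(output_dir, f)

  sim <- pipeline_stage("simulate", simulate_primary_screen(config))
  write_library(sim$library, path("library.csv"))
  write_layouts(sim$layouts, path("layout.csv"))
  write_measurements(sim$measurements, path("measurements.csv"))

  normalized <- pipeline_stage(
    "normalize", normalize_screen(sim$measurements, sim$layouts))
  utils::write.csv(normalized, path("normalized.csv"), row.names = FALSE)

  scores <- pipeline_stage(
    "aggregate", reaction_scores(normalized, sim$layouts, min_replicates))
  utils::write.csv(scores, path("reactions.csv"), row.names = FALSE)

  if (calibrate) {
    cutoffs <- pipeline_stage(
      "calibrate",
      calibrate_cutoffs(scores$score[scores$usable], target_hit_rate))
  }
  message(sprintf("[call] cut-offs: up >= %g, down <= %g (%s)",
                  cutoffs$up_cutoff, cutoffs$down_cutoff, cutoffs$derivation))
  calls <- pipeline_stage("call", call_reactions(scores, cutoffs))
  utils::write.csv(calls, path("calls.csv"), row.names = FALSE)
  hits <- pipeline_stage("call", call_genes(calls, sim$library))
  utils::write.csv(hits, path("hits.csv"), row.names = FALSE)
  screen_summary <- summarize_screen(calls, hits)

  hit_genes <- hits$gene_symbol[hits$hit]
  secondary <- NULL
  if (length(hit_genes) > 0L) {
    sec_sim <- pipeline_stage(
      "secondary", simulate_secondary_screen(config, hit_genes))
    secondary <- pipeline_stage(
      "secondary",
      run_secondary(hits, sec_sim$measurements, sec_sim$layouts,
                    cutoffs = cutoffs, cap_tolerance = cap_tolerance,
                    viability_floor = viability_floor))
    utils::write.csv(secondary$results, path("secondary.csv"),
                     row.names = FALSE)
  } else {
    message("[secondary] no hits to re-test")
  }

  annotation <- NULL
  if (length(hit_genes) > 0L) {
    tm <- if (is.null(term_map)) list() else term_map
    annotation <- pipeline_stage("annotate", group_summary(hit_genes, tm))
    utils::write.csv(annotation, path("annotation.csv"), row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    cutoffs = list(up = cutoffs$up_cutoff, down = cutoffs$down_cutoff,
                   derivation = cutoffs$derivation),
    thresholds = list(cap_tolerance = cap_tolerance,
                      viability_floor = viability_floor,
                      min_replicates = min_replicates),
    primary = screen_summary,
    secondary = if (is.null(secondary)) NULL else secondary$summary,
    untested_secondary = if (is.null(secondary)) character(0)
                         else secondary$untested
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  freq <- frequency_distribution(scores$score[scores$usable], bin_width)
  report <- c(
    "Screen analysis report",
    "======================",
    sprintf("genes: %d; reactions scored: %d (usable: %d)",
            config$n_genes, nrow(scores), sum(scores$usable)),
    sprintf("cut-offs: up >= %g, down <= %g (%s; target hit rate %.0f%%)",
            cutoffs$up_cutoff, cutoffs$down_cutoff, cutoffs$derivation,
            100 * cutoffs$target_hit_rate),
    sprintf("secondary thresholds: cap within +/-%g of 100, viability >= %g",
            cap_tolerance * 100, viability_floor * 100),
    "",
    "Frequency distribution of reaction scores (% of control):",
    render_histogram(freq),
    "",
    sprintf("affected genes (>= 1 reaction beyond a cut-off): %d",
            screen_summary$n_affected),
    sprintf("concordant hits (>= 2 siRNAs same direction): %d (%d negative, %d positive regulators)",
            screen_summary$n_hits, screen_summary$n_negative_regulators,
            screen_summary$n_positive_regulators),
    sprintf("per-reaction call rate: %.2f%%; per-gene hit rate: %.2f%%",
            100 * screen_summary$reaction_call_rate,
            100 * screen_summary$gene_hit_rate),
    if (!is.null(secondary)) {
      sprintf("secondary: %d tested, %d confirmed, %d IRES-specific, %d specific+viable",
              secondary$summary$tested, secondary$summary$confirmed,
              secondary$summary$ires_specific,
              secondary$summary$specific_viable)
    } else "secondary: not run (no hits)"
  )
  writeLines(report, path("report.txt"))

  invisible(list(
    config = config, simulation = sim, normalized = normalized,
    scores = scores, cutoffs = cutoffs, calls = calls, hits = hits,
    secondary = secondary, annotation = annotation, summary = summary
  ))
}
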