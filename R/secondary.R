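# Secondary screen: primary hits are re-tested against the IRES reporter,
# a cap-driven reporter (specificity control) and ATP content (viability).
# A hit is confirmed when its IRES-channel score is again beyond the
# primary cut-offs in the primary direction; it is IRES-specific when the
# cap channel stays near control level; it survives when additionally the
# ATP channel stays above the viability floor.

#' Evaluate one gene's secondary-screen profile
#'
#' @param ires_score,cap_score,viability_score Per-gene scores on the
#'   percent-of-control scale (100 = control level) for the IRES-reporter,
#'   cap-reporter and ATP channels.
#' @param primary_direction `"up"` or `"down"`, the gene's primary-screen
#'   hit direction.
#' @param cutoffs A [cutoff_pair()]; confirmation reuses the primary
#'   cut-offs on the IRES channel.
#' @param cap_tolerance "No effect on the cap reporter" means
#'   `|cap_score - 100| <= cap_tolerance * 100` (default 0.25).
#' @param viability_floor "No effect on viability" means
#'   `viability_score >= viability_floor * 100` (default 0.70).
#' @return A one-row tibble with the three scores and logical `confirmed`,
#'   `ires_specific`, `viable`, `specific_hit` columns
#'   (`specific_hit = confirmed & ires_specific & viable`).
#' @export
evaluate_secondary <- function(ires_score, cap_score, viability_score,
                               primary_direction, cutoffs = cutoff_pair(),
                               cap_tolerance = 0.25, viability_floor = 0.70) {
  stopifnot(inherits(cutoffs, "cutoff_pair"),
            primary_direction %in% c("up", "down"),
            cap_tolerance >= 0, viability_floor >= 0)
  for (ch in c("ires_score", "cap_score", "viability_score")) {
    v <- get(ch)
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("missing secondary channel: ", sub("_score", "", ch), call. = FALSE)
    }
  }
  confirmed <- if (primary_direction == "up") {
    ires_score >= cutoffs$up_cutoff
  } else {
    ires_score <= cutoffs$down_cutoff
  }
  ires_specific <- confirmed && abs(cap_score - 100) <= cap_tolerance * 100
  viable <- viability_score >= viability_floor * 100
  tibble::tibble(
    ires_score = ires_score, cap_score = cap_score,
    viability_score = viability_score,
    primary_direction = primary_direction,
    confirmed = confirmed, ires_specific = ires_specific, viable = viable,
    specific_hit = confirmed && ires_specific && viable
  )
}

#' Run the secondary screen over all primary hits
#'
#' Normalizes the secondary measurements per plate x channel, aggregates
#' each hit gene's wells per channel (median of all normalized values of
#' its siRNA wells across replicate plates), and applies
#' [evaluate_secondary()] per gene. Hit genes without secondary
#' measurements are reported in `untested`, never silently dropped.
#'
#' @param hits Output of [call_genes()]; only rows with `hit = TRUE` are
#'   re-tested.
#' @param measurements,layouts Secondary-screen tables, e.g. from
#'   [simulate_secondary_screen()].
#' @param cutoffs A [cutoff_pair()].
#' @param cap_tolerance,viability_floor See [evaluate_secondary()].
#' @return A list with `results` (one row per tested gene), `untested`
#'   (character vector) and `summary` (counts: tested, confirmed,
#'   ires_specific, specific_viable).
#' @export
run_secondary <- function(hits, measurements, layouts,
                          cutoffs = cutoff_pair(),
                          cap_tolerance = 0.25, viability_floor = 0.70) {
  hit_tbl <- hits[hits$hit, c("gene_symbol", "direction")]
  if (nrow(hit_tbl) == 0L) {
    return(list(
      results = tibble::tibble(gene_symbol = character(0)),
      untested = character(0),
      summary = list(tested = 0L, confirmed = 0L, ires_specific = 0L,
                     specific_viable = 0L)
    ))
  }
  normalized <- normalize_screen(measurements, layouts)
  gene_wells <- layouts[layouts$content_type == "gene",
                        c("plate_id", "well", "gene_symbol")]
  per_gene <- dplyr::inner_join(normalized, gene_wells,
                                by = c("plate_id", "well")) |>
    dplyr::group_by(.data$gene_symbol, .data$channel) |>
    dplyr::summarise(score = stats::median(.data$normalized_value),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "score")

  tested <- dplyr::inner_join(hit_tbl, per_gene, by = "gene_symbol")
  untested <- setdiff(hit_tbl$gene_symbol, tested$gene_symbol)
  for (ch in c("fluc_ires", "fluc_cap", "atp")) {
    if (!ch %in% names(tested)) tested[[ch]] <- NA_real_
  }
  results <- dplyr::bind_rows(lapply(seq_len(nrow(tested)), function(i) {
    row <- tested[i, ]
    out <- evaluate_secondary(
      ires_score = row$fluc_ires, cap_score = row$fluc_cap,
      viability_score = row$atp, primary_direction = row$direction,
      cutoffs = cutoffs, cap_tolerance = cap_tolerance,
      viability_floor = viability_floor
    )
    dplyr::bind_cols(tibble::tibble(gene_symbol = row$gene_symbol), out)
  }))
  list(
    results = results,
    untested = untested,
    summary = list(
      tested = nrow(results),
      confirmed = sum(results$confirmed),
      ires_specific = sum(results$ires_specific),
      specific_viable = sum(results$specific_hit)
    )
  )
}
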