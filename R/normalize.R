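# Percent-of-control normalization: every raw value on a plate is expressed
# relative to the median of that plate's scrambled-siRNA negative-control
# wells, which is set to 100. Controls are normalized too, so the anchoring
# invariant (scrambled median == 100 on every plate x channel) is directly
# checkable on the output.

#' Median of a plate's scrambled-control wells
#'
#' Computes the raw-scale normalization anchor for one plate and channel:
#' the median of the scrambled-control well measurements (midpoint of the
#' two central values for even counts). A plate without any measured
#' scrambled well, or with a zero control median, is unusable.
#'
#' @param measurements Measurements tibble for (at least) the plate of
#'   interest (`plate_id`, `well`, `channel`, `raw_value`).
#' @param layout Layout tibble covering the plate.
#' @param plate_id Plate identifier.
#' @param channel Measurement channel (default `"fluc_ires"`).
#' @return The control median, a positive scalar.
#' @export
plate_control_median <- function(measurements, layout, plate_id,
                                 channel = "fluc_ires") {
  scr_wells <- layout$well[layout$plate_id == plate_id &
                             layout$content_type == "scrambled_control"]
  vals <- measurements$raw_value[measurements$plate_id == plate_id &
                                   measurements$channel == channel &
                                   measurements$well %in% scr_wells]
  if (length(vals) == 0L) {
    stop("plate ", plate_id, " (channel ", channel,
         ") has no measured scrambled-control well; plate unusable",
         call. = FALSE)
  }
  m <- stats::median(vals)
  if (m <= 0) {
    stop("control median is not positive on plate ", plate_id,
         " (channel ", channel, ")", call. = FALSE)
  }
  m
}

control_median_table <- function(measurements, layouts) {
  scr <- layouts[layouts$content_type == "scrambled_control",
                 c("plate_id", "well")]
  ctrl <- dplyr::inner_join(measurements, scr, by = c("plate_id", "well"))
  medians <- ctrl |>
    dplyr::group_by(.data$plate_id, .data$channel) |>
    dplyr::summarise(control_median = stats::median(.data$raw_value),
                     n_controls = dplyr::n(), .groups = "drop")
  present <- unique(measurements[, c("plate_id", "channel")])
  missing <- dplyr::anti_join(present, medians, by = c("plate_id", "channel"))
  if (nrow(missing) > 0L) {
    stop("no measured scrambled-control wells on plate(s): ",
         paste(sprintf("%s/%s", missing$plate_id, missing$channel),
               collapse = ", "), call. = FALSE)
  }
  if (any(medians$control_median <= 0)) {
    bad <- medians[medians$control_median <= 0, ]
    stop("non-positive control median on plate(s): ",
         paste(sprintf("%s/%s", bad$plate_id, bad$channel), collapse = ", "),
         call. = FALSE)
  }
  medians
}

#' Normalize raw measurements to the percent-of-control scale
#'
#' Divides every well (controls included) by its plate's scrambled-control
#' median and multiplies by 100, per plate and channel. After
#' normalization the median of the scrambled wells is exactly 100 on every
#' plate x channel, and rescaling all raw values of a plate by any positive
#' constant leaves the output unchanged.
#'
#' `normalize_plate()` is the single-plate convenience wrapper.
#'
#' @param measurements Measurements tibble (`plate_id`, `well`, `channel`,
#'   `raw_value`).
#' @param layouts Layout tibble covering every plate present.
#' @return A tibble with columns `plate_id`, `well`, `channel`,
#'   `normalized_value`.
#' @export
normalize_screen <- function(measurements, layouts) {
  medians <- control_median_table(measurements, layouts)
  out <- dplyr::inner_join(measurements, medians,
                           by = c("plate_id", "channel"))
  tibble::tibble(
    plate_id = out$plate_id,
    well = out$well,
    channel = out$channel,
    normalized_value = out$raw_value / out$control_median * 100
  )
}

#' @rdname normalize_screen
#' @param plate_id Single plate to normalize (defaults to the only plate in
#'   `measurements`).
#' @export
normalize_plate <- function(measurements, layouts, plate_id = NULL) {
  if (is.null(plate_id)) {
    plate_id <- unique(measurements$plate_id)
    if (length(plate_id) != 1L) {
      stop("measurements cover several plates; pass plate_id", call. = FALSE)
    }
  }
  normalize_screen(measurements[measurements$plate_id == plate_id, ], layouts)
}

#' Aggregate replicate values of one reaction into its score
#'
#' The score of a gene x siRNA x channel reaction is the median of its
#' normalized values across replicate plates. Reactions with fewer than
#' `min_replicates` contributing values are flagged unusable and excluded
#' from hit calling downstream.
#'
#' @param values Numeric vector of normalized replicate values (>= 1).
#' @param min_replicates Minimum replicates for a usable score (default 2).
#' @return A list with `score`, `n_replicates_used` and `usable`.
#' @export
aggregate_replicates <- function(values, min_replicates = 2L) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no replicate values supplied", call. = FALSE)
  list(
    score = stats::median(values),
    n_replicates_used = length(values),
    usable = length(values) >= min_replicates
  )
}

#' Per-reaction scores for a whole screen
#'
#' Joins normalized measurements to the layout, keeps gene wells, and
#' aggregates each gene x siRNA x channel across replicate plates with
#' [aggregate_replicates()]. Unusable reactions (fewer than
#' `min_replicates` values) are kept in the table with `usable = FALSE` and
#' reported with a warning.
#'
#' @param normalized Output of [normalize_screen()].
#' @param layouts Layout tibble.
#' @param min_replicates Minimum replicates for a usable score (default 2).
#' @return A tibble with columns `gene_symbol`, `sirna_index`, `channel`,
#'   `score`, `n_replicates_used`, `usable`.
#' @export
reaction_scores <- function(normalized, layouts, min_replicates = 2L) {
  gene_wells <- layouts[layouts$content_type == "gene",
                        c("plate_id", "well", "gene_symbol", "sirna_index")]
  joined <- dplyr::inner_join(normalized, gene_wells,
                              by = c("plate_id", "well"))
  scores <- joined |>
    dplyr::group_by(.data$gene_symbol, .data$sirna_index, .data$channel) |>
    dplyr::summarise(score = stats::median(.data$normalized_value),
                     n_replicates_used = dplyr::n(), .groups = "drop")
  scores$usable <- scores$n_replicates_used >= min_replicates
  if (any(!scores$usable)) {
    bad <- scores[!scores$usable, ]
    warning(nrow(bad), " reaction(s) with fewer than ", min_replicates,
            " replicates flagged unusable: ",
            paste(utils::head(sprintf("%s/siRNA%d", bad$gene_symbol,
                                      bad$sirna_index), 5L),
                  collapse = ", "),
            if (nrow(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  scores
}
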