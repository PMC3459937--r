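# Hit calling: per-siRNA Up/Down calls against fixed or calibrated
# cut-offs on the percent-of-control scale, then gene-level hits by
# at-least-two-siRNA same-direction concordance. An Up hit (increased
# reporter signal on knockdown) implies a negative regulator of the IRES;
# a Down hit implies a positive regulator.

#' Construct an Up/Down cut-off pair
#'
#' The defaults (250 for Up, 80 for Down on the percent-of-control scale)
#' are the screen's published operating point, chosen to keep the hit rate
#' under 10%. Boundary values are inclusive: a score equal to a cut-off is
#' a call.
#'
#' @param up_cutoff Up cut-off (> 100), default 250.
#' @param down_cutoff Down cut-off (< 100), default 80.
#' @param target_hit_rate Hit-rate budget the pair is meant to respect
#'   (default 0.10).
#' @param derivation `"fixed"` or `"calibrated"`.
#' @return An object of class `cutoff_pair`.
#' @export
cutoff_pair <- function(up_cutoff = 250, down_cutoff = 80,
                        target_hit_rate = 0.10, derivation = "fixed") {
  stopifnot(is.numeric(up_cutoff), is.numeric(down_cutoff),
            target_hit_rate > 0, target_hit_rate < 1)
  if (!(down_cutoff < 100 && 100 < up_cutoff)) {
    stop("cut-offs must straddle the control level: down < 100 < up ",
         sprintf("(got down = %g, up = %g)", down_cutoff, up_cutoff),
         call. = FALSE)
  }
  derivation <- match.arg(derivation, c("fixed", "calibrated"))
  structure(
    list(up_cutoff = up_cutoff, down_cutoff = down_cutoff,
         target_hit_rate = target_hit_rate, derivation = derivation),
    class = "cutoff_pair"
  )
}

#' @export
print.cutoff_pair <- function(x, ...) {
  cat(sprintf("<cutoff_pair> up >= %g, down <= %g (%s, target hit rate %.0f%%)\n",
              x$up_cutoff, x$down_cutoff, x$derivation,
              100 * x$target_hit_rate))
  invisible(x)
}

#' Frequency distribution of reaction scores
#'
#' Histogram with half-open bins `[lo, hi)` anchored at `origin`; the last
#' bin is closed so counts always sum to the number of scores.
#'
#' @param scores Nonempty numeric vector.
#' @param bin_width Positive bin width.
#' @param origin Bin-grid origin (default 0).
#' @return A tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
frequency_distribution <- function(scores, bin_width, origin = 0) {
  if (length(scores) == 0L) stop("scores must be nonempty", call. = FALSE)
  stopifnot(is.numeric(scores), all(is.finite(scores)), bin_width > 0)
  lo <- origin + bin_width * floor((min(scores) - origin) / bin_width)
  hi <- origin + bin_width * ceiling((max(scores) - origin) / bin_width)
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(scores, breaks = breaks, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  tibble::tibble(
    bin_lo = utils::head(breaks, -1L),
    bin_hi = utils::tail(breaks, -1L),
    count = h$counts
  )
}

#' Calibrate Up/Down cut-offs from the score distribution
#'
#' Reconstructs a histogram-style calibration: place the Down cut-off at
#' the `q` quantile and the Up cut-off at the `1 - q` quantile with
#' `q = target_hit_rate / 2` (rank-symmetric tails), then round each
#' cut-off outward to the nearest multiple of `grid` (down towards zero,
#' up away from it), stepping further outward if inclusive boundaries
#' would leave either tail above `q`. The fraction of scores at or beyond
#' the returned cut-offs is therefore at most `target_hit_rate`.
#'
#' @param scores Nonempty numeric vector of reaction scores.
#' @param target_hit_rate Maximum acceptable fraction of calls (default
#'   0.10).
#' @param grid Rounding grid for the returned cut-offs (default 10,
#'   yielding round published-style values such as 250/80).
#' @return A `cutoff_pair` with `derivation = "calibrated"`.
#' @export
calibrate_cutoffs <- function(scores, target_hit_rate = 0.10, grid = 10) {
  if (length(scores) == 0L) stop("scores must be nonempty", call. = FALSE)
  stopifnot(target_hit_rate > 0, target_hit_rate < 1, grid > 0)
  scores <- scores[is.finite(scores)]
  if (diff(range(scores)) == 0) {
    stop("degenerate score distribution (all values equal); cannot calibrate",
         call. = FALSE)
  }
  q <- target_hit_rate / 2
  down <- grid * floor(stats::quantile(scores, q, type = 1, names = FALSE) / grid)
  while (mean(scores <= down) > q) down <- down - grid
  up <- grid * ceiling(stats::quantile(scores, 1 - q, type = 1, names = FALSE) / grid)
  while (mean(scores >= up) > q) up <- up + grid
  # cut-offs must straddle the control level; stepping further outward can
  # only shrink the tails, so the budget is preserved
  while (down >= 100) down <- down - grid
  while (up <= 100) up <- up + grid
  if (!(down < 100 && 100 < up)) {
    stop("calibrated cut-offs do not straddle the control level (100): ",
         sprintf("down = %g, up = %g", down, up), call. = FALSE)
  }
  cutoff_pair(up_cutoff = up, down_cutoff = down,
              target_hit_rate = target_hit_rate, derivation = "calibrated")
}

#' Direction call for reaction scores
#'
#' `"up"` for scores at or above the Up cut-off, `"down"` at or below the
#' Down cut-off, `"none"` otherwise.
#'
#' @param score Numeric vector of reaction scores.
#' @param cutoffs A [cutoff_pair()].
#' @return Character vector of directions.
#' @export
call_reaction <- function(score, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_pair"))
  ifelse(score >= cutoffs$up_cutoff, "up",
         ifelse(score <= cutoffs$down_cutoff, "down", "none"))
}

#' Direction calls for a reaction-score table
#'
#' Applies [call_reaction()] to every usable reaction of one channel.
#'
#' @param scores Output of [reaction_scores()].
#' @param cutoffs A [cutoff_pair()].
#' @param channel Channel to call (default `"fluc_ires"`).
#' @return The usable reactions of `channel` with a `direction` column.
#' @export
call_reactions <- function(scores, cutoffs, channel = "fluc_ires") {
  out <- scores[scores$channel == channel & scores$usable, ]
  out$direction <- call_reaction(out$score, cutoffs)
  out
}

#' Gene-level concordance call
#'
#' A gene is a hit when at least two of its usable siRNA reactions are
#' called in the same direction; mixed up/down support never yields a hit.
#' Up hits are negative regulators, Down hits positive regulators.
#'
#' @param directions Character vector of per-siRNA directions (`"up"`,
#'   `"down"`, `"none"`) for one gene; usable reactions only.
#' @return A list with `hit`, `direction` (`NA` when not a hit),
#'   `n_supporting_sirnas` and `regulator_sign`.
#' @export
call_gene <- function(directions) {
  stopifnot(all(directions %in% c("up", "down", "none")))
  n_up <- sum(directions == "up")
  n_down <- sum(directions == "down")
  # equal opposing support (impossible with 3 siRNAs) is not a hit
  hit <- max(n_up, n_down) >= 2L && n_up != n_down
  dir <- if (hit) { if (n_up > n_down) "up" else "down" } else NA_character_
  list(
    hit = hit,
    direction = dir,
    n_supporting_sirnas = max(n_up, n_down),
    regulator_sign = if (!hit) NA_character_
                     else if (dir == "up") "negative" else "positive"
  )
}

#' Gene-level hits for a whole screen
#'
#' Groups per-siRNA direction calls by gene and applies [call_gene()].
#'
#' @param calls Output of [call_reactions()].
#' @param gene_class Optional named vector or library tibble mapping genes
#'   to classes (kinase/phosphatase); attached when given.
#' @return A tibble with one row per gene: `gene_symbol`, `gene_class`,
#'   `hit`, `direction`, `n_supporting_sirnas`, `regulator_sign`,
#'   `n_usable_sirnas`.
#' @export
call_genes <- function(calls, gene_class = NULL) {
  hits <- calls |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      n_usable_sirnas = dplyr::n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
  hits$hit <- pmax(hits$n_up, hits$n_down) >= 2L & hits$n_up != hits$n_down
  hits$direction <- ifelse(!hits$hit, NA_character_,
                           ifelse(hits$n_up > hits$n_down, "up", "down"))
  hits$n_supporting_sirnas <- ifelse(
    hits$hit, pmax(hits$n_up, hits$n_down), pmax(hits$n_up, hits$n_down)
  )
  hits$regulator_sign <- ifelse(!hits$hit, NA_character_,
                                ifelse(hits$direction == "up",
                                       "negative", "positive"))
  hits$gene_class <- lookup_gene_class(hits$gene_symbol, gene_class)
  hits[, c("gene_symbol", "gene_class", "hit", "direction",
           "n_supporting_sirnas", "regulator_sign", "n_usable_sirnas")]
}

lookup_gene_class <- function(genes, gene_class) {
  if (is.null(gene_class)) return(rep(NA_character_, length(genes)))
  if (is.data.frame(gene_class)) {
    map <- gene_class[!duplicated(gene_class$gene_symbol), ]
    return(map$gene_class[match(genes, map$gene_symbol)])
  }
  unname(gene_class[genes])
}

#' Screen-level summary counts
#'
#' Tabulates, per gene class: genes "affected" (at least one usable
#' reaction beyond a cut-off), concordant hits, and hits by regulator
#' sign, plus the per-reaction and per-gene hit rates.
#'
#' @param calls Output of [call_reactions()].
#' @param hits Output of [call_genes()].
#' @return A list of summary counts and rates.
#' @export
summarize_screen <- function(calls, hits) {
  affected_genes <- unique(calls$gene_symbol[calls$direction != "none"])
  cls <- hits$gene_class
  cls[is.na(cls)] <- "unclassified"
  by_class <- function(genes) {
    table(factor(cls[match(genes, hits$gene_symbol)],
                 levels = unique(cls)))
  }
  hit_genes <- hits$gene_symbol[hits$hit]
  list(
    n_genes = nrow(hits),
    n_reactions = nrow(calls),
    n_affected = length(affected_genes),
    affected_by_class = as.list(by_class(affected_genes)),
    n_hits = length(hit_genes),
    hits_by_class = as.list(by_class(hit_genes)),
    n_negative_regulators = sum(hits$hit & hits$regulator_sign == "negative",
                                na.rm = TRUE),
    n_positive_regulators = sum(hits$hit & hits$regulator_sign == "positive",
                                na.rm = TRUE),
    reaction_call_rate = mean(calls$direction != "none"),
    gene_hit_rate = mean(hits$hit)
  )
}
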