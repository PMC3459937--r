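#' Build a screen simulation configuration
#'
#' Collects every parameter of the synthetic screen generator and validates
#' it. The defaults reproduce the geometry of the kinase/phosphatase screen
#' the package is modelled on: 96-well plates, three siRNAs per gene each
#' run on three replicate plates, four scrambled negative-control wells plus
#' FLuc and PLK1 positive-control wells per plate.
#'
#' All randomness downstream flows from `seed`: each generator stage uses a
#' fixed small offset from it (primary screen +0, secondary +101, qPCR +202,
#' ELISA +303), so stages are individually reproducible and mutually
#' independent.
#'
#' @param n_genes Number of genes in the library (>= 0).
#' @param sirnas_per_gene Independent siRNA reagents per gene (default 3).
#' @param replicate_plates Replicate plates per layout plate (default 3).
#' @param wells_per_plate Physical wells per plate (default 96, 8 x 12).
#' @param n_neg_controls_per_plate Scrambled-siRNA negative-control wells per
#'   plate (default 4); their median anchors normalization at 100.
#' @param n_fluc_controls_per_plate,n_plk1_controls_per_plate Positive-control
#'   wells per plate (defaults 1 and 1).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   well noise (default 0.15).
#' @param plate_effect_sd SD of the per-plate multiplicative effect on the
#'   log scale (default 0.10).
#' @param baseline_signal Mean raw luminescence of a neutral well (counts).
#' @param planted_regulators Optional tibble/data.frame describing planted
#'   effects, as returned by [plant_regulators()]: columns `gene`
#'   (integer index into the library or gene symbol), `effect_multiplier`
#'   (> 0; full-knockdown fold effect on the IRES reporter),
#'   `ires_specific` and `toxic` (logical).
#' @param knockdown_efficiency_range Two fractions in `[0, 1]`; each siRNA's
#'   knockdown efficiency is drawn uniformly from this range (default
#'   `c(0.70, 0.95)`).
#' @param kinase_fraction Fraction of library genes labelled kinase, the rest
#'   phosphatase (default 702/1000, the screened proportion).
#' @param fluc_control_effect Residual signal fraction of FLuc-siRNA
#'   positive-control wells (default 0.05).
#' @param plk1_control_effect Signal fraction of PLK1 positive-control wells
#'   on the luciferase channels (default 0.30).
#' @param toxic_viability ATP-channel signal fraction for toxic genes and the
#'   PLK1 control (default 0.25, the PLK1-like profile).
#' @param seed Integer master seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_primary_screen()], [plant_regulators()]
#' @export
simulation_config <- function(n_genes,
                              sirnas_per_gene = 3L,
                              replicate_plates = 3L,
                              wells_per_plate = 96L,
                              n_neg_controls_per_plate = 4L,
                              n_fluc_controls_per_plate = 1L,
                              n_plk1_controls_per_plate = 1L,
                              noise_cv = 0.15,
                              plate_effect_sd = 0.10,
                              baseline_signal = 1000,
                              planted_regulators = NULL,
                              knockdown_efficiency_range = c(0.70, 0.95),
                              kinase_fraction = 0.702,
                              fluc_control_effect = 0.05,
                              plk1_control_effect = 0.30,
                              toxic_viability = 0.25,
                              seed = 1L) {
  stopifnot(
    length(n_genes) == 1L, n_genes >= 0, n_genes == as.integer(n_genes),
    sirnas_per_gene >= 1, replicate_plates >= 1,
    wells_per_plate == 96L,
    n_neg_controls_per_plate >= 1,
    n_fluc_controls_per_plate >= 1,
    n_plk1_controls_per_plate >= 0,
    noise_cv >= 0, plate_effect_sd >= 0, baseline_signal > 0,
    length(knockdown_efficiency_range) == 2L,
    knockdown_efficiency_range[1] >= 0, knockdown_efficiency_range[2] <= 1,
    knockdown_efficiency_range[1] <= knockdown_efficiency_range[2],
    kinase_fraction >= 0, kinase_fraction <= 1,
    fluc_control_effect > 0, fluc_control_effect < 1,
    plk1_control_effect > 0,
    toxic_viability > 0, toxic_viability <= 1,
    length(seed) == 1L, is.finite(seed)
  )
  n_controls <- n_neg_controls_per_plate + n_fluc_controls_per_plate +
    n_plk1_controls_per_plate
  if (n_controls >= wells_per_plate) {
    stop("plate capacity overflow: ", n_controls, " control wells requested but ",
         "plates have only ", wells_per_plate, " wells (no sample wells left)",
         call. = FALSE)
  }

  planted <- normalize_planted(planted_regulators, n_genes)

  cfg <- list(
    n_genes = as.integer(n_genes),
    sirnas_per_gene = as.integer(sirnas_per_gene),
    replicate_plates = as.integer(replicate_plates),
    wells_per_plate = as.integer(wells_per_plate),
    n_neg_controls_per_plate = as.integer(n_neg_controls_per_plate),
    n_fluc_controls_per_plate = as.integer(n_fluc_controls_per_plate),
    n_plk1_controls_per_plate = as.integer(n_plk1_controls_per_plate),
    noise_cv = noise_cv,
    plate_effect_sd = plate_effect_sd,
    baseline_signal = baseline_signal,
    planted_regulators = planted,
    knockdown_efficiency_range = knockdown_efficiency_range,
    kinase_fraction = kinase_fraction,
    fluc_control_effect = fluc_control_effect,
    plk1_control_effect = plk1_control_effect,
    toxic_viability = toxic_viability,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Describe planted regulators for the simulator
#'
#' Convenience constructor for the `planted_regulators` table of
#' [simulation_config()]. `effect_multiplier` is the fold effect a complete
#' knockdown would have on the IRES reporter: values > 1 plant Up effects
#' (negative regulators of the IRES), values < 1 plant Down effects
#' (positive regulators). `ires_specific` regulators leave the cap-reporter
#' channel untouched in the secondary screen; `toxic` genes drag the ATP
#' viability channel down to the configured `toxic_viability` fraction.
#'
#' @param gene Integer index into the generated library (1-based) or gene
#'   symbol.
#' @param effect_multiplier Positive fold effect at complete knockdown.
#' @param ires_specific,toxic Logical flags, recycled as needed.
#' @return A tibble with one row per planted regulator.
#' @export
plant_regulators <- function(gene, effect_multiplier,
                             ires_specific = FALSE, toxic = FALSE) {
  tibble::tibble(
    gene = gene,
    effect_multiplier = effect_multiplier,
    ires_specific = ires_specific,
    toxic = toxic
  )
}

# Coerce planted_regulators input to a canonical tibble and validate it.
normalize_planted <- function(planted, n_genes) {
  if (is.null(planted) || (is.data.frame(planted) && nrow(planted) == 0L)) {
    return(plant_regulators(integer(0), numeric(0))[0, ])
  }
  stopifnot(is.data.frame(planted))
  planted <- tibble::as_tibble(planted)
  if (!"ires_specific" %in% names(planted)) planted$ires_specific <- FALSE
  if (!"toxic" %in% names(planted)) planted$toxic <- FALSE
  required <- c("gene", "effect_multiplier", "ires_specific", "toxic")
  missing <- setdiff(required, names(planted))
  if (length(missing) > 0L) {
    stop("planted_regulators lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(planted$effect_multiplier)) ||
      any(planted$effect_multiplier <= 0)) {
    stop("planted effect_multiplier values must be positive", call. = FALSE)
  }
  if (anyDuplicated(planted$gene)) {
    stop("each planted regulator must appear exactly once", call. = FALSE)
  }
  if (is.numeric(planted$gene)) {
    if (any(planted$gene < 1 | planted$gene > n_genes)) {
      stop("planted gene index outside 1..n_genes", call. = FALSE)
    }
    planted$gene <- as.integer(planted$gene)
  }
  planted[required]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d (%d siRNAs each, %d replicate plates)\n",
              x$n_genes, x$sirnas_per_gene, x$replicate_plates))
  cat(sprintf("  controls/plate: %d scrambled, %d FLuc, %d PLK1\n",
              x$n_neg_controls_per_plate, x$n_fluc_controls_per_plate,
              x$n_plk1_controls_per_plate))
  cat(sprintf("  noise_cv: %.3g, plate_effect_sd: %.3g, baseline: %g\n",
              x$noise_cv, x$plate_effect_sd, x$baseline_signal))
  cat(sprintf("  planted regulators: %d, knockdown U(%.2f, %.2f), seed: %d\n",
              nrow(x$planted_regulators), x$knockdown_efficiency_range[1],
              x$knockdown_efficiency_range[2], x$seed))
  invisible(x)
}

#' Load a simulation configuration from a YAML file
#'
#' The YAML file carries scalar fields named after the arguments of
#' [simulation_config()]; `planted_regulators` is a list of mappings with
#' keys `gene`, `effect_multiplier`, `ires_specific`, `toxic`.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_regulators)) {
    raw$planted_regulators <- dplyr::bind_rows(lapply(
      raw$planted_regulators,
      function(p) plant_regulators(
        gene = p$gene,
        effect_multiplier = p$effect_multiplier,
        ires_specific = isTRUE(p$ires_specific),
        toxic = isTRUE(p$toxic)
      )
    ))
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(simulation_config, raw)
}
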