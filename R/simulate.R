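# Synthetic screen generator. The signal model is multiplicative:
#   raw = baseline * plate_effect * gene_effect * lognormal noise
# with gene_effect = 1 + k * (m - 1) for a gene planted with full-knockdown
# effect multiplier m and a per-siRNA knockdown efficiency k. Neutral genes
# have m = 1 and therefore gene_effect = 1 whatever k is.

# Stage offsets for the single-master-seed stream-splitting scheme.
.SEED_OFFSETS <- c(library = 11L, primary = 0L, secondary = 101L,
                   qpcr = 202L, elisa = 303L)

sub_seed <- function(config, stage) {
  (config$seed + .SEED_OFFSETS[[stage]]) %% 2147483647L
}

# Log-normal noise factors with mean 1 and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

well_addresses <- function() {
  paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))
}

random_sirna_duplex <- function(n) {
  sense <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), 21L, replace = TRUE), collapse = "")
  }, character(1))
  comp <- chartr("ACGU", "UGCA", sense)
  antisense <- vapply(strsplit(comp, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1))
  list(sense = sense, antisense = antisense)
}

#' Generate the synthetic siRNA library for a configuration
#'
#' Builds the reagent table (three siRNA duplexes per gene by default) with
#' synthetic gene symbols, RefSeq-style identifiers, random 21-nt duplexes,
#' and a kinase/phosphatase class split in the configured proportion.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()] object.
#' @return A tibble with columns `gene_symbol`, `refseq_id`, `sirna_index`,
#'   `sense_seq`, `antisense_seq`, `gene_class`.
#' @export
make_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  s <- config$sirnas_per_gene
  if (g == 0L) {
    return(tibble::tibble(
      gene_symbol = character(0), refseq_id = character(0),
      sirna_index = integer(0), sense_seq = character(0),
      antisense_seq = character(0), gene_class = character(0)
    ))
  }
  set.seed(sub_seed(config, "library"))
  genes <- sprintf("G%04d", seq_len(g))
  n_kin <- round(g * config$kinase_fraction)
  classes <- c(rep("kinase", n_kin), rep("phosphatase", g - n_kin))
  lib <- tidyr::expand_grid(
    gene_symbol = genes,
    sirna_index = seq_len(s)
  )
  duplex <- random_sirna_duplex(nrow(lib))
  lib$refseq_id <- sprintf("NM_%06d", match(lib$gene_symbol, genes) + 100000L)
  lib$sense_seq <- duplex$sense
  lib$antisense_seq <- duplex$antisense
  lib$gene_class <- classes[match(lib$gene_symbol, genes)]
  lib[, c("gene_symbol", "refseq_id", "sirna_index",
          "sense_seq", "antisense_seq", "gene_class")]
}

# Resolve planted regulator identifiers (index or symbol) to gene symbols.
resolve_planted <- function(config, genes) {
  planted <- config$planted_regulators
  if (nrow(planted) == 0L) {
    planted$gene_symbol <- character(0)
    return(planted)
  }
  if (is.numeric(planted$gene)) {
    planted$gene_symbol <- genes[planted$gene]
  } else {
    bad <- setdiff(planted$gene, genes)
    if (length(bad) > 0L) {
      stop("planted regulator gene(s) not in library: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    planted$gene_symbol <- planted$gene
  }
  planted
}

# Per-plate control-well block placed at the end of the plate in row-major
# order (fixed positions; the layout table is the source of truth downstream).
control_block <- function(config) {
  tibble::tibble(content_type = c(
    rep("scrambled_control", config$n_neg_controls_per_plate),
    rep("fluc_control", config$n_fluc_controls_per_plate),
    rep("plk1_control", config$n_plk1_controls_per_plate)
  ))
}

# Lay out reactions siRNA-major (all siRNA-1 reactions, then siRNA-2, ...)
# so a gene's reactions land on different plate sets and share no control
# wells: each is an independent reaction, as in the screen design.
build_layouts <- function(config, reactions) {
  wells <- well_addresses()
  ctrl <- control_block(config)
  capacity <- config$wells_per_plate - nrow(ctrl)
  sample_wells <- wells[seq_len(capacity)]
  ctrl_wells <- wells[capacity + seq_len(nrow(ctrl))]

  n_layout <- max(1L, ceiling(nrow(reactions) / capacity))
  if (nrow(reactions) > 0L) {
    reactions$layout_plate <- ((seq_len(nrow(reactions)) - 1L) %/% capacity) + 1L
    reactions$well <- sample_wells[((seq_len(nrow(reactions)) - 1L) %% capacity) + 1L]
  } else {
    reactions$layout_plate <- integer(0)
    reactions$well <- character(0)
  }

  per_plate <- lapply(seq_len(n_layout), function(p) {
    genes_p <- reactions[reactions$layout_plate == p,
                         c("well", "gene_symbol", "sirna_index")]
    genes_p$content_type <- rep("gene", nrow(genes_p))
    ctrl_p <- tibble::tibble(
      well = ctrl_wells,
      gene_symbol = NA_character_,
      sirna_index = NA_integer_,
      content_type = ctrl$content_type
    )
    unused <- setdiff(sample_wells, genes_p$well)
    empty_p <- tibble::tibble(
      well = unused, gene_symbol = NA_character_,
      sirna_index = NA_integer_, content_type = "empty"
    )
    out <- dplyr::bind_rows(genes_p, empty_p, ctrl_p)
    out$layout_plate <- p
    out
  })
  layout1 <- dplyr::bind_rows(per_plate)

  reps <- tidyr::expand_grid(
    layout_plate = seq_len(n_layout),
    replicate_index = seq_len(config$replicate_plates)
  )
  layouts <- dplyr::inner_join(reps, layout1, by = "layout_plate",
                               relationship = "many-to-many")
  layouts$plate_id <- sprintf("P%03d_R%d", layouts$layout_plate,
                              layouts$replicate_index)
  layouts[, c("plate_id", "replicate_index", "well", "content_type",
              "gene_symbol", "sirna_index")]
}

# Per-reagent knockdown efficiencies, uniform within the configured range.
draw_knockdown <- function(config, reagents) {
  lo <- config$knockdown_efficiency_range[1]
  hi <- config$knockdown_efficiency_range[2]
  reagents$knockdown <- stats::runif(nrow(reagents), lo, hi)
  reagents
}

sample_plate_effects <- function(config, plate_ids) {
  tibble::tibble(
    plate_id = plate_ids,
    plate_effect = exp(stats::rnorm(length(plate_ids), 0, config$plate_effect_sd))
  )
}

#' Simulate a complete primary screen
#'
#' Generates the library, the plate layouts and the raw luminescence table
#' for the primary IRES-reporter screen, along with the ground truth needed
#' to score recovery. Every gene x siRNA reaction appears on
#' `replicate_plates` replicate plates; every plate carries the configured
#' scrambled, FLuc and PLK1 control wells. The raw value of a well is
#' `baseline_signal * plate_effect * gene_effect * noise` where
#' `gene_effect = 1 + k (m - 1)` for planted effect multiplier `m` and
#' per-siRNA knockdown efficiency `k`, FLuc-control wells are strongly
#' reduced, and the noise factor is log-normal with mean 1 and CV
#' `noise_cv`.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements `library`, `layouts`, `measurements`
#'   (columns `plate_id`, `well`, `channel`, `raw_value`), `ground_truth`
#'   (per-gene true sign, multiplier and flags), `knockdown` (per-reagent
#'   realized knockdown efficiency) and `plate_effects`.
#' @export
simulate_primary_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lib <- make_library(config)
  genes <- unique(lib$gene_symbol)
  planted <- resolve_planted(config, genes)

  reactions <- lib[order(lib$sirna_index, lib$gene_symbol),
                   c("gene_symbol", "sirna_index")]
  layouts <- build_layouts(config, reactions)

  set.seed(sub_seed(config, "primary"))
  reagents <- draw_knockdown(config, unique(lib[, c("gene_symbol", "sirna_index")]))
  plate_effects <- sample_plate_effects(config, unique(layouts$plate_id))

  multiplier <- stats::setNames(rep(1, length(genes)), genes)
  multiplier[planted$gene_symbol] <- planted$effect_multiplier

  wells <- layouts[layouts$content_type != "empty", ]
  wells <- dplyr::left_join(wells, reagents, by = c("gene_symbol", "sirna_index"))
  wells <- dplyr::left_join(wells, plate_effects, by = "plate_id")
  gene_effect <- ifelse(
    wells$content_type == "gene",
    1 + wells$knockdown * (multiplier[wells$gene_symbol] - 1),
    ifelse(wells$content_type == "fluc_control", config$fluc_control_effect,
           ifelse(wells$content_type == "plk1_control",
                  config$plk1_control_effect, 1))
  )
  noise <- lognormal_noise(nrow(wells), config$noise_cv)
  measurements <- tibble::tibble(
    plate_id = wells$plate_id,
    well = wells$well,
    channel = "fluc_ires",
    raw_value = config$baseline_signal * wells$plate_effect * gene_effect * noise
  )

  ground_truth <- tibble::tibble(
    gene_symbol = genes,
    true_multiplier = unname(multiplier[genes]),
    true_sign = ifelse(multiplier[genes] > 1, "negative",
                       ifelse(multiplier[genes] < 1, "positive", "none")),
    ires_specific = genes %in% planted$gene_symbol[planted$ires_specific],
    toxic = genes %in% planted$gene_symbol[planted$toxic]
  )

  list(
    library = lib,
    layouts = layouts,
    measurements = measurements,
    ground_truth = ground_truth,
    knockdown = reagents,
    plate_effects = plate_effects
  )
}

#' Simulate the secondary (specificity and viability) screen
#'
#' Re-tests the given genes with all their siRNAs on fresh triplicate
#' plates, read in three channels: the IRES-driven FLuc reporter
#' (`fluc_ires`), a cap-driven FLuc reporter (`fluc_cap`), and ATP content
#' (`atp`). IRES-specific regulators perturb only the IRES channel;
#' non-specific regulators perturb both reporter channels; toxic genes
#' additionally pull the ATP channel down to `toxic_viability` (25% by
#' default, the PLK1-like profile). Each plate x channel read gets its own
#' plate effect, handled downstream by per-plate normalization.
#'
#' @param config A [simulation_config()] object (same seed as the primary
#'   screen reproduces the same library).
#' @param genes Character vector of gene symbols to re-test (typically the
#'   primary hits).
#' @return A list with `layouts` and `measurements` in the same formats as
#'   [simulate_primary_screen()].
#' @export
simulate_secondary_screen <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  if (length(genes) == 0L) stop("genes must be nonempty", call. = FALSE)
  lib <- make_library(config)
  known <- unique(lib$gene_symbol)
  bad <- setdiff(genes, known)
  if (length(bad) > 0L) {
    stop("unknown gene_id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  planted <- resolve_planted(config, known)

  reagents <- lib[lib$gene_symbol %in% genes, c("gene_symbol", "sirna_index")]
  reactions <- reagents[order(reagents$sirna_index, reagents$gene_symbol), ]
  layouts <- build_layouts(config, reactions)

  set.seed(sub_seed(config, "secondary"))
  reagents <- draw_knockdown(config, reactions[, c("gene_symbol", "sirna_index")])
  channels <- c("fluc_ires", "fluc_cap", "atp")
  plate_reads <- tidyr::expand_grid(
    plate_id = unique(layouts$plate_id), channel = channels
  )
  plate_reads$plate_effect <- exp(
    stats::rnorm(nrow(plate_reads), 0, config$plate_effect_sd)
  )

  multiplier <- stats::setNames(rep(1, length(known)), known)
  multiplier[planted$gene_symbol] <- planted$effect_multiplier
  is_specific <- stats::setNames(rep(FALSE, length(known)), known)
  is_specific[planted$gene_symbol] <- planted$ires_specific
  is_toxic <- stats::setNames(rep(FALSE, length(known)), known)
  is_toxic[planted$gene_symbol] <- planted$toxic

  wells <- layouts[layouts$content_type != "empty", ]
  wells <- dplyr::left_join(wells, reagents, by = c("gene_symbol", "sirna_index"))
  idx <- tidyr::expand_grid(row = seq_len(nrow(wells)), channel = channels)
  wells <- dplyr::bind_cols(wells[idx$row, ], idx["channel"])
  wells <- dplyr::left_join(wells, plate_reads, by = c("plate_id", "channel"))

  kd_effect <- 1 + wells$knockdown * (multiplier[wells$gene_symbol] - 1)
  gene_effect <- rep(1, nrow(wells))
  sel_gene <- wells$content_type == "gene"
  sel_ires <- sel_gene & wells$channel == "fluc_ires"
  sel_cap <- sel_gene & wells$channel == "fluc_cap" &
    !is_specific[wells$gene_symbol]
  sel_atp <- sel_gene & wells$channel == "atp" & is_toxic[wells$gene_symbol]
  gene_effect[sel_ires] <- kd_effect[sel_ires]
  gene_effect[sel_cap] <- kd_effect[sel_cap]
  gene_effect[sel_atp] <- config$toxic_viability

  sel_fluc_ctrl <- wells$content_type == "fluc_control" & wells$channel != "atp"
  sel_plk1_fluc <- wells$content_type == "plk1_control" & wells$channel != "atp"
  sel_plk1_atp <- wells$content_type == "plk1_control" & wells$channel == "atp"
  gene_effect[sel_fluc_ctrl] <- config$fluc_control_effect
  gene_effect[sel_plk1_fluc] <- config$plk1_control_effect
  gene_effect[sel_plk1_atp] <- config$toxic_viability

  noise <- lognormal_noise(nrow(wells), config$noise_cv)
  measurements <- tibble::tibble(
    plate_id = wells$plate_id,
    well = wells$well,
    channel = wells$channel,
    raw_value = config$baseline_signal * wells$plate_effect * gene_effect * noise
  )
  list(layouts = layouts, measurements = measurements)
}

#' Simulate qPCR Ct observations for a known expression ratio
#'
#' Control-group Cts are drawn around fixed baselines; treated-group target
#' Cts are shifted by `delta_ct = -log(true_ratio) / log(efficiency)` so the
#' efficiency-corrected ratio of the treated group relative to control
#' equals `true_ratio`; reference-gene Cts are unshifted. Gaussian noise of
#' SD `ct_sd` is added to every Ct.
#'
#' @param config A [simulation_config()] object (supplies the seed).
#' @param true_ratio True expression ratio treated/control (> 0).
#' @param efficiency Amplification efficiency of the target assay, in
#'   (1, 2]; 2 means perfect doubling per cycle.
#' @param n_per_group Samples per group (>= 2).
#' @param ct_sd Gaussian Ct noise SD in cycles (default 0.15).
#' @param ref_efficiency Efficiency of the reference assay (defaults to
#'   `efficiency`).
#' @param control_ct_target,control_ct_ref Baseline Cts of the target and
#'   reference assays in the control group.
#' @param target_gene,reference_gene Gene symbols used for labelling.
#' @return A tibble with columns `sample_id`, `sample_group`, `gene_symbol`,
#'   `gene_role`, `ct`, `efficiency` (two rows per sample: target and
#'   reference).
#' @export
simulate_qpcr <- function(config, true_ratio, efficiency = 2,
                          n_per_group = 3L, ct_sd = 0.15,
                          ref_efficiency = efficiency,
                          control_ct_target = 24, control_ct_ref = 18,
                          target_gene = "TARGET", reference_gene = "ACTB") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(true_ratio) || true_ratio <= 0) {
    stop("true_ratio must be positive", call. = FALSE)
  }
  check_efficiency(efficiency)
  check_efficiency(ref_efficiency)
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  stopifnot(ct_sd >= 0)

  set.seed(sub_seed(config, "qpcr"))
  shift <- -log(true_ratio) / log(efficiency)
  samples <- tibble::tibble(
    sample_id = c(sprintf("ctrl_%02d", seq_len(n_per_group)),
                  sprintf("trt_%02d", seq_len(n_per_group))),
    sample_group = rep(c("control", "treated"), each = n_per_group)
  )
  target <- samples
  target$gene_symbol <- target_gene
  target$gene_role <- "target"
  target$ct <- control_ct_target +
    ifelse(target$sample_group == "treated", shift, 0) +
    stats::rnorm(nrow(target), 0, ct_sd)
  target$efficiency <- efficiency
  ref <- samples
  ref$gene_symbol <- reference_gene
  ref$gene_role <- "reference"
  ref$ct <- control_ct_ref + stats::rnorm(nrow(ref), 0, ct_sd)
  ref$efficiency <- ref_efficiency
  dplyr::bind_rows(target, ref)
}

#' Simulate ELISA concentration measurements for two groups
#'
#' Treated-group concentrations are drawn around
#' `control_mean * (1 - percent_reduction)` with additive Gaussian noise.
#'
#' @param config A [simulation_config()] object (supplies the seed).
#' @param control_mean Mean concentration of the control group (> 0).
#' @param percent_reduction Fractional reduction in the treated group, in
#'   `[0, 1)`.
#' @param n_per_group Samples per group (>= 2; a downstream t-test needs at
#'   least two).
#' @param noise_sd Additive Gaussian noise SD (default 5% of control mean).
#' @return A tibble with columns `group` and `concentration`.
#' @export
simulate_elisa <- function(config, control_mean, percent_reduction,
                           n_per_group, noise_sd = 0.05 * control_mean) {
  stopifnot(inherits(config, "sim_config"))
  if (control_mean <= 0) stop("control_mean must be positive", call. = FALSE)
  if (percent_reduction < 0 || percent_reduction >= 1) {
    stop("percent_reduction must be in [0, 1)", call. = FALSE)
  }
  if (n_per_group < 2L) {
    stop("n_per_group must be >= 2 (downstream t-test needs two values per group)",
         call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  set.seed(sub_seed(config, "elisa"))
  means <- c(control = control_mean,
             treated = control_mean * (1 - percent_reduction))
  tibble::tibble(
    group = rep(c("control", "treated"), each = n_per_group),
    concentration = rep(means, each = n_per_group) +
      stats::rnorm(2L * n_per_group, 0, noise_sd)
  )
}

check_efficiency <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e <= 1) || any(e > 2)) {
    stop("amplification efficiency must be in (1, 2]", call. = FALSE)
  }
  invisible(e)
}
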