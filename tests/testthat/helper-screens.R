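# Shared fixture builders: everything is generated in code at test time.

tiny_config <- function(n_genes = 20, noise_cv = 0.15, plate_effect_sd = 0.1,
                        planted = NULL, seed = 1) {
  simulation_config(
    n_genes = n_genes, noise_cv = noise_cv, plate_effect_sd = plate_effect_sd,
    planted_regulators = planted, seed = seed
  )
}

# A mixed planted set: strong Up effects (negative regulators), strong Down
# effects (positive regulators), some IRES-specific, some toxic.
demo_planted <- function() {
  plant_regulators(
    gene = 1:9,
    effect_multiplier = c(4, 5, 6, 0.2, 0.25, 0.3, 4.5, 0.2, 0.25),
    ires_specific = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    toxic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

# Hand-built single plate: a layout plus raw measurements, for exercising
# normalization without the simulator.
manual_plate <- function(scrambled = c(1000, 1100, 900, 1050),
                         gene_values = c(2050, 0, 512),
                         plate_id = "P001_R1", channel = "fluc_ires") {
  n_s <- length(scrambled)
  n_g <- length(gene_values)
  layout <- tibble::tibble(
    plate_id = plate_id,
    replicate_index = 1L,
    well = format_well(rep(0L, n_s + n_g), seq_len(n_s + n_g) - 1L),
    content_type = c(rep("scrambled_control", n_s), rep("gene", n_g)),
    gene_symbol = c(rep(NA_character_, n_s), sprintf("G%04d", seq_len(n_g))),
    sirna_index = c(rep(NA_integer_, n_s), rep(1L, n_g))
  )
  measurements <- tibble::tibble(
    plate_id = plate_id,
    well = layout$well,
    channel = channel,
    raw_value = c(scrambled, gene_values)
  )
  list(layout = layout, measurements = measurements)
}
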