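# Shared settings for the analysis scripts: the simulated screen emulating
# the kinase/phosphatase library (1,000 genes, 702:298 split, 3 siRNAs per
# gene on triplicate 96-well plates) with 24 planted regulators. Sourced by
# the numbered scripts; run them from the repository root in order.

library(iresscreen)

RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
SCREEN_SEED <- 2026L

# Planted truth: twelve 4-6x activations (negative regulators of the IRES),
# twelve 0.15-0.30x reductions (positive regulators); three of the positive
# regulators are IRES-specific and non-toxic (the MAPK3-like profile), two
# are PLK1-like toxic genes.
screen_planted <- function() {
  plant_regulators(
    gene = 1:24,
    effect_multiplier = c(rep(c(4, 5, 6), 4), rep(c(0.15, 0.2, 0.25, 0.3), 3)),
    ires_specific = c(rep(FALSE, 12), rep(c(TRUE, FALSE, FALSE, FALSE), 3)),
    toxic = c(rep(FALSE, 12), rep(c(FALSE, FALSE, FALSE, TRUE), 2),
              rep(FALSE, 4))
  )
}

screen_config <- function(seed = SCREEN_SEED) {
  simulation_config(n_genes = 1000, planted_regulators = screen_planted(),
                    seed = seed)
}
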