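test_that("an empty library yields plates carrying only control wells", {
  cfg <- tiny_config(n_genes = 0)
  sim <- simulate_primary_screen(cfg)
  expect_equal(nrow(sim$library), 0L)
  expect_gt(nrow(sim$measurements), 0L)
  measured <- dplyr::inner_join(sim$measurements, sim$layouts,
                                by = c("plate_id", "well"))
  expect_true(all(measured$content_type %in%
                    c("scrambled_control", "fluc_control", "plk1_control")))
})

test_that("zero noise collapses neutral wells onto the baseline exactly", {
  cfg <- tiny_config(n_genes = 6, noise_cv = 0, plate_effect_sd = 0)
  sim <- simulate_primary_screen(cfg)
  gene_wells <- dplyr::inner_join(
    sim$measurements,
    sim$layouts[sim$layouts$content_type == "gene", c("plate_id", "well")],
    by = c("plate_id", "well")
  )
  expect_equal(gene_wells$raw_value,
               rep(cfg$baseline_signal, nrow(gene_wells)))
})

test_that("identical seed and config reproduce measurement tables bit-identically", {
  cfg <- tiny_config(n_genes = 12, planted = demo_planted()[1:3, ], seed = 7)
  s1 <- simulate_primary_screen(cfg)
  s2 <- simulate_primary_screen(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$library, s2$library)
  sec1 <- simulate_secondary_screen(cfg, c("G0001", "G0002"))
  sec2 <- simulate_secondary_screen(cfg, c("G0001", "G0002"))
  expect_identical(sec1$measurements, sec2$measurements)
})

test_that("screen geometry matches the design: replicates, controls, positives", {
  cfg <- tiny_config(n_genes = 25)
  sim <- simulate_primary_screen(cfg)
  reps <- sim$layouts |>
    dplyr::filter(.data$content_type == "gene") |>
    dplyr::count(.data$gene_symbol, .data$sirna_index)
  expect_true(all(reps$n == cfg$replicate_plates))
  per_plate <- sim$layouts |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      n_scr = sum(.data$content_type == "scrambled_control"),
      n_fluc = sum(.data$content_type == "fluc_control")
    )
  expect_true(all(per_plate$n_scr >= 4))
  expect_true(all(per_plate$n_fluc >= 1))
  # FLuc positive-control wells are strongly reduced
  fluc <- dplyr::inner_join(
    sim$measurements,
    sim$layouts[sim$layouts$content_type == "fluc_control",
                c("plate_id", "well")],
    by = c("plate_id", "well")
  )
  expect_true(all(fluc$raw_value < 0.25 * cfg$baseline_signal))
})

test_that("a gene's three reactions are laid out on distinct plate sets", {
  cfg <- tiny_config(n_genes = 200)
  sim <- simulate_primary_screen(cfg)
  plates <- sim$layouts |>
    dplyr::filter(.data$content_type == "gene", .data$replicate_index == 1L) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(n_plates = dplyr::n_distinct(.data$plate_id))
  expect_true(all(plates$n_plates == cfg$sirnas_per_gene))
})

test_that("zero-noise wells reproduce the analytic signal model exactly", {
  cfg <- tiny_config(n_genes = 10, noise_cv = 0, plate_effect_sd = 0.2,
                     planted = plant_regulators(1:2, c(4, 0.25)))
  sim <- simulate_primary_screen(cfg)
  joined <- sim$measurements |>
    dplyr::inner_join(sim$layouts, by = c("plate_id", "well")) |>
    dplyr::filter(.data$content_type == "gene") |>
    dplyr::left_join(sim$knockdown, by = c("gene_symbol", "sirna_index")) |>
    dplyr::left_join(sim$plate_effects, by = "plate_id") |>
    dplyr::left_join(sim$ground_truth, by = "gene_symbol")
  expected <- cfg$baseline_signal * joined$plate_effect *
    (1 + joined$knockdown * (joined$true_multiplier - 1))
  expect_equal(joined$raw_value, expected)
})

test_that("raising a planted effect multiplier raises that gene's expected signal", {
  scores_for <- function(m) {
    cfg <- tiny_config(n_genes = 5, noise_cv = 0, plate_effect_sd = 0,
                       planted = plant_regulators(1, m), seed = 3)
    sim <- simulate_primary_screen(cfg)
    norm <- normalize_screen(sim$measurements, sim$layouts)
    sc <- reaction_scores(norm, sim$layouts)
    mean(sc$score[sc$gene_symbol == "G0001"])
  }
  ms <- c(0.5, 1, 2, 4, 8)
  vals <- vapply(ms, scores_for, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("marginal CV of neutral wells matches noise_cv at plate_effect_sd = 0", {
  cfg <- tiny_config(n_genes = 1200, noise_cv = 0.15, plate_effect_sd = 0,
                     seed = 11)
  sim <- simulate_primary_screen(cfg)
  gene_wells <- dplyr::inner_join(
    sim$measurements,
    sim$layouts[sim$layouts$content_type == "gene", c("plate_id", "well")],
    by = c("plate_id", "well")
  )
  expect_gte(nrow(gene_wells), 10000L)
  cv <- stats::sd(gene_wells$raw_value) / mean(gene_wells$raw_value)
  expect_lt(abs(cv - cfg$noise_cv), 0.01)
})

test_that("control capacity overflow is a sizing error naming the wells", {
  expect_error(
    simulation_config(n_genes = 1, n_neg_controls_per_plate = 90,
                      n_fluc_controls_per_plate = 5,
                      n_plk1_controls_per_plate = 1),
    "capacity overflow.*96 wells"
  )
})

test_that("secondary channels follow the specificity and toxicity model at zero noise", {
  planted <- plant_regulators(
    gene = 1:3,
    effect_multiplier = c(0.25, 0.25, 1),
    ires_specific = c(TRUE, FALSE, FALSE),
    toxic = c(FALSE, TRUE, FALSE)
  )
  cfg <- tiny_config(n_genes = 3, noise_cv = 0, plate_effect_sd = 0,
                     planted = planted)
  sec <- simulate_secondary_screen(cfg, c("G0001", "G0002", "G0003"))
  norm <- normalize_screen(sec$measurements, sec$layouts)
  sc <- reaction_scores(norm, sec$layouts) |>
    dplyr::group_by(.data$gene_symbol, .data$channel) |>
    dplyr::summarise(score = stats::median(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "score")
  specific <- sc[sc$gene_symbol == "G0001", ]
  expect_lt(specific$fluc_ires, 100)
  expect_equal(specific$fluc_cap, 100)
  expect_equal(specific$atp, 100)
  toxic <- sc[sc$gene_symbol == "G0002", ]
  expect_equal(toxic$atp, 25)      # PLK1-like viability profile
  expect_lt(toxic$fluc_cap, 100)   # all channels reduced jointly
  neutral <- sc[sc$gene_symbol == "G0003", ]
  expect_equal(unlist(neutral[, c("fluc_ires", "fluc_cap", "atp")]),
               c(fluc_ires = 100, fluc_cap = 100, atp = 100))
})

test_that("secondary screen rejects empty or unknown gene lists", {
  cfg <- tiny_config(n_genes = 3)
  expect_error(simulate_secondary_screen(cfg, character(0)), "nonempty")
  expect_error(simulate_secondary_screen(cfg, "NOPE"), "unknown gene")
})

test_that("qPCR simulator shifts treated target Cts by -log(ratio)/log(E)", {
  cfg <- tiny_config(n_genes = 1)
  q <- simulate_qpcr(cfg, true_ratio = 0.25, efficiency = 2,
                     n_per_group = 3, ct_sd = 0)
  tgt <- q[q$gene_role == "target", ]
  delta <- mean(tgt$ct[tgt$sample_group == "treated"]) -
    mean(tgt$ct[tgt$sample_group == "control"])
  expect_equal(delta, 2)  # -log2(0.25)
  ref <- q[q$gene_role == "reference", ]
  expect_equal(stats::sd(ref$ct), 0)

  ident <- simulate_qpcr(cfg, true_ratio = 1, efficiency = 2,
                         n_per_group = 3, ct_sd = 0)
  tgt <- ident[ident$gene_role == "target", ]
  expect_equal(tgt$ct[tgt$sample_group == "treated"],
               tgt$ct[tgt$sample_group == "control"])

  expect_error(simulate_qpcr(cfg, true_ratio = 2, efficiency = 1),
               "efficiency")
  expect_identical(simulate_qpcr(cfg, 0.5, n_per_group = 3),
                   simulate_qpcr(cfg, 0.5, n_per_group = 3))
})

test_that("ELISA simulator hits the requested group means", {
  cfg <- tiny_config(n_genes = 1)
  e <- simulate_elisa(cfg, control_mean = 100, percent_reduction = 0.25,
                      n_per_group = 4, noise_sd = 0)
  expect_equal(unique(e$concentration[e$group == "treated"]), 75)
  expect_equal(unique(e$concentration[e$group == "control"]), 100)
  flat <- simulate_elisa(cfg, 100, 0, 3, noise_sd = 0)
  expect_equal(mean(flat$concentration[flat$group == "treated"]),
               mean(flat$concentration[flat$group == "control"]))
  expect_error(simulate_elisa(cfg, 100, 0.25, 1), ">= 2")
  expect_identical(simulate_elisa(cfg, 100, 0.25, 5),
                   simulate_elisa(cfg, 100, 0.25, 5))
})
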