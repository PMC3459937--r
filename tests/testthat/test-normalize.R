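test_that("the control median is the plain median of scrambled wells", {
  p <- manual_plate(scrambled = c(1000, 1100, 900, 1050))
  expect_equal(
    plate_control_median(p$measurements, p$layout, "P001_R1"), 1025)
  single <- manual_plate(scrambled = 500)
  expect_equal(
    plate_control_median(single$measurements, single$layout, "P001_R1"), 500)
})

test_that("plates without scrambled controls are unusable", {
  p <- manual_plate()
  no_ctrl <- p$layout
  no_ctrl$content_type[no_ctrl$content_type == "scrambled_control"] <- "mock"
  expect_error(plate_control_median(p$measurements, no_ctrl, "P001_R1"),
               "no measured scrambled-control")
  expect_error(normalize_screen(p$measurements, no_ctrl),
               "scrambled-control")
})

test_that("normalization is raw / control-median x 100, controls included", {
  p <- manual_plate(scrambled = c(1000, 1100, 900, 1050),
                    gene_values = c(2050, 0))
  norm <- normalize_plate(p$measurements, p$layout)
  gene_rows <- norm[norm$well %in% p$layout$well[p$layout$content_type == "gene"], ]
  expect_equal(gene_rows$normalized_value, c(200, 0))
  scr_rows <- norm[norm$well %in%
                     p$layout$well[p$layout$content_type == "scrambled_control"], ]
  expect_equal(stats::median(scr_rows$normalized_value), 100)
})

test_that("normalization is invariant to rescaling a plate", {
  p <- manual_plate()
  n1 <- normalize_plate(p$measurements, p$layout)
  scaled <- p$measurements
  scaled$raw_value <- scaled$raw_value * 3
  n2 <- normalize_plate(scaled, p$layout)
  expect_equal(n1$normalized_value, n2$normalized_value)
})

test_that("replicate aggregation is a median with a usability threshold", {
  expect_equal(aggregate_replicates(c(95, 100, 260)),
               list(score = 100, n_replicates_used = 3L, usable = TRUE))
  expect_equal(aggregate_replicates(c(300, 280, 320))$score, 300)
  one <- aggregate_replicates(100, min_replicates = 2)
  expect_false(one$usable)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("aggregation commutes with replicate reordering", {
  set.seed(5)
  for (i in 1:20) {
    v <- stats::rlnorm(sample(2:6, 1), log(100), 0.3)
    expect_equal(aggregate_replicates(v)$score,
                 aggregate_replicates(sample(v))$score)
  }
})

test_that("reaction scores flag dropped reactions instead of erroring", {
  cfg <- tiny_config(n_genes = 4)
  sim <- simulate_primary_screen(cfg)
  # drop two of G0001/siRNA1's replicate wells
  target <- sim$layouts[sim$layouts$gene_symbol %in% "G0001" &
                          sim$layouts$sirna_index %in% 1L, ]
  drop <- paste(target$plate_id[1:2], target$well[1:2])
  meas <- sim$measurements[!paste(sim$measurements$plate_id,
                                  sim$measurements$well) %in% drop, ]
  norm <- normalize_screen(meas, sim$layouts)
  expect_warning(sc <- reaction_scores(norm, sim$layouts), "unusable")
  flagged <- sc[sc$gene_symbol == "G0001" & sc$sirna_index == 1L, ]
  expect_false(flagged$usable)
  expect_equal(flagged$n_replicates_used, 1L)
  expect_true(all(sc$usable[sc$gene_symbol != "G0001" | sc$sirna_index != 1L]))
})
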