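test_that("secondary evaluation applies the specificity and viability rules", {
  cp <- cutoff_pair()
  specific <- evaluate_secondary(45, 98, 95, "down", cp)
  expect_true(specific$confirmed)
  expect_true(specific$ires_specific)
  expect_true(specific$viable)
  expect_true(specific$specific_hit)

  nonspecific <- evaluate_secondary(40, 35, 90, "down", cp)
  expect_true(nonspecific$confirmed)
  expect_false(nonspecific$ires_specific)
  expect_false(nonspecific$specific_hit)

  plk1_like <- evaluate_secondary(30, 100, 25, "down", cp)
  expect_true(plk1_like$confirmed)
  expect_false(plk1_like$viable)
  expect_false(plk1_like$specific_hit)

  unconfirmed <- evaluate_secondary(120, 100, 100, "up", cp)
  expect_false(unconfirmed$confirmed)
  expect_false(unconfirmed$ires_specific)  # ires_specific implies confirmed
})

test_that("a missing channel is an evaluation error naming the channel", {
  expect_error(evaluate_secondary(45, NA, 95, "down"), "cap")
  expect_error(evaluate_secondary(NA, 100, 95, "down"), "ires")
})

test_that("tightening thresholds never enlarges the surviving set", {
  set.seed(12)
  profiles <- tibble::tibble(
    ires = stats::runif(200, 0, 400),
    cap = stats::runif(200, 0, 300),
    atp = stats::runif(200, 0, 150),
    dir = sample(c("up", "down"), 200, replace = TRUE)
  )
  survivors <- function(cap_tol, floor_) {
    keep <- vapply(seq_len(nrow(profiles)), function(i) {
      evaluate_secondary(profiles$ires[i], profiles$cap[i], profiles$atp[i],
                         profiles$dir[i], cap_tolerance = cap_tol,
                         viability_floor = floor_)$specific_hit
    }, logical(1))
    which(keep)
  }
  loose <- survivors(0.30, 0.60)
  tight_cap <- survivors(0.10, 0.60)
  tight_viab <- survivors(0.30, 0.90)
  expect_true(all(tight_cap %in% loose))
  expect_true(all(tight_viab %in% loose))
})

test_that("at zero noise the survivors are exactly the specific non-toxic planted set", {
  cfg <- tiny_config(n_genes = 30, noise_cv = 0, plate_effect_sd = 0,
                     planted = demo_planted())
  sim <- simulate_primary_screen(cfg)
  norm <- normalize_screen(sim$measurements, sim$layouts)
  sc <- reaction_scores(norm, sim$layouts)
  hits <- call_genes(call_reactions(sc, cutoff_pair()), sim$library)
  sec <- simulate_secondary_screen(cfg, hits$gene_symbol[hits$hit])
  res <- run_secondary(hits, sec$measurements, sec$layouts)

  truth <- sim$ground_truth
  expected <- truth$gene_symbol[truth$ires_specific & !truth$toxic]
  expect_setequal(res$results$gene_symbol[res$results$specific_hit], expected)
  # containment: specific within confirmed within tested
  expect_lte(res$summary$ires_specific, res$summary$confirmed)
  expect_lte(res$summary$confirmed, res$summary$tested)
  expect_equal(res$summary$tested, sum(hits$hit))
})

test_that("all-neutral secondary data confirms nothing", {
  cfg <- tiny_config(n_genes = 10, noise_cv = 0, plate_effect_sd = 0)
  hits <- tibble::tibble(
    gene_symbol = c("G0001", "G0002"), gene_class = "kinase", hit = TRUE,
    direction = c("up", "down"), n_supporting_sirnas = 3L,
    regulator_sign = c("negative", "positive"), n_usable_sirnas = 3L
  )
  sec <- simulate_secondary_screen(cfg, hits$gene_symbol)
  res <- run_secondary(hits, sec$measurements, sec$layouts)
  expect_equal(res$summary$confirmed, 0L)
})

test_that("hit genes without secondary data are listed as untested", {
  cfg <- tiny_config(n_genes = 10, noise_cv = 0, plate_effect_sd = 0,
                     planted = plant_regulators(1:2, c(4, 0.2)))
  sim <- simulate_primary_screen(cfg)
  norm <- normalize_screen(sim$measurements, sim$layouts)
  hits <- call_genes(call_reactions(reaction_scores(norm, sim$layouts),
                                    cutoff_pair()), sim$library)
  sec <- simulate_secondary_screen(cfg, "G0001")  # G0002 never re-tested
  res <- run_secondary(hits, sec$measurements, sec$layouts)
  expect_equal(res$untested, "G0002")
  expect_equal(res$results$gene_symbol, "G0001")
})
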