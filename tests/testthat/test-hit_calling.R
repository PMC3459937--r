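test_that("frequency distribution counts with half-open bins, last bin closed", {
  fd <- frequency_distribution(c(50, 150, 150, 350), bin_width = 100)
  expect_equal(fd$bin_lo, c(0, 100, 200, 300))
  expect_equal(fd$count, c(1L, 2L, 0L, 1L))
  expect_equal(sum(fd$count), 4L)

  one <- frequency_distribution(42, bin_width = 10)
  expect_equal(sum(one$count > 0), 1L)

  set.seed(2)
  x <- stats::runif(200, 0, 400)
  expect_equal(frequency_distribution(x, 25)$count,
               frequency_distribution(sample(x), 25)$count)
  expect_equal(sum(frequency_distribution(x, 25)$count), 200L)
  expect_error(frequency_distribution(numeric(0), 10), "nonempty")
})

test_that("calibrated cut-offs sit at rank-symmetric quantiles, rounded outward", {
  cp <- calibrate_cutoffs(1:1000, target_hit_rate = 0.10, grid = 1)
  sorted <- sort(1:1000)
  expect_lte(cp$down_cutoff, sorted[50])
  expect_gte(cp$up_cutoff, sorted[951])
  beyond <- mean(1:1000 >= cp$up_cutoff | 1:1000 <= cp$down_cutoff)
  expect_lte(beyond, 0.10)
  expect_equal(cp$derivation, "calibrated")
})

test_that("calibration respects the hit-rate budget on random score sets", {
  set.seed(9)
  for (i in 1:100) {
    scores <- stats::rlnorm(sample(200:500, 1), log(100), 0.35) # centred at 100
    target <- sample(c(0.05, 0.10, 0.20), 1)
    cp <- calibrate_cutoffs(scores, target_hit_rate = target, grid = 10)
    beyond <- mean(scores >= cp$up_cutoff | scores <= cp$down_cutoff)
    expect_lte(beyond, target)
    expect_lt(cp$down_cutoff, 100)
    expect_gt(cp$up_cutoff, 100)
  }
})

test_that("calibration boundary behaviour: permissive targets stay inside the data", {
  set.seed(10)
  scores <- stats::runif(500, 0, 200)
  cp <- calibrate_cutoffs(scores, target_hit_rate = 0.99, grid = 10)
  expect_gte(cp$down_cutoff, min(scores) - 10)
  expect_lte(cp$up_cutoff, max(scores) + 10)
  expect_error(calibrate_cutoffs(rep(100, 50)), "degenerate")
})

test_that("reaction calls use inclusive boundaries at the published cut-offs", {
  cp <- cutoff_pair(250, 80)
  expect_equal(call_reaction(260, cp), "up")
  expect_equal(call_reaction(100, cp), "none")
  expect_equal(call_reaction(80, cp), "down")
  expect_equal(call_reaction(250, cp), "up")
  expect_equal(call_reaction(c(249.9, 80.1), cp), c("none", "none"))
  expect_error(cutoff_pair(90, 80), "straddle")
})

test_that("gene calls agree with exhaustive enumeration over all 27 direction vectors", {
  dirs <- c("up", "down", "none")
  grid <- expand.grid(d1 = dirs, d2 = dirs, d3 = dirs,
                      stringsAsFactors = FALSE)
  # independent oracle: a hit is a pair of equal non-none directions
  oracle <- function(v) {
    for (i in 1:2) for (j in (i + 1):3) {
      if (v[i] != "none" && v[i] == v[j]) return(v[i])
    }
    NA_character_
  }
  for (r in seq_len(nrow(grid))) {
    v <- unlist(grid[r, ], use.names = FALSE)
    expected_dir <- oracle(v)
    got <- call_gene(v)
    expect_equal(got$hit, !is.na(expected_dir))
    expect_equal(got$direction, expected_dir)
    if (!is.na(expected_dir)) {
      expect_equal(got$regulator_sign,
                   if (expected_dir == "up") "negative" else "positive")
      expect_gte(got$n_supporting_sirnas, 2L)
    }
  }
})

test_that("fewer than two usable calls never make a hit", {
  expect_false(call_gene(c("up"))$hit)
  expect_false(call_gene(character(0))$hit)
  expect_true(call_gene(c("down", "down"))$hit)
})

test_that("raising a score never demotes an up call nor creates a down call", {
  cp <- cutoff_pair(250, 80)
  set.seed(4)
  s <- stats::runif(500, 0, 400)
  bumped <- s + stats::runif(500, 0, 100)
  before <- call_reaction(s, cp)
  after <- call_reaction(bumped, cp)
  expect_false(any(before == "up" & after != "up"))
  expect_false(any(before != "down" & after == "down"))
})

test_that("screen summary tabulates affected genes, hits by class and sign", {
  planted <- plant_regulators(gene = c(1, 2), effect_multiplier = c(5, 6))
  cfg <- tiny_config(n_genes = 10, noise_cv = 0, plate_effect_sd = 0,
                     planted = planted)
  sim <- simulate_primary_screen(cfg)
  norm <- normalize_screen(sim$measurements, sim$layouts)
  sc <- reaction_scores(norm, sim$layouts)
  calls <- call_reactions(sc, cutoff_pair())
  hits <- call_genes(calls, sim$library)
  s <- summarize_screen(calls, hits)
  expect_equal(s$n_hits, 2L)
  expect_equal(s$hits_by_class$kinase, 2L)  # G0001/G0002 are kinases
  expect_equal(s$n_negative_regulators + s$n_positive_regulators, s$n_hits)
  expect_equal(s$n_affected, 2L)
})
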