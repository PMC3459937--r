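# iresscreen

Analysis of plate-based RNAi screens that read out mRNA translation as
reporter luminescence — built for screens against the VEGF IRES (internal
ribosome entry site), where the question is which kinases and phosphatases
regulate cap-independent translation of a transfected FLuc reporter mRNA.
It is aimed at screeners and analysts who have (or want to simulate)
per-well luminescence tables from 96-well siRNA plates and need the full
chain from raw counts to validated, IRES-specific hits.

## The method

Each gene is targeted by three independent siRNAs, each run on three
replicate plates. The analysis is median-based throughout:

* **Normalization.** For well value *x* on a plate whose four
  scrambled-siRNA control wells have median *c*: normalized value
  = *x / c × 100*. The scrambled median is 100 on every plate, exactly.
* **Reaction score.** score(gene, siRNA) = median of the normalized
  triplicate values.
* **Calling.** Up call if score ≥ 250, Down call if score ≤ 80 (inclusive;
  cut-offs chosen to keep the call rate < 10%, and re-derivable from the
  score distribution with `calibrate_cutoffs()`).
* **Gene hits.** A gene is a hit when ≥ 2 siRNAs agree in direction:
  Up ⇒ negative regulator of IRES activity, Down ⇒ positive regulator.
* **Secondary screen.** Hits are re-tested in three channels — IRES
  reporter (confirmation), cap-driven reporter (specificity: within ±25 of
  100), ATP (viability: ≥ 70) — yielding the final IRES-specific, viable
  hit set.
* **Validation statistics.** Efficiency-corrected qPCR ratios
  *E*<sub>target</sub><sup>ΔCt<sub>target</sub></sup> /
  *E*<sub>ref</sub><sup>ΔCt<sub>ref</sub></sup> (ΔCt = control − treated)
  with a REST-style randomization p-value and jackknife SD, and the
  unpaired equal-variance Student's t-test for ELISA group comparisons.

A seeded synthetic-screen generator with planted regulators (known effect
multipliers, IRES-specificity and toxicity flags, partial knockdown per
siRNA) provides ground-truth data for every stage; see the methods
vignette (`vignettes/screen-analysis-methods.Rmd`) for the signal model
and all default choices.

## Worked example

```r
library(iresscreen)

cfg <- simulation_config(
  n_genes = 60,
  planted_regulators = plant_regulators(
    gene = c(1, 2, 3), effect_multiplier = c(5, 0.2, 0.25),
    ires_specific = c(FALSE, TRUE, FALSE), toxic = c(FALSE, FALSE, TRUE)),
  seed = 1)

sim        <- simulate_primary_screen(cfg)
normalized <- normalize_screen(sim$measurements, sim$layouts)
scores     <- reaction_scores(normalized, sim$layouts)
hits       <- call_genes(call_reactions(scores, cutoff_pair()), sim$library)
hits[hits$hit, ]
#>   gene_symbol gene_class hit   direction n_supporting_sirnas regulator_sign
#> 1 G0001       kinase     TRUE  up                          3 negative
#> 2 G0002       kinase     TRUE  down                        3 positive
#> 3 G0003       kinase     TRUE  down                        3 positive
```

All three planted regulators come out as hits with the correct sign: the
5× activation is an Up hit (negative regulator), the two reductions are
Down hits (positive regulators). The secondary screen then separates them:

```r
sec <- simulate_secondary_screen(cfg, hits$gene_symbol[hits$hit])
res <- run_secondary(hits, sec$measurements, sec$layouts)
res$results[, c("gene_symbol", "ires_score", "cap_score", "viability_score", "specific_hit")]
#>   gene_symbol ires_score cap_score viability_score specific_hit
#> 1 G0001            451.      460.             98.0 FALSE
#> 2 G0002             37.1      96.1           102.  TRUE
#> 3 G0003             33.8      36.4            23.8 FALSE
res$summary
#> $tested: 3   $confirmed: 3   $ires_specific: 1   $specific_viable: 1
```

G0001 moves the cap reporter as much as the IRES reporter (not specific);
G0003 is toxic (ATP at 24% of control, the PLK1-like profile); only G0002
— IRES channel down, cap near 100, viable — survives as an IRES-specific
hit, exactly the planted truth.

## Analysis workflow

The `analysis/` scripts run the full study on a simulated 1,000-gene
library (702 kinases, 298 phosphatases; 24 planted regulators), writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # library, layouts, raw wells
Rscript analysis/02_normalize.R   # percent-of-control, reaction scores
Rscript analysis/03_call_hits.R   # histogram, 250/80 calls, gene hits
Rscript analysis/04_secondary.R   # specificity + viability filter
Rscript analysis/05_validation.R  # qPCR (Pfaffl/REST) + ELISA t-test
```

`run_pipeline()` performs the same chain in one call from a
`simulation_config()` or a YAML file.

## File formats

Single dialect: comma-separated, UTF-8, header row.

| file | columns |
|---|---|
| `library.csv` | `gene_symbol, refseq, sirna_index, sense, antisense, gene_class` |
| `layout.csv` | `plate_id, well, content_type, gene_symbol, sirna_index` (+ `replicate_index`) |
| `measurements.csv` | `plate_id, well, channel, value` |

Wells are `A1`–`H12` (case-insensitive, zero padding accepted, written
unpadded); channels are `fluc_ires`, `fluc_cap`, `atp`; content types are
`gene`, `scrambled_control`, `fluc_control`, `plk1_control`, `mock`,
`empty`. Spatial corrections (B-scores, loess) are deliberately not
implemented; they are natural future work for plates with edge effects.

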