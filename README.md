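# isopulse

Stable-isotope pulse-chase analysis of nutrient exchange between reef
sponges and coral holobionts.

Sponges take up dissolved inorganic carbon and nitrogen; corals and their
symbiotic micro-algae (Symbiodiniaceae) may in turn feed on what sponges
release. A dual-label pulse-chase experiment tests this directly: sponges
are enriched for 3 h in seawater spiked with NaH¹³CO₃, Na¹⁵NO₃ and ¹⁵NH₄Cl,
rinsed for 1 h, and then share tanks with coral fragments for a 6 h chase.
Heavy isotope appearing in coral tissue above natural abundance traces the
sponge-to-coral pathway. `isopulse` provides the full quantitative chain for
this design, plus a seeded compartmental simulator so every stage can be
exercised and verified without any external data.

## What it computes

**Tracer arithmetic.** Delta notation is converted through isotope ratios to
atom fractions, `R = R_std(δ/1000 + 1)`, `F = R/(1+R)`; excess incorporation
is `X = (F_sample − F_baseline) · N_tot` µmol of heavy isotope, and the
incorporation rate is `X / N₀ / t` in µmol·mmol⁻¹·h⁻¹, normalized to the
elemental pool of the initial specimen and hours of chase exposure. Standard
ratios (VPDB 0.011180 for C, atmospheric N₂ 0.0036765 for N) and atomic
masses live in an overridable registry shared by analysis and simulator.
Negative excess (a real net label loss) is preserved, never clipped.

**Experiment model.** Baseline tables per species × fraction × element
(time-zero means by default, time-matched controls optionally), per-sample
incorporation results, boxplot-convention group summaries, paired
host/symbiont holobiont totals, and the headline per-species ¹⁵N:¹³C
fold-ratio.

**Permutational statistics, from scratch.** Distance-based PERMANOVA
(Euclidean; pseudo-F identical to classical ANOVA F for scalar responses)
with exhaustive enumeration of small label-arrangement spaces and unique
(rejection-sampled) permutations otherwise; sequential multi-factor tests;
pairwise PERMANOVA with Bonferroni correction; tie-corrected Kruskal–Wallis
with exact small-sample p; Welch's t.

**Symbiodiniaceae density.** Diluted-aliquot counts scaled to cells/ml,
cells/fragment and cells/cm², plus a consistency report comparing
photographic and foil surface-area measurements.

**Simulator.** Linear first-order compartments (sponges → tank water →
coral fractions) over the 3 h pulse / 1 h rinse / 6 h chase timeline,
integrated by fixed-step classical RK4, with destructive sampling, control
tanks, and 0.1‰ Gaussian measurement noise. Emits analysis-ready sample
tables together with latent ground truth for oracle testing and parameter
recovery.

## Worked example

```r
library(isopulse)

sim <- simulate_pulse_chase(sim_config(seed = 1))
sim
#> Simulated pulse-chase experiment
#>   180 bulk samples (54 sponge, 126 coral-fraction)
#>   5 enriched + 3 control tanks; seed 1; noise sd 0.1 permil

res <- compute_incorporation(sim$samples)
fold_ratio_n_vs_c(res)
#>                species excess_15N_umol excess_13C_umol fold_ratio defined
#> 1 Acropora cervicornis          0.2188          0.0340       6.44    TRUE
#> 2     Eunicea flexuosa          0.0672          0.0243       2.77    TRUE
#> 3  Orbicella faveolata          0.0802          0.0244       3.29    TRUE
```

Every coral holobiont took up several-fold more ¹⁵N than ¹³C from
sponge-derived matter, with the branching *A. cervicornis* the strongest
accumulator — the qualitative pattern the design is meant to resolve. Is the
symbiont/host split real? Test the fraction effect on ¹⁵N excess across the
chase samples:

```r
chase <- res[res$element == "N" & res$timepoint %in% c("T3", "T6") &
               res$fraction != "sponge_tissue", ]
permanova(euclidean_dist(chase$excess_umol), factor(chase$fraction),
          permutations = 999, seed = 1)
#> Permutational ANOVA on a distance matrix
#> Permutations: 999 (unique-sampled)
#>      term df         SS      R2 pseudo_F p_perm
#>    groups  1 0.00322663 0.41409  40.9917  0.001
#>  Residual 58 0.00456542 0.58591       NA     NA
#>     Total 59 0.00779205 1.00000       NA     NA
```

Symbiodiniaceae incorporate significantly more ¹⁵N than their hosts
(pseudo-F = 41.0, p = 0.001 — the floor of 1/(B+1) with B = 999). The whole
battery — baselines, incorporation, summaries, statistics, optional cell
densities, JSON run report — runs in one call:

```r
run_pipeline(list(simulate = TRUE, seed = 1, permutations = 999,
                  out_dir = "results/run1"))
```

## Layout

- `R/` — tracer arithmetic (`isocore.R`), experiment model (`pulse_chase.R`),
  permutation statistics (`permstats.R`), simulator (`simulate.R`),
  cell densities (`symb_density.R`), readers/pipeline (`io.R`)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/sponge-coral-tracer.Rmd` — model, assumptions, design choices
- `scripts/acceptance.R` — verification script (above)
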