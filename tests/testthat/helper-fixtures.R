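# shared fixtures built in code; expensive simulations cached per test run

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed = 1, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_pulse_chase(sim_config(seed = seed, ...))
  }
  .sim_cache[[key]]
}

# minimal hand-built bulk-sample table: one coral species, both fractions,
# with T0 baselines and one enriched T3 specimen per fraction
tiny_samples <- function(delta15N_t3 = 1005, delta15N_t0 = 5,
                         delta13C = -15, pctN = 14.007, pctC = 24.022,
                         mass = 1) {
  mk <- function(id, fraction, treatment, timepoint, tank, d15N) {
    data.frame(
      sample_id = id, organism = "coral", species = "Acropora cervicornis",
      fraction = fraction, treatment = treatment, timepoint = timepoint,
      tank_id = tank, delta13C = delta13C, delta15N = d15N,
      pctC = pctC, pctN = pctN, dry_mass_mg = mass, stringsAsFactors = FALSE
    )
  }
  rbind(
    mk("t0h", "coral_host", "control", "T0", "acc", delta15N_t0),
    mk("t0s", "symbiodiniaceae", "control", "T0", "acc", delta15N_t0),
    mk("e3h", "coral_host", "enriched", "T3", "E1", delta15N_t3),
    mk("e3s", "symbiodiniaceae", "enriched", "T3", "E1", delta15N_t3)
  )
}

# hand-built incorporation-style results table for the summary operations
fake_results <- function(species, fraction, element, excess,
                         timepoint = "T6") {
  data.frame(
    sample_id = sprintf("F%03d", seq_along(excess)), species = species,
    fraction = fraction, timepoint = timepoint, tank_id = "E1",
    element = element, excess_umol = excess, rate = excess / 6,
    stringsAsFactors = FALSE
  )
}
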