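---
title: "Tracing sponge-derived nutrients into coral holobionts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing sponge-derived nutrients into coral holobionts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopulse)
```

## The problem

Reef sponges filter dissolved matter out of seawater and return nutrients to
the benthos. Whether corals feed on sponge-derived dissolved matter can be
asked with a dual-label pulse-chase design: sponges are incubated for 3 h in
seawater spiked with inorganic ^13^C (bicarbonate) and ^15^N (nitrate +
ammonium), rinsed for 1 h, and then placed for a 6 h chase into tanks holding
coral fragments. Whatever heavy isotope appears in coral host tissue or in
their symbiotic micro-algae (Symbiodiniaceae) above natural abundance must
have travelled sponge to water to coral. `isopulse` implements the
quantitative chain for such experiments: tracer arithmetic, baseline
handling, incorporation and incorporation-rate estimation, cell-density
normalization, the permutational statistics, and a compartmental simulator
that generates analysis-ready data with known ground truth.

## Tracer arithmetic

Measurements arrive in delta notation, the per-mil deviation of a sample's
heavy/light isotope ratio from an international standard:
\[
\delta = \left(\frac{R_{sample}}{R_{std}} - 1\right) \times 1000 .
\]
Mole bookkeeping cannot be done in delta space; the package converts to atom
fractions \(F = R/(1+R)\) and computes excess incorporation as
\[
X \;=\; (F_{sample} - F_{baseline}) \cdot N_{tot},
\]
where \(N_{tot}\) is the total micromoles of the element in the specimen
(from its mass percent and dry mass). The incorporation rate normalizes
excess to the elemental pool of the *initial* specimen and to chase exposure
time, in µmol · mmol^-1^ · h^-1^. Three conventions are fixed here and used
consistently:

* **Standard ratios.** The standards themselves are community conventions:
  ^13^C/^12^C = 0.011180 (VPDB) and ^15^N/^14^N = 0.0036765 (atmospheric
  N~2~). They live in a registry (`iso_constants()`) shared by the analysis
  and the simulator, and can be overridden.
* **Baselines are averaged in atom-fraction space**, not delta space. At
  natural abundance the difference is negligible (well below measurement
  noise), but a convention must be fixed for reproducibility.
* **Negative excess is preserved.** A net loss of label relative to baseline
  is a real flux (boulder corals can show a net negative ^13^C flux) and is
  never clipped to zero.

Two baseline policies are provided. `t0_mean` (default) subtracts the mean
atom fraction of the pre-pulse specimens of the same species and fraction;
`time_matched_control` subtracts the mean of control-tank corals at the same
chase timepoint (sponges, which have no control tanks, fall back to their
time-zero means). The rate denominator always uses the time-zero elemental
pool — fragments scored at later timepoints were destroyed, so their own
initial content is unobservable. Under drift-free conditions the two
policies agree to within measurement noise, which the test suite checks by
simulation.

## Permutational statistics

Responses here are scalar and signed (delta changes, excesses, rates), so
distances between observations are Euclidean; ecological dissimilarities
such as Bray–Curtis are inappropriate for signed data. The PERMANOVA
partitions the squared dissimilarities (equivalently the Gower-centered
inner-product matrix \(G = -\tfrac12 C \Delta^{2} C\)) and tests
\[
F = \frac{SS_B/(a-1)}{SS_W/(n-a)}
\]
against the null distribution obtained by relabeling observations. Design
choices:

* **Unique permutations.** When the number of distinct label arrangements is
  less than ten times the requested permutation count, the null is
  enumerated exhaustively and the p-value is an exact fraction of the full
  arrangement space; otherwise the requested number of *distinct*
  arrangements is drawn by rejection sampling and the `+1` convention
  \(p = (\#\{F^{\pi} \ge F\} + 1)/(B+1)\) applies, confining p to
  \([1/(B+1), 1]\).
* **Univariate equivalence.** For scalar Euclidean input the pseudo-F is
  numerically identical to the classical one-way ANOVA F; this closed-form
  equivalence is the central correctness oracle in the tests.
* **Multi-factor designs** use sequential (Type-I) sums of squares via the
  projection-trace formulation, tested by free permutation of rows. This
  approximates reduced-model residual permutation; for the balanced designs
  of this experiment the approximation is standard, and it is validated
  against an independent implementation in the test suite.
* **Pairwise tests** run one two-group PERMANOVA per unordered pair on the
  corresponding distance sub-matrix, with Bonferroni correction
  (`p_adj = min(1, p * m)`); no other correction is offered because the
  analysis battery is fixed.
* **Kruskal–Wallis** is tie-corrected, and for pooled \(N \le 10\) the exact
  permutation p is enumerated alongside the chi-squared approximation: at
  such sizes the chi-squared p is unreliable. For two triplets with complete
  rank separation the statistic attains its maximum \(H = 27/7 = 3.857\),
  with exact p \(= 2/20 = 0.1\) while the chi-squared approximation gives
  0.0495 — the two can disagree by a factor of two, which is why both are
  reported.
* **Welch's t** is used for the two-sample comparisons (fractional
  degrees of freedom by Welch–Satterthwaite).

A type-I error calibration (2000 null data sets, B = 999) is part of the
acceptance checks; the rejection rate at \(\alpha = 0.05\) must land in
\([0.03, 0.07]\).

## The simulator

`simulate_pulse_chase()` generates the full experiment: 6 sponge species, 3
coral species × 2 fractions, 5 enriched and 3 control tanks, destructive
sampling at hours 0 (T0), 3 (end of pulse, sponges only), 7 (T3) and 10
(T6). Kinetics are linear and first-order — the minimal model that produces
the observed trajectory shapes (sponge enrichment rising through the pulse
and decaying through the chase, coral fractions accumulating through the
chase) while admitting closed-form solutions for oracle tests:

* pulse: each sponge takes up label from the spiked reservoir at
  \(u_j W_{pulse}\), with the reservoir treated as constant (the spike is
  orders of magnitude larger than total uptake);
* rinse: unincorporated water label is discarded instantly; sponge stores
  hold;
* chase, per tank:
  \(\dot S_j = -r_j S_j\),
  \(\dot W = \sum_j r_j S_j - \sum_k c_k W\),
  \(\dot F_k = c_k W\) (plus optional symbiont-to-host translocation
  \(\tau\)).

The system is integrated with a fixed-step classical 4th-order Runge–Kutta
scheme at \(\Delta t = 0.01\) h, implemented as the one-step transfer matrix
of the (piecewise) constant linear system — numerically identical to
stepping RK4 and exactly mass-conserving, because the flux matrix has zero
column sums over the physical compartments. Fragments destructively sampled
at T3 stop exchanging with the tank but keep their label, so the per-tank
total is conserved through the whole chase (a tested invariant, at 1e-9
relative over randomized configurations). Control tanks hold no sponges and
therefore no dissolved label.

Measurement converts latent compartment excess plus a per-species background
delta into a measured delta through the same constants registry as the
analysis, then adds Gaussian noise with sd 0.1 permil — the analytical
precision of replicate standards on a continuous-flow isotope-ratio mass
spectrometer. Elemental composition is drawn per specimen (percent carbon,
molar C:N, dry mass in the 1.5–2.5 mg range of packed aliquots); host and
symbiont C:N means average 6.36 and 5.94 across coral species.

### What the defaults encode, and what they do not

Defaults mirror the study conditions wherever the study states them: the
timeline, tank and replicate structure, the 10:1 carbon:nitrogen label ratio
of the spike, measurement noise, per-sponge-species pulse enrichment
targets (e.g. +1268.8, +1044.7 and +983.3 permil ^15^N for the three
strongest accumulators, with only the three cyanobacteria-bearing species
accumulating appreciable ^13^C, and pulse ^15^N:^13^C incorporation ratios
spanning a 1.9–300× range), first-order release constants sized
so sponges shed roughly half to three quarters of their label over the
chase, and coral uptake constants ordered to match the biology (symbiont above host
in every species and element; *A. cervicornis* above the other species;
holobiont ^15^N:^13^C fold-ratios within a 2.3–26.8× envelope).

The absolute magnitudes of the coral uptake constants are a deliberate
design choice rather than a match to field-scale measurements: they are set
high enough that **every** rate constant is identifiable from the default
replicate structure at the stated 0.1 permil precision (worst-case estimator
standard deviation ≈ 3%, verified by simulation), so that parameter-recovery
tests exercise estimator correctness rather than signal starvation. The real
experiment's smallest carbon signals sit much closer to the noise floor
(per-sample excesses down to a few 1e-4 µmol); at those magnitudes no
estimator could pin the smallest constants to 10% from ten fragments, and
simulated recovery would test luck, not code. Consequently simulated excess
values run roughly an order of magnitude larger than field-scale
measurements, and comparisons against real data should use the ratio-type
and ordering outputs (fold-ratios, fraction contrasts), not raw micromoles.

Individual sponges vary by a lognormal factor (sdlog 0.2) in pulse uptake,
which propagates realistic tank-to-tank variation into the chase.
Backgrounds are fixed per species and fraction rather than drawn per
individual: all specimen-level scatter enters through measurement noise and
composition. This keeps the zero-noise pipeline-equals-truth oracle exact,
at the cost of understating natural baseline variability — a known
simplification. Translocation defaults to zero because the experimental
design cannot separate direct host uptake from symbiont-to-host transfer;
both pathways are exposed as parameters (`coral_uptake`, `translocation`)
so either hypothesis can be simulated. Sponge detritus release is omitted
(none was observed), so the only label route to corals is dissolved.

### Parameter recovery

With zero translocation each fragment compartment is a linear integrator of
the tank's dissolved pool: \(F_k(t) = c_k \int_0^t W\,\mathrm d s\). The
latent integral is emitted with the ground truth, and
`recover_uptake()` regresses pipeline-computed excess (from the noisy
measurements) through the origin against it. At the default conditions all
twelve coral constants are recovered within 10% (typically within ~5%); the
acceptance checks assert this end to end.

## Symbiodiniaceae density

Counts made on a diluted aliquot of the fixed algal homogenate scale as
count → cells/ml → cells/fragment → cells/cm². Any fixation dilution (the
1:1 paraformaldehyde step) is folded into `dilution_factor` by the data
loader rather than hard-coded, keeping the operation a pure scaling chain.
The two surface-area methods (photographic and foil) are compared per
fragment — ratio and Spearman rank correlation — as a consistency report
only; the pipeline consumes the photographic values.

## Numerical choices and degenerate inputs

* Deltas at or below −1000 permil, atom fractions outside \([0,1)\),
  non-positive pools, masses or exposures are rejected with domain errors;
  row-level validation in the readers rejects individual records (with line
  numbers) rather than whole files.
* Permutation F comparisons use a relative tolerance of 1e-12 so that
  arrangements tied with the observed one (e.g. mirror relabelings) count as
  extreme on every platform.
* A response with zero total sum of squares is flagged degenerate: F = 0,
  p = 1. All-tied Kruskal–Wallis data likewise degenerate to H = 0. A Welch
  test with two zero-variance equal-mean samples is flagged rather than
  returning 0/0.
* Quartiles use linear interpolation (R type 7), the mainstream boxplot
  convention; whiskers extend to the most extreme values within 1.5 × IQR of
  the hinges and everything beyond is listed as outliers.

## Problem sizes used in the checks

The shipped verification uses the default cohort (≈180 specimens per run),
50 random data sets for the ANOVA-equivalence oracle, 2000 null replicates
for type-I calibration, and 100 randomized configurations for the
conservation invariant — sizes chosen so the full battery runs in about a
minute while keeping Monte-Carlo error far from every decision boundary.

## Known limitations

* Simulated micromole magnitudes are calibrated for identifiability, not for
  agreement with field-scale per-sample magnitudes (see above).
* Free permutation with sequential sums of squares approximates
  reduced-model residual permutation for multi-factor calls.
* The kinetic model is linear; saturation, diel physiology and inorganic vs
  organic partitioning of released label are out of scope.
* Surface-area image measurement and water-chemistry lab processing are
  consumed as numbers, not reproduced.
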