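#' Convert delta notation to a heavy/light isotope ratio
#'
#' Inverts the defining relation of delta notation,
#' \eqn{\delta = (R/R_{std} - 1) \times 1000}, giving
#' \eqn{R = R_{std}(\delta/1000 + 1)}. Values at or below -1000 permil would
#' imply a negative heavy-isotope abundance and are rejected.
#'
#' @param delta per-mil deviation(s) from the standard; must exceed -1000.
#' @param standard element code (`"C"`, `"N"`) or a numeric standard ratio.
#' @param constants an [iso_constants()] registry.
#' @return heavy/light abundance ratio(s), same length as `delta`.
#' @seealso [ratio_to_atom_fraction()], [atom_fraction_to_delta()]
#' @examples
#' delta_to_ratio(0, "C")      # the VPDB ratio itself
#' delta_to_ratio(1000, "N")   # doubled AIR ratio
#' @export
delta_to_ratio <- function(delta, standard = "C", constants = iso_constants()) {
  stopifnot(is.numeric(delta))
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("delta at or below -1000 permil implies negative heavy-isotope abundance")
  }
  standard_ratio(standard, constants) * (delta / 1000 + 1)
}

#' Convert a heavy/light ratio to the heavy-isotope atom fraction
#'
#' For a two-isotope element, \eqn{F = R/(1+R)}: the proportion of atoms that
#' are the heavy isotope. Mole bookkeeping of tracer must happen in atom
#' fractions, not deltas.
#'
#' @param ratio non-negative heavy/light abundance ratio(s).
#' @return atom fraction(s) in `[0, 1)`.
#' @export
ratio_to_atom_fraction <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(ratio < 0, na.rm = TRUE)) stop("isotope ratio must be non-negative")
  ratio / (1 + ratio)
}

#' Convert an atom fraction back to delta notation
#'
#' Inverse chain of [delta_to_ratio()] and [ratio_to_atom_fraction()]:
#' \eqn{R = F/(1-F)}, \eqn{\delta = (R/R_{std} - 1) \times 1000}. The full
#' roundtrip is an identity to better than 1e-10 permil.
#'
#' @param f atom fraction(s) in `[0, 1)`.
#' @inheritParams delta_to_ratio
#' @return delta value(s) in permil versus the standard.
#' @export
atom_fraction_to_delta <- function(f, standard = "C", constants = iso_constants()) {
  stopifnot(is.numeric(f))
  if (any(f < 0 | f >= 1, na.rm = TRUE)) stop("atom fraction must lie in [0, 1)")
  r <- f / (1 - f)
  (r / standard_ratio(standard, constants) - 1) * 1000
}

#' Micromoles of an element in a weighed specimen
#'
#' Turns an elemental mass percentage plus dry mass into micromoles:
#' `pct/100 * dry_mass_mg / atomic_mass * 1000`.
#'
#' @param pct_element mass percent of the element, in `(0, 100]`.
#' @param dry_mass_mg specimen dry mass in mg, > 0.
#' @param element `"C"` or `"N"` (selects the atomic mass).
#' @param constants an [iso_constants()] registry.
#' @return micromoles of the element.
#' @examples
#' element_micromoles(12.011, 1, "C") # 10 umol by construction
#' @export
element_micromoles <- function(pct_element, dry_mass_mg, element = "C",
                               constants = iso_constants()) {
  stopifnot(is.numeric(pct_element), is.numeric(dry_mass_mg))
  if (any(pct_element <= 0 | pct_element > 100, na.rm = TRUE)) {
    stop("pct_element must lie in (0, 100]")
  }
  if (any(dry_mass_mg <= 0, na.rm = TRUE)) stop("dry_mass_mg must be positive")
  element <- match.arg(element, names(constants$atomic_mass))
  pct_element / 100 * dry_mass_mg / constants$atomic_mass[[element]] * 1000
}

#' Excess heavy-isotope incorporation above baseline
#'
#' Micromoles of tracer in a specimen beyond natural abundance:
#' `(F_sample - F_baseline) * total_umol`. The result is deliberately allowed
#' to be negative - a net loss of label relative to baseline is a real,
#' reportable flux - and is never clipped.
#'
#' @param f_sample measured heavy-isotope atom fraction(s), in `[0, 1)`.
#' @param f_baseline natural-abundance baseline atom fraction(s), in `[0, 1)`.
#' @param total_umol total micromoles of the element in the specimen, > 0.
#' @return micromoles of excess heavy isotope (signed).
#' @export
excess_incorporation <- function(f_sample, f_baseline, total_umol) {
  stopifnot(is.numeric(f_sample), is.numeric(f_baseline), is.numeric(total_umol))
  if (any(f_sample < 0 | f_sample >= 1, na.rm = TRUE) ||
      any(f_baseline < 0 | f_baseline >= 1, na.rm = TRUE)) {
    stop("atom fractions must lie in [0, 1)")
  }
  if (any(total_umol <= 0, na.rm = TRUE)) stop("total_umol must be positive")
  (f_sample - f_baseline) * total_umol
}

#' Incorporation rate per mmol of element per hour of exposure
#'
#' Normalizes excess incorporation to the elemental pool of the initial
#' (pre-chase) specimen and to the hours of exposure to labeled material:
#' `excess_umol / baseline_element_mmol / exposure_h`, in
#' umol mmol^-1 h^-1. Sign follows the excess.
#'
#' @param excess_umol signed excess incorporation, umol.
#' @param baseline_element_mmol mmol of the element in the initial sample, > 0.
#' @param exposure_h hours of exposure during the chase, > 0 (time-zero
#'   specimens have no rate).
#' @return incorporation rate(s), umol mmol^-1 h^-1.
#' @export
incorporation_rate <- function(excess_umol, baseline_element_mmol, exposure_h) {
  stopifnot(is.numeric(excess_umol), is.numeric(baseline_element_mmol),
            is.numeric(exposure_h))
  if (any(baseline_element_mmol <= 0, na.rm = TRUE)) {
    stop("baseline_element_mmol must be positive")
  }
  if (any(exposure_h <= 0, na.rm = TRUE)) {
    stop("exposure_h must be positive; samples taken before the chase have no rate")
  }
  excess_umol / baseline_element_mmol / exposure_h
}

#' Molar C:N ratio from mass percentages
#'
#' `(pctC / M_C) / (pctN / M_N)` with the registry atomic masses.
#'
#' @param pct_c,pct_n mass percent carbon and nitrogen, both > 0.
#' @param constants an [iso_constants()] registry.
#' @return dimensionless molar C:N ratio(s).
#' @export
molar_cn_ratio <- function(pct_c, pct_n, constants = iso_constants()) {
  stopifnot(is.numeric(pct_c), is.numeric(pct_n))
  if (any(pct_c <= 0, na.rm = TRUE) || any(pct_n <= 0, na.rm = TRUE)) {
    stop("pct_c and pct_n must be positive")
  }
  (pct_c / constants$atomic_mass[["C"]]) / (pct_n / constants$atomic_mass[["N"]])
}

#' Atom fraction of a delta value
#'
#' Convenience composition `ratio_to_atom_fraction(delta_to_ratio(...))`, the
#' direction used throughout the pipeline.
#'
#' @inheritParams delta_to_ratio
#' @return atom fraction(s).
#' @export
delta_to_atom_fraction <- function(delta, standard = "C",
                                   constants = iso_constants()) {
  ratio_to_atom_fraction(delta_to_ratio(delta, standard, constants))
}
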