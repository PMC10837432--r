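#' Isotope constants registry
#'
#' Central registry of the physical constants every conversion in the package
#' uses: the international standard heavy/light abundance ratios (VPDB for
#' carbon, atmospheric N2 for nitrogen), atomic masses, and heavy-isotope
#' labels. The analysis and the simulator share this registry so the two can
#' never drift apart. All values can be overridden, e.g. to use revised
#' standard ratios.
#'
#' @param overrides optional named list; any of `standards$C$ratio`,
#'   `standards$N$ratio`, `atomic_mass` (named numeric, g/mol) may be
#'   replaced. Partial overrides are merged into the defaults.
#' @return a list of class `iso_constants` with elements `standards`
#'   (per-element list with `name` and `ratio`), `atomic_mass` (named numeric,
#'   g/mol) and `heavy_label` (named character).
#' @examples
#' iso_constants()$standards$C$ratio # 0.011180 (VPDB 13C/12C)
#' iso_constants(list(atomic_mass = c(C = 12)))$atomic_mass[["C"]]
#' @export
iso_constants <- function(overrides = NULL) {
  cst <- list(
    standards = list(
      C = list(element = "C", name = "VPDB", ratio = 0.011180),
      N = list(element = "N", name = "AIR",  ratio = 0.0036765)
    ),
    atomic_mass = c(C = 12.011, N = 14.007),
    heavy_label = c(C = "13C", N = "15N")
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    if (!is.null(overrides$standards)) {
      for (el in names(overrides$standards)) {
        cst$standards[[el]] <- utils::modifyList(
          cst$standards[[el]] %||% list(element = el),
          overrides$standards[[el]]
        )
      }
    }
    if (!is.null(overrides$atomic_mass)) {
      cst$atomic_mass[names(overrides$atomic_mass)] <- overrides$atomic_mass
    }
    if (!is.null(overrides$heavy_label)) {
      cst$heavy_label[names(overrides$heavy_label)] <- overrides$heavy_label
    }
  }
  for (el in names(cst$standards)) {
    if (!is.finite(cst$standards[[el]]$ratio) || cst$standards[[el]]$ratio <= 0) {
      stop("standard ratio for ", el, " must be a positive number")
    }
  }
  if (any(!is.finite(cst$atomic_mass)) || any(cst$atomic_mass <= 0)) {
    stop("atomic masses must be positive")
  }
  class(cst) <- "iso_constants"
  cst
}

#' Look up the standard abundance ratio for an element
#'
#' @param standard either an element code (`"C"` or `"N"`) resolved through
#'   the registry, or directly a positive numeric heavy/light ratio.
#' @param constants an [iso_constants()] registry.
#' @return the heavy/light abundance ratio of the reference standard.
#' @export
standard_ratio <- function(standard, constants = iso_constants()) {
  if (is.numeric(standard)) {
    if (length(standard) != 1L || !is.finite(standard) || standard <= 0) {
      stop("a numeric standard must be a single positive ratio")
    }
    return(standard)
  }
  std <- constants$standards[[match.arg(standard, names(constants$standards))]]
  std$ratio
}

`%||%` <- function(a, b) if (is.null(a)) b else a
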