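#' Symbiodiniaceae density from subsample counts
#'
#' Scales a haemocytometer-style count made on a diluted aliquot of the fixed
#' algal homogenate up to the whole fragment, then normalizes by fragment
#' surface area:
#' `cells/ml = counted_cells / counted_volume_ml * dilution_factor`,
#' `cells/fragment = cells/ml * homogenate_volume_ml`,
#' `cells/cm2 = cells/fragment / surface_area_cm2`.
#' Any fixation dilution (e.g. a 1:1 paraformaldehyde step) is expected to be
#' folded into `dilution_factor` by the data loader; the chain itself is a
#' pure scaling.
#'
#' @param records data.frame with columns `counted_cells` (integer >= 0),
#'   `counted_volume_ml` (> 0), `dilution_factor` (>= 1),
#'   `homogenate_volume_ml` (> 0) and `surface_area_cm2` (> 0); extra columns
#'   (e.g. `fragment_id`, `sa_method`) are carried through.
#' @return the input with `cells_per_ml`, `cells_per_fragment` and
#'   `cells_per_cm2` appended.
#' @examples
#' estimate_density(data.frame(
#'   counted_cells = 50, counted_volume_ml = 1, dilution_factor = 10,
#'   homogenate_volume_ml = 100, surface_area_cm2 = 10
#' ))$cells_per_cm2 # 5000
#' @export
estimate_density <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("counted_cells", "counted_volume_ml", "dilution_factor",
            "homogenate_volume_ml", "surface_area_cm2")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  with(records, {
    if (any(counted_cells < 0) || any(counted_cells != round(counted_cells))) {
      stop("counted_cells must be non-negative integers")
    }
    if (any(counted_volume_ml <= 0) || any(homogenate_volume_ml <= 0)) {
      stop("volumes must be strictly positive")
    }
    if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
    if (any(surface_area_cm2 <= 0)) stop("surface_area_cm2 must be strictly positive")
  })
  records$cells_per_ml <- records$counted_cells / records$counted_volume_ml *
    records$dilution_factor
  records$cells_per_fragment <- records$cells_per_ml * records$homogenate_volume_ml
  records$cells_per_cm2 <- records$cells_per_fragment / records$surface_area_cm2
  records
}

#' Agreement between two surface-area methods
#'
#' Compares paired per-fragment surface areas from photographic (ImageJ) and
#' foil-wrapping measurements: per-fragment ratio, mean ratio, and Spearman
#' rank correlation. This is a report-only consistency check - the pipeline
#' consumes the photographic values.
#'
#' @param records data.frame with columns `fragment_id`, `imagej_cm2`,
#'   `foil_cm2`. Fragments missing either measurement are excluded with a
#'   warning.
#' @return list of class `sa_comparison`: `pairs` (per-fragment table with
#'   `ratio` = imagej/foil), `mean_ratio`, `spearman_rho`, `n`.
#' @export
compare_sa_methods <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("fragment_id", "imagej_cm2", "foil_cm2") %in% names(records)))
  complete <- stats::complete.cases(records[, c("imagej_cm2", "foil_cm2")])
  if (any(!complete)) {
    warning(sum(!complete), " unpaired fragment(s) excluded: ",
            paste(records$fragment_id[!complete], collapse = ", "))
    records <- records[complete, , drop = FALSE]
  }
  if (nrow(records) < 2L) stop("need at least 2 paired fragments")
  if (any(records$imagej_cm2 <= 0) || any(records$foil_cm2 <= 0)) {
    stop("surface areas must be strictly positive")
  }
  pairs <- records[, c("fragment_id", "imagej_cm2", "foil_cm2")]
  pairs$ratio <- pairs$imagej_cm2 / pairs$foil_cm2
  res <- list(
    pairs = pairs,
    mean_ratio = mean(pairs$ratio),
    spearman_rho = stats::cor(pairs$imagej_cm2, pairs$foil_cm2,
                              method = "spearman"),
    n = nrow(pairs)
  )
  class(res) <- "sa_comparison"
  res
}

#' @export
print.sa_comparison <- function(x, ...) {
  cat("Surface-area method comparison (imagej vs foil)\n")
  cat(sprintf("  paired fragments: %d\n", x$n))
  cat(sprintf("  mean imagej/foil ratio: %.4f\n", x$mean_ratio))
  cat(sprintf("  Spearman rank correlation: %.4f\n", x$spearman_rho))
  invisible(x)
}
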