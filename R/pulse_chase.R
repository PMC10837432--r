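#' Pulse-chase experimental design constants
#'
#' Timeline of the labeling design: a 3 h pulse in spiked water, a 1 h rinse,
#' and a 6 h chase, with destructive sampling at hours 0 (T0), 3 (end of
#' pulse, sponges only), 7 (T3) and 10 (T6). Exposure used for incorporation
#' rates is time spent in the chase: 3 h at T3 and 6 h at T6.
#'
#' @param pulse_h,rinse_h,chase_h phase durations in hours.
#' @return list of class `experiment_design` with `timepoint_hours` and
#'   `chase_exposure_hours` lookup vectors.
#' @export
experiment_design <- function(pulse_h = 3, rinse_h = 1, chase_h = 6) {
  stopifnot(pulse_h > 0, rinse_h >= 0, chase_h > 0)
  d <- list(
    pulse_h = pulse_h, rinse_h = rinse_h, chase_h = chase_h,
    timepoint_hours = c(
      T0 = 0, PULSE = pulse_h,
      T3 = pulse_h + rinse_h + chase_h / 2,
      T6 = pulse_h + rinse_h + chase_h
    ),
    chase_exposure_hours = c(T3 = chase_h / 2, T6 = chase_h)
  )
  class(d) <- "experiment_design"
  d
}

.timepoints <- c("T0", "PULSE", "T3", "T6")
.fractions  <- c("sponge_tissue", "coral_host", "symbiodiniaceae")
.elements   <- c("C", "N")

delta_column <- function(element) {
  c(C = "delta13C", N = "delta15N")[[element]]
}
pct_column <- function(element) {
  c(C = "pctC", N = "pctN")[[element]]
}

#' Compute natural-abundance baselines per species, fraction and element
#'
#' Baselines are the subtrahend for all enrichment arithmetic. Two policies:
#' \describe{
#'   \item{`t0_mean`}{mean over the treatment-agnostic time-zero specimens of
#'     each species x fraction (the default; the only option for sponges,
#'     which have no control tanks).}
#'   \item{`time_matched_control`}{mean over control-tank specimens of the
#'     same species x fraction at each chase timepoint (corals only).}
#' }
#' Averaging happens in atom-fraction space; the reported baseline delta is
#' the mean atom fraction converted back. The elemental pool used later as
#' the rate denominator (`element_umol`) is always the mean over T0
#' specimens, matching the "initial sample" definition of the rate, since
#' scored fragments are destroyed at later timepoints.
#'
#' @param samples a bulk-sample table as returned by [read_samples()] or
#'   [simulate_pulse_chase()].
#' @param policy baseline policy, see above.
#' @param constants an [iso_constants()] registry.
#' @return data.frame of class `baseline_table`: one row per species x
#'   fraction x element (x timepoint under `time_matched_control`) with
#'   `f_baseline`, `delta_baseline`, `element_umol`, `n`, `policy`.
#' @export
compute_baselines <- function(samples,
                              policy = c("t0_mean", "time_matched_control"),
                              constants = iso_constants()) {
  policy <- match.arg(policy)
  samples <- validate_samples(samples)

  t0_rows <- samples[samples$timepoint == "T0", , drop = FALSE]
  base_rows <- if (policy == "t0_mean") {
    t0_rows
  } else {
    # corals only; sponges (which have no control tanks) are handled below
    # by falling back to their T0 means
    samples[samples$treatment == "control" & samples$timepoint %in% c("T3", "T6"), ,
            drop = FALSE]
  }
  if (nrow(base_rows) == 0L) {
    stop("no baseline samples available under policy '", policy, "'")
  }

  out <- list()
  for (el in .elements) {
    f <- delta_to_atom_fraction(base_rows[[delta_column(el)]], el, constants)
    umol_t0 <- element_micromoles(t0_rows[[pct_column(el)]], t0_rows$dry_mass_mg,
                                  el, constants)
    keys <- if (policy == "t0_mean") {
      interaction(base_rows$species, base_rows$fraction, drop = TRUE, sep = "\r")
    } else {
      interaction(base_rows$species, base_rows$fraction, base_rows$timepoint,
                  drop = TRUE, sep = "\r")
    }
    f_mean <- tapply(f, keys, mean)
    n <- tapply(f, keys, length)
    parts <- do.call(rbind, strsplit(names(f_mean), "\r", fixed = TRUE))
    umol_mean <- tapply(umol_t0,
                        interaction(t0_rows$species, t0_rows$fraction,
                                    drop = TRUE, sep = "\r"),
                        mean)
    umol_key <- paste(parts[, 1], parts[, 2], sep = "\r")
    out[[el]] <- data.frame(
      species = parts[, 1],
      fraction = parts[, 2],
      element = el,
      timepoint = if (policy == "t0_mean") NA_character_ else parts[, 3],
      f_baseline = as.numeric(f_mean),
      delta_baseline = atom_fraction_to_delta(as.numeric(f_mean), el, constants),
      element_umol = as.numeric(umol_mean[umol_key]),
      n = as.integer(n),
      policy = policy,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (policy == "time_matched_control" &&
      any(samples$organism == "sponge")) {
    sponge_t0 <- compute_baselines(
      samples[samples$organism == "sponge", , drop = FALSE],
      "t0_mean", constants)
    res <- rbind(res, as.data.frame(sponge_t0))
  }
  rownames(res) <- NULL
  class(res) <- c("baseline_table", "data.frame")
  res
}

baseline_lookup <- function(baselines, species, fraction, element, timepoint) {
  hit <- baselines$species == species & baselines$fraction == fraction &
    baselines$element == element &
    (is.na(baselines$timepoint) | baselines$timepoint == timepoint)
  idx <- which(hit)
  if (length(idx) == 0L) {
    stop("no baseline for (", species, ", ", fraction, ", ", element,
         if (!anyNA(baselines$timepoint)) paste0(", ", timepoint), ")")
  }
  baselines[idx[1L], ]
}

#' Per-sample excess incorporation and incorporation rates
#'
#' Scores every enriched specimen against its baseline for both elements:
#' delta change, excess heavy-isotope micromoles, and - for chase timepoints
#' T3/T6 - the incorporation rate per mmol of element in the initial sample
#' per hour of chase exposure. Time-zero and pulse specimens carry no rate.
#'
#' @param samples bulk-sample table.
#' @param baselines a [compute_baselines()] table; computed from `samples`
#'   with `policy` when `NULL`.
#' @param design an [experiment_design()].
#' @param policy baseline policy passed on when `baselines` is `NULL`.
#' @param constants an [iso_constants()] registry.
#' @return data.frame of class `incorporation_table`: one row per enriched
#'   sample x element with identity columns, `delta_change`, `excess_umol`,
#'   `baseline_mmol`, `exposure_h` and `rate`.
#' @export
compute_incorporation <- function(samples, baselines = NULL,
                                  design = experiment_design(),
                                  policy = "t0_mean",
                                  constants = iso_constants()) {
  samples <- validate_samples(samples)
  if (is.null(baselines)) {
    baselines <- compute_baselines(samples, policy, constants)
  }
  scored <- samples[samples$treatment == "enriched", , drop = FALSE]
  if (nrow(scored) == 0L) stop("no enriched samples to score")

  out <- vector("list", 2L * nrow(scored))
  k <- 0L
  for (i in seq_len(nrow(scored))) {
    row <- scored[i, ]
    for (el in .elements) {
      b <- tryCatch(
        baseline_lookup(baselines, row$species, row$fraction, el, row$timepoint),
        error = function(e) {
          stop("sample '", row$sample_id, "': ", conditionMessage(e), call. = FALSE)
        }
      )
      f_s <- delta_to_atom_fraction(row[[delta_column(el)]], el, constants)
      umol <- element_micromoles(row[[pct_column(el)]], row$dry_mass_mg, el,
                                 constants)
      exc <- excess_incorporation(f_s, b$f_baseline, umol)
      expo <- unname(design$chase_exposure_hours[row$timepoint])
      rate <- if (!is.na(expo)) {
        incorporation_rate(exc, b$element_umol / 1000, expo)
      } else NA_real_
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = row$sample_id, species = row$species,
        fraction = row$fraction, timepoint = row$timepoint,
        tank_id = row$tank_id, element = el,
        delta_sample = row[[delta_column(el)]],
        delta_baseline = b$delta_baseline,
        delta_change = row[[delta_column(el)]] - b$delta_baseline,
        f_sample = f_s, f_baseline = b$f_baseline,
        sample_umol = umol,
        excess_umol = exc,
        baseline_mmol = b$element_umol / 1000,
        exposure_h = if (is.na(expo)) NA_real_ else expo,
        rate = rate,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  class(res) <- c("incorporation_table", "data.frame")
  res
}

#' Holobiont 15N:13C incorporation fold-ratio per coral species
#'
#' For each coral species, the ratio of summed holobiont (host + symbiont)
#' excess 15N to summed excess 13C at the requested timepoint. A zero or
#' negative carbon denominator is flagged (`defined = FALSE`) rather than
#' dropped: a net-negative carbon flux is a real outcome.
#'
#' @param results an [compute_incorporation()] table.
#' @param timepoint chase timepoint at which to take totals (default `"T6"`).
#' @return data.frame with per-species summed excesses, `fold_ratio` and
#'   `defined`; the min/max over species with a defined ratio is attached as
#'   attribute `"range"`.
#' @export
fold_ratio_n_vs_c <- function(results, timepoint = "T6") {
  stopifnot(inherits(results, "data.frame"))
  cor <- results[results$fraction %in% c("coral_host", "symbiodiniaceae") &
                   results$timepoint == timepoint, , drop = FALSE]
  if (nrow(cor) == 0L) stop("no coral results at timepoint ", timepoint)
  sp <- sort(unique(cor$species))
  n15 <- vapply(sp, function(s)
    sum(cor$excess_umol[cor$species == s & cor$element == "N"]), numeric(1))
  c13 <- vapply(sp, function(s)
    sum(cor$excess_umol[cor$species == s & cor$element == "C"]), numeric(1))
  if (any(n15 == 0 & c13 == 0)) stop("species with no excess in either element")
  res <- data.frame(
    species = sp, excess_15N_umol = n15, excess_13C_umol = c13,
    fold_ratio = ifelse(c13 > 0, n15 / c13, NA_real_),
    defined = c13 > 0, stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  ok <- res$defined
  attr(res, "range") <- if (any(ok)) range(res$fold_ratio[ok]) else c(NA_real_, NA_real_)
  res
}

#' Group summaries in the boxplot convention
#'
#' Five-number-style summaries per group: n, mean, linear-interpolation
#' quartiles (R's default type-7 convention), whiskers extending to the most
#' extreme value within 1.5 x IQR of the hinges, and the values beyond the
#' whiskers as outliers.
#'
#' @param results an [compute_incorporation()] table (or any data.frame).
#' @param by character vector of grouping columns.
#' @param value name of the numeric column to summarize.
#' @return data.frame with one row per group: `n`, `mean`, `median`, `q1`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `n_outliers` and `outliers`
#'   (semicolon-separated values).
#' @export
summarize_groups <- function(results,
                             by = c("species", "fraction", "timepoint", "element"),
                             value = "excess_umol") {
  stopifnot(inherits(results, "data.frame"), all(by %in% names(results)),
            value %in% names(results))
  x <- results[[value]]
  keep <- !is.na(x)
  x <- x[keep]
  keys <- interaction(results[keep, by, drop = FALSE], drop = TRUE, sep = "\r")
  groups <- split(x, keys)
  stats <- lapply(groups, function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v >= lo_fence & v <= hi_fence
    out <- v[!inside]
    data.frame(
      n = length(v), mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
      whisker_lo = min(v[inside]), whisker_hi = max(v[inside]),
      n_outliers = length(out),
      outliers = paste(format(out, trim = TRUE), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  colnames(parts) <- by
  res <- cbind(as.data.frame(parts, stringsAsFactors = FALSE),
               do.call(rbind, stats))
  rownames(res) <- NULL
  res
}

#' Paired host/symbiont excess totals per coral species
#'
#' Per species and element at the requested timepoint: the mean excess of the
#' host fraction, of the Symbiodiniaceae fraction, and their sum (the
#' holobiont total), with per-fraction sample sizes for provenance. A species
#' missing one fraction is kept as a partial record with `complete = FALSE`.
#'
#' @inheritParams fold_ratio_n_vs_c
#' @return data.frame with `host_excess_umol`, `symbiont_excess_umol`,
#'   `holobiont_excess_umol`, `n_host`, `n_symbiont`, `complete`.
#' @export
assemble_holobiont_totals <- function(results, timepoint = "T6") {
  cor <- results[results$fraction %in% c("coral_host", "symbiodiniaceae") &
                   results$timepoint == timepoint, , drop = FALSE]
  if (nrow(cor) == 0L) stop("no coral results at timepoint ", timepoint)
  grid <- expand.grid(species = sort(unique(cor$species)), element = .elements,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$species[i]; el <- grid$element[i]
    host <- cor$excess_umol[cor$species == s & cor$element == el &
                              cor$fraction == "coral_host"]
    symb <- cor$excess_umol[cor$species == s & cor$element == el &
                              cor$fraction == "symbiodiniaceae"]
    complete <- length(host) > 0 && length(symb) > 0
    if (!complete) {
      warning("species ", s, " element ", el, " is missing a fraction at ",
              timepoint, "; partial record flagged", call. = FALSE)
    }
    hm <- if (length(host)) mean(host) else NA_real_
    sm <- if (length(symb)) mean(symb) else NA_real_
    data.frame(
      species = s, element = el,
      host_excess_umol = hm, symbiont_excess_umol = sm,
      holobiont_excess_umol = sum(c(hm, sm), na.rm = !complete),
      n_host = length(host), n_symbiont = length(symb),
      complete = complete, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
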