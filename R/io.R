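.sample_columns <- c("sample_id", "organism", "species", "fraction",
                     "treatment", "timepoint", "tank_id", "delta13C",
                     "delta15N", "pctC", "pctN", "dry_mass_mg")

.count_columns <- c("fragment_id", "counted_cells", "counted_volume_ml",
                    "dilution_factor", "homogenate_volume_ml",
                    "surface_area_cm2", "sa_method")

apply_column_map <- function(df, column_map, required) {
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(df)) {
        stop("column_map points '", canonical, "' at missing column '", src, "'")
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " (use column_map to rename source headers)")
  }
  df[, required, drop = FALSE]
}

# row-level invariant checks; returns character reason or NA
sample_row_problem <- function(row) {
  if (!row$organism %in% c("sponge", "coral")) return("unknown organism")
  if (!row$fraction %in% .fractions) return("unknown fraction")
  if (row$organism == "sponge" && row$fraction != "sponge_tissue") {
    return("sponges cannot carry a coral fraction")
  }
  if (row$organism == "coral" && row$fraction == "sponge_tissue") {
    return("corals cannot carry the sponge fraction")
  }
  if (!row$treatment %in% c("enriched", "control")) return("unknown treatment")
  if (row$treatment == "control" && row$organism != "coral") {
    return("control treatment exists only for corals")
  }
  if (!row$timepoint %in% .timepoints) return("unknown timepoint")
  if (row$timepoint == "PULSE" && row$organism != "sponge") {
    return("the end-of-pulse timepoint exists only for sponges")
  }
  if (!is.finite(row$delta13C) || row$delta13C <= -1000) return("invalid delta13C")
  if (!is.finite(row$delta15N) || row$delta15N <= -1000) return("invalid delta15N")
  if (!is.finite(row$pctC) || row$pctC <= 0 || row$pctC > 100) return("invalid pctC")
  if (!is.finite(row$pctN) || row$pctN <= 0 || row$pctN > 100) return("invalid pctN")
  if (!is.finite(row$dry_mass_mg) || row$dry_mass_mg <= 0) return("invalid dry_mass_mg")
  NA_character_
}

#' Validate a bulk-sample table
#'
#' Checks column presence and the structural invariants of the design
#' (fractions consistent with organism, control treatment only for corals,
#' end-of-pulse sampling only for sponges, physical ranges on deltas,
#' percentages and mass). Invalid rows are dropped with a warning naming the
#' row numbers and reasons; the dropped rows are attached as attribute
#' `"rejected"`.
#'
#' @param samples data.frame with the canonical bulk-sample columns.
#' @return the validated (possibly reduced) data.frame.
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  missing <- setdiff(.sample_columns, names(samples))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(attr(samples, "validated"))) return(samples)
  reasons <- vapply(seq_len(nrow(samples)),
                    function(i) sample_row_problem(samples[i, ]), character(1))
  bad <- !is.na(reasons)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: ",
            paste0("row ", which(bad), " (", reasons[bad], ")", collapse = "; "))
    rejected <- cbind(samples[bad, , drop = FALSE], reason = reasons[bad])
    samples <- samples[!bad, , drop = FALSE]
    attr(samples, "rejected") <- rejected
  }
  if (nrow(samples) == 0L) stop("no valid sample rows remain")
  attr(samples, "validated") <- TRUE
  samples
}

#' Read a bulk-sample CSV
#'
#' Reads a delimited table of per-specimen isotope measurements. Deposited
#' datasets with different headers are ingested by supplying `column_map`, a
#' named character vector `c(canonical = "source header", ...)`. Rows
#' violating design invariants are rejected individually (with line numbers)
#' rather than failing the whole file.
#'
#' @param path CSV file path.
#' @param column_map optional header mapping, see above.
#' @return validated bulk-sample data.frame (rejected rows in attribute
#'   `"rejected"`).
#' @export
read_samples <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_column_map(df, column_map, .sample_columns)
  validate_samples(df)
}

#' Read a cell-count / surface-area CSV
#'
#' @param path CSV file path with the columns of [estimate_density()] records
#'   plus `fragment_id` and `sa_method`.
#' @param column_map optional header mapping as in [read_samples()].
#' @return data.frame of cell-count records.
#' @export
read_cell_counts <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  apply_column_map(df, column_map, .count_columns)
}

stats_row <- function(element, response, subset, factor_name, fit) {
  data.frame(
    element = element, response = response, subset = subset,
    factor = factor_name, df = fit$tab$df[1], pseudo_F = fit$pseudo_F,
    R2 = fit$R2, p_perm = fit$p_perm, p_adj = NA_real_,
    n_perm = fit$n_perm, method = fit$method, stringsAsFactors = FALSE
  )
}

# the statistical battery applied to an incorporation table (corals, chase)
run_stats <- function(results, permutations, seed) {
  if (!is.null(seed)) set.seed(seed)
  cor_rows <- results[results$fraction %in% c("coral_host", "symbiodiniaceae") &
                        results$timepoint %in% c("T3", "T6"), ]
  out <- list()
  for (el in c("C", "N")) {
    for (resp in c("excess_umol", "rate")) {
      sub <- cor_rows[cor_rows$element == el & !is.na(cor_rows[[resp]]), ]
      if (nrow(sub) < 4L) next
      d <- euclidean_dist(sub[[resp]])
      out[[length(out) + 1L]] <- stats_row(
        el, resp, "corals:T3+T6", "fraction",
        permanova(d, factor(sub$fraction), permutations))
      for (fr in unique(sub$fraction)) {
        ss <- sub[sub$fraction == fr, ]
        if (length(unique(ss$species)) < 2L || nrow(ss) < 4L) next
        dfr <- euclidean_dist(ss[[resp]])
        out[[length(out) + 1L]] <- stats_row(
          el, resp, paste0(fr, ":T3+T6"), "species",
          permanova(dfr, factor(ss$species), permutations))
        out[[length(out) + 1L]] <- stats_row(
          el, resp, paste0(fr, ":T3+T6"), "timepoint",
          permanova(dfr, factor(ss$timepoint), permutations))
        pw <- pairwise_permanova(dfr, factor(ss$species), permutations)
        for (i in seq_len(nrow(pw))) {
          out[[length(out) + 1L]] <- data.frame(
            element = el, response = resp, subset = paste0(fr, ":T3+T6"),
            factor = paste0("species:", pw$group1[i], " vs ", pw$group2[i]),
            df = 1L, pseudo_F = pw$pseudo_F[i], R2 = pw$R2[i],
            p_perm = pw$p_perm[i], p_adj = pw$p_adj[i],
            n_perm = pw$n_perm[i], method = pw$method[i],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' One reproducible end-to-end run: load (or simulate) samples, compute
#' baselines and per-sample incorporation, group summaries, holobiont totals
#' and the 15N:13C fold-ratio, run the permutational statistics battery,
#' optionally estimate Symbiodiniaceae densities, and write everything plus
#' a machine-readable JSON run report to `out_dir`. Outputs are deterministic
#' for a given seed. Results are computed in full before any file is written,
#' so a failing stage leaves no partial output.
#'
#' @param config a list (or path to a YAML/JSON file encoding one) with
#'   fields: exactly one of `simulate` (arguments to [sim_config()]) or
#'   `samples_csv`; optional `cell_counts_csv`, `column_map`,
#'   `baseline_policy` (default `"t0_mean"`), `permutations` (default 999),
#'   `seed` (default 1), `constants` (overrides for [iso_constants()]); and
#'   `out_dir`.
#' @return (invisibly) a list with all result tables and the report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  if (is.null(config$simulate) == is.null(config$samples_csv)) {
    stop("exactly one of 'simulate' or 'samples_csv' must be given")
  }
  permutations <- config$permutations %||% 999
  stopifnot(permutations >= 1)
  seed <- config$seed %||% 1
  policy <- config$baseline_policy %||% "t0_mean"
  constants <- iso_constants(config$constants)

  if (!is.null(config$simulate)) {
    message("stage simulate: generating synthetic cohort (seed ", seed, ")")
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% seed
    sim_args$constants <- constants
    sim <- simulate_pulse_chase(do.call(sim_config, sim_args))
    samples <- sim$samples
  } else {
    message("stage load: reading ", config$samples_csv)
    sim <- NULL
    samples <- read_samples(config$samples_csv, config$column_map)
  }
  message("stage load: ", nrow(samples), " sample rows in")

  baselines <- compute_baselines(samples, policy, constants)
  results <- compute_incorporation(samples, baselines, experiment_design(),
                                   constants = constants)
  message("stage incorporation: ", nrow(results), " sample x element results")
  summaries <- summarize_groups(results)
  totals <- assemble_holobiont_totals(results)
  folds <- fold_ratio_n_vs_c(results)
  stats_tab <- run_stats(results, permutations, seed)
  message("stage stats: ", nrow(stats_tab), " tests")

  density <- NULL
  if (!is.null(config$cell_counts_csv)) {
    counts <- read_cell_counts(config$cell_counts_csv, config$column_map)
    density <- estimate_density(counts)
    message("stage density: ", nrow(density), " fragments")
  }

  report <- list(
    package = "isopulse",
    version = as.character(utils::packageVersion("isopulse")),
    seed = seed, permutations = permutations, baseline_policy = policy,
    constants = list(
      standard_ratio_C = constants$standards$C$ratio,
      standard_ratio_N = constants$standards$N$ratio,
      atomic_mass = as.list(constants$atomic_mass)
    ),
    n_samples = nrow(samples),
    samples_per_group = as.list(table(paste(samples$species, samples$fraction,
                                            samples$timepoint)))
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  wr(results, "incorporation.csv")
  wr(summaries, "group_summaries.csv")
  wr(totals, "holobiont_totals.csv")
  wr(folds, "fold_ratios.csv")
  wr(stats_tab, "stats.csv")
  if (!is.null(density)) wr(density, "density.csv")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("stage write: outputs in ", config$out_dir)

  invisible(list(samples = samples, baselines = baselines, results = results,
                 summaries = summaries, totals = totals, fold_ratios = folds,
                 stats = stats_tab, density = density, report = report,
                 sim = sim))
}
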