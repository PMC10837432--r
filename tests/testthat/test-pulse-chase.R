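test_that("design timeline: chase exposure equals elapsed time minus pulse+rinse", {
  d <- experiment_design()
  expect_equal(unname(d$timepoint_hours), c(0, 3, 7, 10))
  for (tp in c("T3", "T6")) {
    expect_equal(d$chase_exposure_hours[[tp]],
                 d$timepoint_hours[[tp]] - (d$pulse_h + d$rinse_h))
  }
})

test_that("baselines average in atom-fraction space", {
  s <- rbind(tiny_samples(delta15N_t0 = 4), tiny_samples(delta15N_t0 = 6))
  s$sample_id <- paste0(s$sample_id, seq_len(nrow(s)))
  b <- compute_baselines(s)
  bn <- b[b$element == "N" & b$fraction == "coral_host", ]
  f_expected <- mean(delta_to_atom_fraction(c(4, 6), "N"))
  expect_equal(bn$f_baseline, f_expected, tolerance = 1e-15)
  expect_equal(bn$delta_baseline, atom_fraction_to_delta(f_expected, "N"))
  expect_equal(bn$delta_baseline, 5, tolerance = 1e-3) # near-linear at natural abundance
  expect_equal(bn$n, 2L)

  single <- compute_baselines(tiny_samples())
  sn <- single[single$element == "N" & single$fraction == "coral_host", ]
  expect_equal(sn$delta_baseline, 5, tolerance = 1e-10)
  expect_equal(sn$n, 1L)
})

test_that("a missing baseline group fails naming the offending key", {
  s <- tiny_samples()
  s <- s[s$fraction != "symbiodiniaceae" | s$timepoint != "T0", ]
  expect_error(compute_incorporation(s), "symbiodiniaceae")
})

test_that("incorporation table reproduces the hand-built tracer chain", {
  # enriched T3 sample: d15N 1005 vs baseline 5, 10 umol N (pctN = M_N, 1 mg)
  res <- compute_incorporation(tiny_samples())
  rn <- res[res$element == "N" & res$fraction == "coral_host", ]
  expect_equal(nrow(rn), 1L)
  expect_equal(rn$delta_change, 1000, tolerance = 1e-9)
  r1 <- 0.0036765 * 2.005; f1 <- r1 / (1 + r1)
  r0 <- 0.0036765 * 1.005; f0 <- r0 / (1 + r0)
  expect_equal(rn$excess_umol, (f1 - f0) * 10, tolerance = 1e-12)
  expect_equal(rn$exposure_h, 3)
  # rate = excess / (0.01 mmol) / 3 h
  expect_equal(rn$rate, rn$excess_umol / 0.01 / 3, tolerance = 1e-12)

  # a sample identical to its baseline scores zero excess and zero rate
  s0 <- tiny_samples(delta15N_t3 = 5)
  r0 <- compute_incorporation(s0)
  expect_equal(r0$excess_umol[r0$element == "N"], c(0, 0), tolerance = 1e-15)
  expect_equal(r0$rate[r0$element == "N"], c(0, 0), tolerance = 1e-15)
})

test_that("rate x exposure x baseline pool equals excess for every chase sample", {
  sim <- cached_sim(seed = 4)
  res <- compute_incorporation(sim$samples)
  chase <- res[res$timepoint %in% c("T3", "T6"), ]
  expect_true(all(!is.na(chase$rate)))
  expect_equal(chase$rate * chase$exposure_h * chase$baseline_mmol,
               chase$excess_umol, tolerance = 1e-12)
  # T0 and end-of-pulse samples carry no rate
  expect_true(all(is.na(res$rate[!res$timepoint %in% c("T3", "T6")])))
})

test_that("t0_mean and time_matched_control baselines agree under zero drift", {
  sim <- cached_sim(seed = 4)
  b_t0 <- compute_baselines(sim$samples, "t0_mean")
  b_ctl <- compute_baselines(sim$samples, "time_matched_control")
  coral <- b_ctl[b_ctl$fraction %in% c("coral_host", "symbiodiniaceae"), ]
  for (i in seq_len(nrow(coral))) {
    ref <- b_t0[b_t0$species == coral$species[i] &
                  b_t0$fraction == coral$fraction[i] &
                  b_t0$element == coral$element[i], ]
    # both estimate the same background; tolerance ~ measurement noise / sqrt(n)
    tol <- 4 * 0.1 * standard_ratio(coral$element[i]) / 1000 / sqrt(3)
    expect_lt(abs(coral$f_baseline[i] - ref$f_baseline), tol)
  }
  # sponges fall back to their T0 means under the control policy
  expect_true(any(b_ctl$fraction == "sponge_tissue"))
})

test_that("control corals show no delta drift beyond measurement noise", {
  sim <- cached_sim(seed = 4)
  s <- sim$samples
  b <- compute_baselines(s)
  ctl <- s[s$treatment == "control" & s$timepoint %in% c("T3", "T6"), ]
  for (el in c("C", "N")) {
    dcol <- if (el == "C") "delta13C" else "delta15N"
    for (key in unique(paste(ctl$species, ctl$fraction))) {
      rows <- ctl[paste(ctl$species, ctl$fraction) == key, ]
      ref <- b[b$species == rows$species[1] & b$fraction == rows$fraction[1] &
                 b$element == el, ]
      dd <- rows[[dcol]] - ref$delta_baseline
      expect_lt(abs(mean(dd)), 3 * 0.1 / sqrt(nrow(rows)) + 0.1 / sqrt(5))
    }
  }
})

test_that("fold ratio arithmetic, flagging and scale invariance", {
  res <- rbind(
    fake_results("A", "coral_host", "N", c(0.01, 0.01)),
    fake_results("A", "symbiodiniaceae", "N", c(0.0, 0.0)),
    fake_results("A", "coral_host", "C", c(0.001, 0.001)),
    fake_results("A", "symbiodiniaceae", "C", c(0.0, 0.0))
  )
  fr <- fold_ratio_n_vs_c(res)
  expect_equal(fr$fold_ratio, 10)
  expect_true(fr$defined)

  equal <- res
  equal$excess_umol[equal$element == "C"] <-
    equal$excess_umol[equal$element == "N"]
  expect_equal(fold_ratio_n_vs_c(equal)$fold_ratio, 1)

  scaled <- res
  scaled$excess_umol <- scaled$excess_umol * 7.3
  expect_equal(fold_ratio_n_vs_c(scaled)$fold_ratio, 10, tolerance = 1e-12)

  neg <- res
  neg$excess_umol[neg$element == "C"] <- -0.001
  frn <- fold_ratio_n_vs_c(neg)
  expect_false(frn$defined)
  expect_true(is.na(frn$fold_ratio))
})

test_that("group summaries follow the 1.5 IQR boxplot convention", {
  res <- fake_results("A", "coral_host", "C", c(1, 2, 3, 4, 5))
  s <- summarize_groups(res)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n_outliers, 0L)
  expect_equal(s$whisker_lo, 1)
  expect_equal(s$whisker_hi, 5)

  one <- summarize_groups(fake_results("A", "coral_host", "C", 2.5))
  expect_equal(one$mean, 2.5)
  expect_equal(one$median, 2.5)
  expect_equal(one$q1, 2.5)
  expect_equal(one$n_outliers, 0L)

  out <- summarize_groups(fake_results("A", "coral_host", "C", c(1, 2, 3, 100)))
  # type-7 quartiles: q1 = 1.75, q3 = 27.25, upper fence = 65.5
  expect_equal(out$q1, 1.75)
  expect_equal(out$q3, 27.25)
  expect_equal(out$n_outliers, 1L)
  expect_equal(out$outliers, "100")
  expect_equal(out$whisker_hi, 3)
})

test_that("holobiont totals pair host and symbiont means with provenance", {
  res <- rbind(
    fake_results("A", "coral_host", "N", c(0.0004, 0.0004)),
    fake_results("A", "symbiodiniaceae", "N", c(0.02, 0.02)),
    fake_results("A", "coral_host", "C", c(0.001, 0.003)),
    fake_results("A", "symbiodiniaceae", "C", c(0.002, 0.004))
  )
  tot <- assemble_holobiont_totals(res)
  n_row <- tot[tot$element == "N", ]
  expect_equal(n_row$holobiont_excess_umol, 0.0204)
  expect_equal(n_row$n_host, 2L)
  expect_true(all(tot$complete))

  zero <- res
  zero$excess_umol <- 0
  expect_equal(assemble_holobiont_totals(zero)$holobiont_excess_umol, c(0, 0))

  partial <- res[res$fraction == "coral_host" | res$element == "N", ]
  expect_warning(tot2 <- assemble_holobiont_totals(partial), "missing a fraction")
  expect_false(all(tot2$complete))
})
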