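lot3 <- function() data.frame(
  lot_id = c("lot1", "lot2", "lot3"),
  start = as.Date(c("2015-01-01", "2016-01-01", "2017-01-01")),
  end = as.Date(c("2016-01-01", "2017-01-01", "2019-01-01")))

test_that("batch assignment combines lots and calibration epochs", {
  # one lot, no recalibration: everything in (lot1, epoch 0)
  dates <- as.Date(c("2015-03-01", "2015-09-30"))
  one <- data.frame(lot_id = "lot1", start = as.Date("2015-01-01"),
                    end = as.Date("2016-01-01"))
  expect_identical(assign_batches(dates, one), c("lot1.e0", "lot1.e0"))
  # period boundary: assigned to the period starting that day
  b <- assign_batches(as.Date("2016-01-01"), lot3())
  expect_identical(b, "lot2.e0")
  # recalibration on the acquisition day starts a new epoch that day
  cal <- as.Date("2015-06-01")
  expect_identical(assign_batches(as.Date(c("2015-05-31", "2015-06-01")),
                                  lot3(), cal),
                   c("lot1.e0", "lot1.e1"))
  # 3 lots x 7 recalibrations: up to 21 distinct batches reachable
  cals <- seq(as.Date("2015-03-01"), as.Date("2018-09-01"), length.out = 7)
  all_days <- seq(as.Date("2015-01-02"), as.Date("2018-12-30"), by = "week")
  ids <- assign_batches(all_days, lot3(), cals)
  expect_lte(length(unique(ids)), 3 * 8)
  expect_gte(length(unique(ids)), 8)
  # date outside all periods names the sample
  expect_error(assign_batches(stats::setNames(as.Date("2020-01-01"), "s9"),
                              lot3()),
               "s9")
})

mini_table <- function(mfis, batches, instrument = "instr01",
                       dates = NULL) {
  n <- length(mfis)
  if (is.null(dates)) {
    dates <- as.Date("2015-01-01") + seq_len(n) +
      365 * (as.integer(factor(batches)) - 1)
  }
  cohort_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)), instrument_id = instrument,
    center_id = "center01", acquisition_date = dates, panel_id = "panel1",
    batch_id = batches, group = "healthy",
    freq.t_cells = 25, count.t_cells = 1250,
    mfi.t_cells.CD3 = mfis, stringsAsFactors = FALSE))
}

test_that("batch coefficients are first-batch over batch medians", {
  # single batch: all coefficients 1
  tab <- mini_table(c(900, 1000, 1100), rep("lot1.e0", 3))
  bc <- batch_coefficients(tab)
  expect_equal(bc$coefficient, 1)
  # first batch median 1000, second 800 -> coefficient 1.25
  tab2 <- mini_table(c(900, 1000, 1100, 700, 800, 900),
                     rep(c("lot1.e0", "lot2.e0"), each = 3))
  bc2 <- batch_coefficients(tab2)
  expect_equal(bc2$coefficient[bc2$batch_id == "lot2.e0"], 1.25)
  expect_equal(bc2$coefficient[bc2$batch_id == "lot1.e0"], 1)
})

test_that("simulated lot effects are recovered within sampling error", {
  # 3 batches with multiplicative effects (1, 0.8, 1.3), 50 samples each
  set.seed(60)
  true_eff <- c(1, 0.8, 1.3)
  mfis <- unlist(lapply(true_eff, function(e) e * 1000 * 10^rnorm(50, 0, 0.08)))
  tab <- mini_table(mfis, rep(c("lot1.e0", "lot2.e0", "lot3.e0"), each = 50))
  bc <- batch_coefficients(tab)
  for (i in 2:3) {
    got <- bc$coefficient[bc$batch_id == sprintf("lot%d.e0", i)]
    expect_lt(abs(got - 1 / true_eff[i]) / (1 / true_eff[i]), 0.05)
  }
})

test_that("center coefficients align instruments to the reference", {
  # identical samples on both instruments: coefficients exactly 1
  base <- c(900, 1000, 1100, 1050)
  tabs <- lapply(c("instr01", "instr02"), function(i)
    as.data.frame(mini_table(base, rep("lot1.e0", 4), instrument = i)))
  tab <- cohort_table(do.call(rbind, tabs))
  cc <- center_coefficients(tab, "instr01", require_batch_corrected = FALSE)
  expect_equal(cc$coefficient, c(1, 1))
  # uniform 2x gain on one instrument -> coefficient 0.5
  tabs[[2]]$mfi.t_cells.CD3 <- 2 * tabs[[2]]$mfi.t_cells.CD3
  tab2 <- cohort_table(do.call(rbind, tabs))
  cc2 <- center_coefficients(tab2, "instr01", require_batch_corrected = FALSE)
  expect_equal(cc2$coefficient[cc2$instrument_id == "instr02"], 0.5)
})

test_that("application rescales MFIs only and records provenance", {
  tab <- mini_table(c(400, 500, 600), rep("lot1.e0", 3))
  co <- correction_coefficients(
    data.frame(instrument_id = "instr01", batch_id = "lot1.e0",
               feature = "mfi.t_cells.CD3", coefficient = 1.25),
    scope = "batch", reference = c(instr01 = "lot1.e0"))
  out <- apply_coefficients(tab, co)
  expect_equal(out$mfi.t_cells.CD3, c(500, 625, 750))
  expect_identical(out$freq.t_cells, tab$freq.t_cells)
  expect_identical(out$count.t_cells, tab$count.t_cells)
  expect_identical(attr(out, "corrections"), "batch")
  # all-1 coefficients leave the table unchanged
  co1 <- correction_coefficients(
    data.frame(instrument_id = "instr01", batch_id = "lot1.e0",
               feature = "mfi.t_cells.CD3", coefficient = 1),
    scope = "batch", reference = c(instr01 = "lot1.e0"))
  expect_identical(apply_coefficients(tab, co1)$mfi.t_cells.CD3,
                   tab$mfi.t_cells.CD3)
  # unmapped rows error
  tab_bad <- mini_table(c(100, 200), rep("lot9.e0", 2))
  expect_error(apply_coefficients(tab_bad, co), "no batch coefficient")
})

test_that("exact invariants of the two median-ratio corrections hold", {
  cfg <- sim_config(n_centers = 5L, n_samples_per_center = 21L,
                    center_effect_range = c(0.7, 1.4), seed = 61)
  tab <- simulate_cohort_table(cfg)
  bc <- batch_coefficients(tab)
  tab_b <- apply_coefficients(tab, bc)
  cc <- suppressWarnings(center_coefficients(tab_b, "instr01"))
  tab_c <- apply_coefficients(tab_b, cc)
  feats <- mfi_columns(tab)[c(1, 20, 57)]
  for (f in feats) {
    # per-batch medians within each instrument coincide after batch step
    for (ins in unique(tab$instrument_id)) {
      sub <- tab_b[tab_b$instrument_id == ins, ]
      meds <- tapply(sub[[f]], sub$batch_id, stats::median)
      expect_equal(unname(diff(range(meds))), 0, tolerance = 1e-9)
    }
    # per-instrument medians coincide after center step
    meds <- tapply(tab_c[[f]], tab_c$instrument_id, stats::median)
    expect_equal(unname(diff(range(meds))), 0, tolerance = 1e-9)
  }
  # idempotence: coefficients recomputed on corrected tables are all 1
  expect_equal(batch_coefficients(tab_b)$coefficient,
               rep(1, nrow(bc)), tolerance = 1e-9)
  expect_equal(suppressWarnings(center_coefficients(tab_c, "instr01"))$coefficient,
               rep(1, nrow(cc)), tolerance = 1e-9)
  # frequencies and counts bit-identical through both corrections
  for (f in c(freq_columns(tab), count_columns(tab))) {
    expect_identical(tab_c[[f]], tab[[f]])
  }
})

test_that("disease-group median ratios survive both corrections", {
  # no interleaved recalibrations so every batch holds both groups
  cfg <- sim_config(n_centers = 4L, n_samples_per_center = 24L,
                    n_calibrations = 0L,
                    center_effect_range = c(0.7, 1.4), seed = 62)
  tab <- simulate_cohort_table(cfg)
  tab_c <- apply_coefficients(
    apply_coefficients(tab, batch_coefficients(tab)),
    suppressWarnings(center_coefficients(
      apply_coefficients(tab, batch_coefficients(tab)), "instr01")))
  f <- "mfi.b_cells.CD19"
  n_checked <- 0L
  for (ins in unique(tab$instrument_id)) {
    # ratio of group medians within (instrument, batch) is invariant
    sub0 <- tab[tab$instrument_id == ins, ]
    sub1 <- tab_c[tab_c$instrument_id == ins, ]
    for (b in unique(sub0$batch_id)) {
      s0 <- sub0[sub0$batch_id == b, ]
      s1 <- sub1[sub1$batch_id == b, ]
      if (length(unique(s0$group)) < 2) next
      if (min(table(s0$group)) < 2) next
      r0 <- stats::median(s0[[f]][s0$group == "disease"]) /
        stats::median(s0[[f]][s0$group == "healthy"])
      r1 <- stats::median(s1[[f]][s1$group == "disease"]) /
        stats::median(s1[[f]][s1$group == "healthy"])
      expect_equal(r1, r0, tolerance = 1e-9)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 3L)
})

test_that("pipeline order and case-mix assumptions are enforced", {
  cfg <- sim_config(n_centers = 3L, n_samples_per_center = 6L, seed = 63)
  tab <- simulate_cohort_table(cfg)
  expect_error(center_coefficients(tab, "instr01"), "refused")
  # heterogeneous case mix triggers the chi-squared warning
  tab_b <- apply_coefficients(tab, batch_coefficients(tab))
  skew <- tab_b
  skew$group <- ifelse(skew$instrument_id == "instr01", "healthy", "disease")
  skew$group[seq(1, nrow(skew), by = 6)] <- "healthy"
  expect_warning(center_coefficients(cohort_table(skew), "instr01"),
                 "case mix|composition")
})
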