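test_that("peak detection recovers generator peak locations within 2%", {
  cfg <- small_cfg(seed = 10, bead_events_per_peak = 500L)
  em <- simulate_beads(cfg, "instr01", seed = 11, gains = rep(1, 8))
  ps <- detect_peaks(em)
  # expected linear-scale mean of a log10-normal peak
  expected <- cfg$bead_peaks * exp((log(10) * cfg$bead_peak_sd)^2 / 2)
  for (ch in colnames(ps$peaks)) {
    expect_lt(max(abs(ps$peaks[, ch] - expected) / expected), 0.02)
  }
})

test_that("low-scatter debris does not disturb the detected peaks", {
  cfg_clean <- small_cfg(seed = 10, bead_events_per_peak = 500L,
                         bead_debris_events = 0L)
  cfg_dirty <- small_cfg(seed = 10, bead_events_per_peak = 500L,
                         bead_debris_events = 1000L)
  ps_clean <- detect_peaks(simulate_beads(cfg_clean, "instr01", seed = 12,
                                          gains = rep(1, 8)))
  ps_dirty <- detect_peaks(simulate_beads(cfg_dirty, "instr01", seed = 12,
                                          gains = rep(1, 8)))
  # same seed: the peak events are identical draws, debris is appended
  expect_equal(ps_dirty$peaks, ps_clean$peaks, tolerance = 1e-12)
})

test_that("unresolvable peak structure raises a peak-detection error", {
  # 7 well-separated clusters cannot support 8 resolvable peaks: one
  # mode gets split into two near-coincident centers
  set.seed(33)
  peaks7 <- 10^seq(2, 4.4, length.out = 7)
  x <- 10^rnorm(7 * 80, rep(log10(peaks7), each = 80), 0.03)
  vals <- cbind(FSC = rep(5e4, length(x)), SSC = rep(5e4, length(x)),
                CD3 = x)
  em <- tiny_em(vals)
  expect_error(detect_peaks(em), "resolvable peaks")
})

test_that("peak detection is order-invariant and scale-equivariant", {
  cfg <- small_cfg(seed = 13)
  em <- simulate_beads(cfg, "instr01", seed = 14, gains = rep(1, 8))
  ps <- detect_peaks(em)
  perm <- withr::with_seed(1, sample.int(n_events(em)))
  em_perm <- em
  em_perm$values <- em$values[perm, ]
  expect_equal(detect_peaks(em_perm)$peaks, ps$peaks, tolerance = 1e-12)
  # scaling all fluorescence intensities by g scales every peak by g
  g <- 1.37
  em_g <- em
  fluo <- fluorescence_channels(em)
  em_g$values[, fluo] <- em_g$values[, fluo] * g
  expect_equal(detect_peaks(em_g)$peaks, g * ps$peaks, tolerance = 1e-12)
})

test_that("peak recovery error shrinks with more events per peak", {
  expected <- function(cfg) cfg$bead_peaks * exp((log(10) * cfg$bead_peak_sd)^2 / 2)
  err <- vapply(c(100L, 2000L), function(npp) {
    cfg <- small_cfg(seed = 15, bead_events_per_peak = npp)
    errs <- vapply(1:4, function(r) {
      ps <- detect_peaks(simulate_beads(cfg, "instr01", seed = 100 + r,
                                        gains = rep(1, 8)))
      max(abs(ps$peaks[, "CD3"] - expected(cfg)) / expected(cfg))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("QC deviation implements the 5% daily rule", {
  ref <- peak_set(matrix(10^seq(2, 4.8, length.out = 8), 8, 2,
                         dimnames = list(NULL, c("CD3", "CD4"))),
                  is_reference = TRUE)
  expect_true(qc_deviation(ref, ref)$pass)
  expect_equal(max(qc_deviation(ref, ref)$deviation), 0)
  # one peak at 1.06x its reference: 6% deviation, fail
  obs <- ref
  obs$peaks[5, "CD3"] <- 1.06 * obs$peaks[5, "CD3"]
  rep_ <- qc_deviation(obs, ref)
  expect_false(rep_$pass)
  expect_equal(unname(rep_$deviation[5, "CD3"]), 6, tolerance = 1e-9)
  # uniform 4% shift passes (4 < 5)
  obs4 <- ref
  obs4$peaks <- 1.04 * obs4$peaks
  rep4 <- qc_deviation(obs4, ref)
  expect_true(rep4$pass)
  expect_equal(max(rep4$deviation), 4, tolerance = 1e-9)
  # channel mismatch errors
  obs_bad <- ref
  colnames(obs_bad$peaks) <- c("CD3", "CD8")
  expect_error(qc_deviation(obs_bad, ref), "mismatch")
})

test_that("peak sets round-trip through their CSV store", {
  cfg <- small_cfg(seed = 16)
  ps <- detect_peaks(simulate_beads(cfg, "instr01", seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_set(ps, path)
  rt <- read_peak_set(path)
  expect_equal(rt$peaks, ps$peaks, tolerance = 1e-12)
  expect_identical(rt$instrument_id, ps$instrument_id)
})
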