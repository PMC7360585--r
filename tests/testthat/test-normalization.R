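ref_ps <- function(peaks = 10^seq(2, 4.8, length.out = 8),
                   channels = c("CD3", "CD4")) {
  peak_set(matrix(peaks, length(peaks), length(channels),
                  dimnames = list(NULL, channels)), is_reference = TRUE)
}

test_that("identity and pure-gain fits are exact", {
  ref <- ref_ps()
  tr <- fit_affine(ref, ref)
  expect_equal(tr$alpha, c(1, 1), tolerance = 1e-12)
  expect_equal(tr$beta, c(0, 0), tolerance = 1e-9)
  # observed = 1.10 x reference: proportional data has the exact
  # through-origin solution alpha = 1/1.10
  obs <- ref
  obs$peaks <- 1.10 * obs$peaks
  tr <- fit_affine(obs, ref)
  expect_equal(tr$alpha, rep(1 / 1.1, 2), tolerance = 1e-9)
  expect_equal(tr$beta, c(0, 0), tolerance = 1e-6)
  expect_true(all(tr$r_squared > 0.999999))
})

test_that("unweighted fit matches the closed-form normal equations", {
  # independent oracle: direct evaluation of the OLS sums
  ols_oracle <- function(x, y) {
    n <- length(x)
    alpha <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
    beta <- mean(y) - alpha * mean(x)
    c(alpha, beta)
  }
  set.seed(20)
  for (rep in 1:5) {
    ref_peaks <- sort(10^runif(8, 2, 4.8))
    obs_peaks <- sort(ref_peaks * runif(1, 0.8, 1.2) + rnorm(8, 0, 20))
    ref <- ref_ps(ref_peaks, "CD3")
    obs <- ref_ps(obs_peaks, "CD3")
    tr <- fit_affine(obs, ref, weights = "none", min_r_squared = 0.9)
    expect_equal(c(tr$alpha, tr$beta), ols_oracle(obs_peaks, ref_peaks),
                 tolerance = 1e-9)
  }
})

test_that("corrupted bead fits are rejected, not silently accepted", {
  ref <- ref_ps()
  # peaks no longer linearly related to the reference: poor R^2
  obs <- ref
  obs$peaks[, "CD4"] <- sort(ref$peaks[, "CD4"] *
                               c(30, 10, 4, 2, 0.9, 0.5, 0.9, 1.1))
  expect_error(fit_affine(obs, ref), "fit-quality error")
})

test_that("apply_affine transforms fluorescence only and keeps order", {
  em <- tiny_em(matrix(c(100, 200, 100, 200, 100, 200), 2, 3,
                       dimnames = list(NULL, c("FSC", "CD3", "CD4"))))
  tr <- structure(
    data.frame(channel = c("CD3", "CD4"), alpha = c(0.5, 1), beta = c(10, 0),
               r_squared = 1, max_residual_pct = 0),
    class = c("affine_transform", "data.frame"))
  out <- apply_affine(em, tr)
  expect_equal(out$values[, "CD3"], c(60, 110))
  expect_identical(out$values[, "FSC"], em$values[, "FSC"])
  expect_identical(out$values[, "CD4"], em$values[, "CD4"])
  expect_true(out$meta$normalized)
  # identity transform is bit-exact
  id <- tr; id$alpha <- c(1, 1); id$beta <- c(0, 0)
  expect_identical(apply_affine(em, id)$values, em$values)
  # missing channel transform errors
  expect_error(apply_affine(em, tr[1, ]), "no affine transform")
})

test_that("affine perturbations are removed with zero residual", {
  ref <- ref_ps()
  for (g in c(0.8, 1.12)) {
    for (b in c(-30, 0, 55)) {
      obs <- ref
      obs$peaks <- g * obs$peaks + b
      if (any(obs$peaks <= 0)) next
      tr <- fit_affine(obs, ref)
      corrected <- tr$alpha[1] * obs$peaks[, "CD3"] + tr$beta[1]
      expect_equal(corrected, ref$peaks[, "CD3"], tolerance = 1e-6)
    }
  }
})

test_that("normalizing already-normalized data composes to identity", {
  cfg <- small_cfg(seed = 21)
  ref <- cfg$panel$reference_peaks
  beads <- simulate_beads(cfg, "instr01", seed = 22, gains = rep(1.2, 8))
  tr <- fit_affine(detect_peaks(beads), ref)
  normalized <- apply_affine(beads, tr)
  tr2 <- fit_affine(detect_peaks(normalized), ref)
  expect_equal(tr2$alpha, rep(1, 8), tolerance = 0.01)
  expect_lt(max(abs(tr2$beta)) / min(ref$peaks), 0.05)
})

test_that("gain-perturbed beads normalize back to reference within 2.5% CV", {
  v <- validate_gain_perturbation(seed = 42)
  expect_lte(v$bead_cv, 2.5)
})

test_that("transforms round-trip through their JSON log", {
  cfg <- small_cfg(seed = 23)
  tr <- fit_affine(detect_peaks(simulate_beads(cfg, "instr01", seed = 24)),
                   cfg$panel$reference_peaks)
  path <- withr::local_tempfile(fileext = ".json")
  write_affine(tr, path)
  rt <- read_affine(path)
  expect_equal(rt$alpha, tr$alpha, tolerance = 1e-12)
  expect_equal(rt$beta, tr$beta, tolerance = 1e-12)
})
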