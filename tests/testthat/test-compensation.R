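test_that("compensation inverts known spillover exactly", {
  # identity spillover leaves values untouched
  em <- tiny_em(matrix(c(1000, 100, 110, 50), 2, 2,
                       dimnames = list(NULL, c("CD3", "CD4"))),
                scatter = c(FALSE, FALSE))
  S_id <- spillover_matrix(diag(2), c("CD3", "CD4"))
  expect_identical(apply_compensation(em, S_id)$values, em$values)
  # hand-invertible 2x2: true (100, 100), 10% spill CD3 -> CD4 gives
  # observed (100, 110); compensation recovers (100, 100)
  S <- spillover_matrix(matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE),
                        c("CD3", "CD4"))
  obs <- tiny_em(matrix(c(100, 110), 1, 2,
                        dimnames = list(NULL, c("CD3", "CD4"))),
                 scatter = c(FALSE, FALSE))
  comp <- apply_compensation(obs, S)
  expect_equal(comp$values[1, ], c(CD3 = 100, CD4 = 100), tolerance = 1e-12)
  expect_true(comp$meta$compensated)
})

test_that("random spillover round-trips observed = true * S", {
  set.seed(30)
  for (rep in 1:5) {
    n <- 4
    S <- diag(n)
    S[row(S) != col(S)] <- runif(n * (n - 1), 0, 0.15)
    chans <- paste0("M", 1:n)
    S <- spillover_matrix(S, chans)
    true <- matrix(10^runif(200 * n, 1, 4.5), 200, n,
                   dimnames = list(NULL, chans))
    obs <- tiny_em(true %*% unclass(S), channels = chans,
                   scatter = rep(FALSE, n))
    comp <- apply_compensation(obs, S)
    expect_lt(max(abs(comp$values - true) / true), 1e-6)
  }
})

test_that("spillover keyword parsing round-trips and takes precedence", {
  S <- spillover_matrix(matrix(c(1, 0.04, 0.02, 1), 2, 2, byrow = TRUE),
                        c("CD3", "CD4"))
  rt <- parse_spillover(format_spillover(S))
  expect_equal(unclass(rt), unclass(S), tolerance = 1e-12)
  expect_error(parse_spillover("3,a,b"), "malformed")
  # keyword-based compensation recovers the true event
  true <- matrix(c(500, 80), 1, 2, dimnames = list(NULL, c("CD3", "CD4")))
  em <- event_matrix(true %*% unclass(S),
                     channel_names = c("CD3", "CD4"),
                     scatter = c(FALSE, FALSE),
                     keywords = list(`$SPILLOVER` = format_spillover(S)))
  comp <- apply_compensation(em)
  expect_equal(comp$values, true, tolerance = 1e-9)
})

test_that("singular or ill-conditioned spillover is rejected", {
  S <- matrix(c(1, 0.999, 0.999, 1), 2, 2)
  sm <- spillover_matrix(S, c("CD3", "CD4"))
  em <- tiny_em(matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("CD3", "CD4"))),
                scatter = c(FALSE, FALSE))
  expect_error(apply_compensation(em, sm, max_condition = 100),
               "ill-conditioned")
  expect_error(spillover_matrix(matrix(c(1, 1.2, 0, 1), 2, 2), c("A", "B")),
               "\\[0, 1\\)")
})

test_that("residual-spill slope quantifies compensation quality", {
  # primary CD19 (B cells), secondary CD56: biologically silent on
  # CD19+ cells, so any bright-vs-dim slope is instrumental spill
  cfg <- small_cfg(seed = 31)
  sim <- simulate_sample(cfg, "instr01", cell_seed = 32, gains = rep(1, 8))
  comp <- apply_compensation(sim$em, cfg$spillover)
  # lymphocyte-scatter restriction keeps counting beads out of the mask
  is_lymph <- function(em) channel_values(em, "SSC") <= 10^3.9
  bright <- channel_values(comp, "CD19") > 10^2.8 & is_lymph(comp)
  r <- residual_spill(comp, "CD19", "CD56", bright)
  expect_true(r$conclusive)
  expect_lt(abs(r$slope), 0.01)
  # acquire with 5 extra points of true CD19 -> CD56 spill but
  # compensate with the nominal matrix: slope near +0.05 remains
  cfg_hot <- cfg
  S_hot <- unclass(cfg$spillover)
  S_hot["CD19", "CD56"] <- S_hot["CD19", "CD56"] + 0.05
  cfg_hot$spillover <- spillover_matrix(S_hot, cfg$markers)
  sim_hot <- simulate_sample(cfg_hot, "instr01", cell_seed = 32,
                             gains = rep(1, 8))
  under <- apply_compensation(sim_hot$em, cfg$spillover)
  r_under <- residual_spill(under, "CD19", "CD56",
                            channel_values(under, "CD19") > 10^2.8 &
                              is_lymph(under))
  expect_lt(abs(r_under$slope - 0.05), 0.015)
  # empty mask is inconclusive, not an error
  r_empty <- residual_spill(comp, "CD19", "CD56", rep(FALSE, n_events(comp)))
  expect_false(r_empty$conclusive)
  expect_true(is.na(r_empty$slope))
})
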