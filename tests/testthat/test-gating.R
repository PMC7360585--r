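gated_sample <- function(seed = 40, cfg = small_cfg(seed = seed)) {
  sim <- simulate_sample(cfg, "instr01", cell_seed = seed + 1,
                         gains = rep(1, 8))
  em <- apply_compensation(sim$em, cfg$spillover)
  labels <- gate_events(em, cfg$panel$populations, cfg$panel$thresholds)
  list(cfg = cfg, em = em, labels = labels, truth = sim$truth)
}

test_that("threshold gating recovers generator frequencies within 1 point", {
  g <- gated_sample(seed = 40)
  truth_frac <- 100 * g$truth$fractions
  names(truth_frac) <- g$truth$populations
  # deepest gate labels against the generator's mixture components
  n_leuk <- sum(g$labels %in% g$truth$populations)
  got <- 100 * table(g$labels)[g$truth$populations] / n_leuk
  for (p in g$truth$populations) {
    expect_lt(abs(got[[p]] - truth_frac[[p]]), 1.0, label = p)
  }
  # internal nodes aggregate their descendants
  st <- population_stats(g$em, g$labels, g$cfg$panel$populations)
  t_members <- sum(got[c("t_cells", "cd4_t_cells", "cd8_t_cells",
                         "nk_like_t_cells")])
  expect_equal(st$freq_leukocytes[st$population == "t_cells"], t_members,
               tolerance = 0.05)
})

test_that("predicates implement the marker definitions", {
  cfg <- small_cfg()
  defs <- cfg$panel$populations
  thr <- cfg$panel$thresholds
  # one event, CD3 above and CD19 below threshold, lymphocyte scatter
  mk_event <- function(over = c()) {
    v <- c(FSC = 10^4.5, SSC = 10^3.6, CD3 = 100, CD4 = 100, CD8 = 100,
           CD19 = 100, CD56 = 100, CD16 = 100, CD14 = 100, CD15 = 100)
    v[names(over)] <- over
    tiny_em(matrix(v, 1, dimnames = list(NULL, names(v))))
  }
  lab <- function(em) as.character(gate_events(em, defs, thr))
  expect_identical(lab(mk_event(c(CD3 = 5000))), "t_cells")
  expect_identical(lab(mk_event(c(CD3 = 5000, CD4 = 4000))), "cd4_t_cells")
  expect_identical(lab(mk_event(c(CD19 = 3000))), "b_cells")
  expect_identical(lab(mk_event(c(CD56 = 2000, CD16 = 9000))), "nk_dim")
  expect_identical(lab(mk_event(c(FSC = 10^3.0))), "debris")
  # missing threshold errors
  thr2 <- thr; thr2$CD3 <- NULL
  expect_error(gate_events(mk_event(), defs, thr2), "missing threshold")
})

test_that("all-baseline input yields zero populations with low-count flags", {
  cfg <- small_cfg()
  set.seed(41)
  n <- 500
  vals <- matrix(10^rnorm(n * 10, 1.8, 0.15), n, 10,
                 dimnames = list(NULL, cfg$panel$channels))
  vals[, "FSC"] <- 10^rnorm(n, 3.2, 0.1)
  vals[, "SSC"] <- 10^rnorm(n, 3.0, 0.1)
  em <- tiny_em(vals)
  st <- population_stats(em, gate_events(em, cfg$panel$populations,
                                         cfg$panel$thresholds),
                         cfg$panel$populations)
  cells <- !st$population %in% c("debris", "counting_beads")
  expect_true(all(st$n[cells] == 0))
  expect_true(all(st$low_count[cells]))
  expect_true(all(st$freq_leukocytes[cells] == 0))
})

test_that("gating is deterministic and permutation-equivariant", {
  g <- gated_sample(seed = 42)
  expect_identical(gate_events(g$em, g$cfg$panel$populations,
                               g$cfg$panel$thresholds), g$labels)
  perm <- withr::with_seed(2, sample.int(n_events(g$em)))
  em_p <- g$em
  em_p$values <- g$em$values[perm, ]
  expect_identical(as.character(gate_events(em_p, g$cfg$panel$populations,
                                            g$cfg$panel$thresholds)),
                   as.character(g$labels)[perm])
})

test_that("absolute counting follows the bead-ratio formula", {
  expect_equal(absolute_count(5000, 1000, 100), 500)
  expect_equal(absolute_count(0, 1000, 100), 0)
  expect_error(absolute_count(100, 0, 100), "zero counting-bead")
  expect_error(absolute_count(100, 10, -1), "positive")
  # Poisson sampling: estimated concentration within 3 SE of truth
  g <- gated_sample(seed = 43)
  st <- population_stats(g$em, g$labels, g$cfg$panel$populations,
                         beads_per_volume = g$cfg$beads_per_ul)
  total <- sum(st$count[st$population %in%
                          c("lymphocytes", "monocytes", "granulocytes")])
  conc_true <- g$truth$concentration
  se <- conc_true * sqrt(1 / g$cfg$n_bead_events + 1 / g$cfg$n_events)
  expect_lt(abs(total - conc_true), 3 * se)
})

test_that("frequencies are invariant under threshold-preserving rescaling", {
  # the MFI corrections act on the stats table; event-level monotone
  # transforms that keep every event on its threshold side leave the
  # gate assignment unchanged
  g <- gated_sample(seed = 44)
  cfg <- g$cfg
  em2 <- g$em
  thr <- cfg$panel$thresholds
  # strictly monotone map fixing every cut point: power-stretch within
  # each inter-cut segment, linear stretch above the last cut
  warp <- function(x, cuts) {
    cuts <- sort(cuts)
    y <- x
    lo <- x > 0 & x <= cuts[1]
    y[lo] <- cuts[1] * (x[lo] / cuts[1])^1.3
    if (length(cuts) > 1) {
      for (i in seq_len(length(cuts) - 1)) {
        seg <- x > cuts[i] & x <= cuts[i + 1]
        w <- cuts[i + 1] - cuts[i]
        y[seg] <- cuts[i] + w * ((x[seg] - cuts[i]) / w)^1.3
      }
    }
    hi <- x > cuts[length(cuts)]
    y[hi] <- cuts[length(cuts)] + (x[hi] - cuts[length(cuts)]) * 1.5
    y
  }
  for (ch in fluorescence_channels(em2)) {
    em2$values[, ch] <- warp(em2$values[, ch], thr[[ch]])
  }
  expect_identical(as.character(gate_events(em2, cfg$panel$populations, thr)),
                   as.character(g$labels))
})
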