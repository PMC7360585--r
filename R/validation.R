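#' Gain-perturbation validation of the bead-anchored normalization
#'
#' Replays, on synthetic data, the PMT-perturbation experiment that
#' validates the normalization step: acquire a reference 8-peak bead
#' file, re-acquire it with every fluorescence channel's gain multiplied
#' by a factor in `gain_range` (a 10-15 percent measurement shift by
#' default), fit the per-channel affine transform from the perturbed
#' peaks back to the reference peaks, and apply it to the perturbed
#' events.
#'
#' Two numbers summarize how completely the perturbation is removed,
#' each a maximum over pairwise CVs between the reference quantity and
#' its corrected counterpart:
#' \itemize{
#'   \item `bead_cv`: over the 8 bead peaks of every channel
#'     (reference peak MFI vs corrected peak MFI);
#'   \item `sample_cv`: over the population-level marker MFIs of a
#'     stained sample (same cell-level draws acquired under both gain
#'     settings, the perturbed acquisition normalized with the
#'     bead-derived transform, both gated by the threshold hierarchy).
#' }
#'
#' @param seed integer seed for all randomness (gain draws, bead and
#'   cell sampling).
#' @param gain_range range the per-channel gain factors are drawn from.
#' @param cfg a [sim_config()]; the default uses one instrument at
#'   default event counts.
#' @param min_population_events MFI pairs are compared only for
#'   populations with at least this many events in both acquisitions.
#' @return list with `bead_cv`, `sample_cv` (percent), `gains`, and the
#'   per-pair CV tables `bead_cvs`, `sample_cvs`.
#' @export
validate_gain_perturbation <- function(seed = 1L,
                                       gain_range = c(1.10, 1.15),
                                       cfg = sim_config(n_centers = 1L,
                                                        seed = seed),
                                       min_population_events = 20L) {
  instrument <- cfg$instruments$instrument_id[1L]
  markers <- cfg$markers
  gains <- with_seed(derive_seed(seed, "gains"), {
    stats::setNames(stats::runif(length(markers), gain_range[1L],
                                 gain_range[2L]), markers)
  })
  ref_beads <- simulate_beads(cfg, instrument, seed = derive_seed(seed, "ref"),
                              gains = rep(1, length(markers)))
  ref_peaks <- detect_peaks(ref_beads)
  pert_beads <- simulate_beads(cfg, instrument,
                               seed = derive_seed(seed, "pert"),
                               gains = gains)
  transform <- fit_affine(detect_peaks(pert_beads), ref_peaks)
  corr_peaks <- detect_peaks(apply_affine(pert_beads, transform))
  bead_cvs <- matrix(NA_real_, nrow(ref_peaks$peaks), length(markers),
                     dimnames = list(NULL, markers))
  for (m in markers) {
    for (k in seq_len(nrow(ref_peaks$peaks))) {
      bead_cvs[k, m] <- cv(c(ref_peaks$peaks[k, m], corr_peaks$peaks[k, m]))
    }
  }
  # same cells acquired under both gain settings
  cell_seed <- derive_seed(seed, "cells")
  unpert <- simulate_sample(cfg, instrument, cell_seed = cell_seed,
                            seed = derive_seed(seed, "acq"),
                            gains = rep(1, length(markers)))$em
  pert <- simulate_sample(cfg, instrument, cell_seed = cell_seed,
                          seed = derive_seed(seed, "acq"),
                          gains = gains)$em
  pert <- apply_affine(pert, transform)
  unpert <- apply_compensation(unpert, cfg$spillover)
  pert <- apply_compensation(pert, cfg$spillover)
  defs <- cfg$panel$populations
  thr <- cfg$panel$thresholds
  st0 <- population_stats(unpert, gate_events(unpert, defs, thr), defs)
  st1 <- population_stats(pert, gate_events(pert, defs, thr), defs)
  sample_cvs <- mfi_pair_cvs(st0, st1, min_population_events)
  list(bead_cv = max(bead_cvs), sample_cv = max(sample_cvs$cv),
       gains = gains, bead_cvs = bead_cvs, sample_cvs = sample_cvs)
}

# CV between matched (population, marker) MFI pairs of two gated
# acquisitions, restricted to populations well-populated in both.
mfi_pair_cvs <- function(st0, st1, min_events) {
  m0 <- attr(st0, "mfi")
  m1 <- attr(st1, "mfi")
  keep <- st0$population[st0$n >= min_events & st1$n >= min_events &
                           !st0$population %in% c("debris", "counting_beads", "all")]
  rows <- list()
  for (p in keep) {
    for (mk in colnames(m0)) {
      if (is.na(m0[p, mk]) || is.na(m1[p, mk])) next
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, marker = mk, cv = cv(c(m0[p, mk], m1[p, mk])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Multi-instrument harmonization validation
#'
#' Simulates the cross-sectional design of a multi-center study: a
#' number of instruments with per-channel gains drawn in `gain_range`
#' all acquire the same underlying stained sample (shared cell-level
#' draws). Each instrument's 8-peak bead file is fitted against the
#' shared frozen reference targets, sample events are normalized,
#' compensated and gated, and for every (population, marker) the CV of
#' the MFIs across instruments is computed.
#'
#' @param seed integer seed.
#' @param n_instruments number of simulated instruments (11 by
#'   default).
#' @param gain_range per-channel gain range across instruments.
#' @param cfg a [sim_config()].
#' @param min_population_events populations entering the CV must have
#'   at least this many events on every instrument.
#' @return list with `max_cv` (percent), `cvs` (per feature), `gains`.
#' @export
validate_multi_instrument <- function(seed = 1L, n_instruments = 11L,
                                      gain_range = c(0.8, 1.25),
                                      cfg = sim_config(n_centers = n_instruments,
                                                       seed = seed),
                                      min_population_events = 20L) {
  markers <- cfg$markers
  reference <- cfg$panel$reference_peaks
  stopifnot(setequal(colnames(reference$peaks), markers))
  cell_seed <- derive_seed(seed, "shared_cells")
  defs <- cfg$panel$populations
  thr <- cfg$panel$thresholds
  gains_all <- with_seed(derive_seed(seed, "inst_gains"), {
    matrix(stats::runif(n_instruments * length(markers),
                        gain_range[1L], gain_range[2L]),
           n_instruments, length(markers), dimnames = list(NULL, markers))
  })
  stats_by_instrument <- vector("list", n_instruments)
  for (i in seq_len(n_instruments)) {
    instrument <- cfg$instruments$instrument_id[i]
    gains <- gains_all[i, ]
    beads <- simulate_beads(cfg, instrument,
                            seed = derive_seed(seed, "beads", i),
                            gains = gains)
    transform <- fit_affine(detect_peaks(beads), reference)
    em <- simulate_sample(cfg, instrument, cell_seed = cell_seed,
                          seed = derive_seed(seed, "acq", i),
                          gains = gains)$em
    em <- apply_compensation(apply_affine(em, transform), cfg$spillover)
    stats_by_instrument[[i]] <-
      population_stats(em, gate_events(em, defs, thr), defs)
  }
  pops <- stats_by_instrument[[1L]]$population
  ok <- Reduce(`&`, lapply(stats_by_instrument, function(s)
    s$n >= min_population_events))
  keep <- pops[ok & !pops %in% c("debris", "counting_beads", "all")]
  rows <- list()
  for (p in keep) {
    for (mk in markers) {
      vals <- vapply(stats_by_instrument, function(s) attr(s, "mfi")[p, mk],
                     numeric(1))
      if (anyNA(vals)) next
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, marker = mk, cv = cv(vals), stringsAsFactors = FALSE)
    }
  }
  cvs <- do.call(rbind, rows)
  list(max_cv = max(cvs$cv), cvs = cvs, gains = gains_all)
}
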