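#' Configuration for the synthetic multi-center cohort generator
#'
#' Describes a simulated study: a set of centers each with one
#' instrument (per-channel gains around 1; the first instrument is the
#' reference and has unit gains), an antibody-lot schedule with
#' recalibration epochs, log-normal population templates for the
#' panel-1 leukocyte populations, an 8-peak bead template, counting
#' beads, disease groups with multiplicative marker effects, and a
#' spillover matrix injected into every stained sample so compensation
#' is exercised rather than bypassed.
#'
#' All derived randomness (instrument gains, lot effects) is drawn here
#' once from `seed`, so a config is itself the ground truth: the gains,
#' lot effects and templates it holds are exactly what the generator
#' uses. Every generator function is seed-deterministic.
#'
#' Scale defaults are chosen for desk execution (about 10^4 events per
#' sample, tens of samples per center); the full-cohort scale of a real
#' multi-year study is emulated, never required.
#'
#' @param n_centers number of centers/instruments (default 11).
#' @param n_samples_per_center samples per center.
#' @param n_events stained-cell events per sample.
#' @param n_bead_events expected counting-bead events per sample
#'   (Poisson).
#' @param beads_per_ul counting-bead concentration (beads/uL).
#' @param bead_events_per_peak events per rainbow-bead peak in a QC
#'   acquisition.
#' @param bead_debris_events low-scatter debris events added to each
#'   bead acquisition.
#' @param bead_peak_sd,marker_sd,scatter_sd log10 standard deviations of
#'   bead peaks, marker intensities and scatter.
#' @param gain_range per-channel fluorescence gain range across
#'   instruments (instrument 1 is pinned to 1).
#' @param scatter_gains per-instrument scatter gain (recycled; default
#'   1, i.e. scatter comparable across instruments).
#' @param lot_effect_range multiplicative per-marker antibody-lot effect
#'   range (lot 1 is pinned to 1).
#' @param residual_sd log10 sd of a per-instrument, per-marker residual
#'   response (optical-bench effects that bead normalization cannot
#'   remove; 0 by default).
#' @param center_effect_range per-center multiplicative MFI effect used
#'   by [simulate_cohort_table()] (center 1 pinned to 1).
#' @param sample_debris_frac fraction of debris events in stained
#'   samples.
#' @param groups named numeric vector of disease-group mixture weights.
#' @param disease_effects named list: group -> named vector of
#'   multiplicative marker effects (e.g. a CD19 shift in one group).
#' @param date_range two `Date`s bounding the inclusion period.
#' @param n_lots,n_calibrations antibody lots and recalibration
#'   procedures over the period.
#' @param seed integer seed; all derived draws come from it.
#' @return a `sim_config` list (see Details for derived fields:
#'   `panel`, `templates`, `instruments`, `gains`, `lot_periods`,
#'   `calib_dates`, `lot_effects`, `residual`, `center_effects`,
#'   `spillover`, `bead_peaks`).
#' @export
sim_config <- function(n_centers = 11L, n_samples_per_center = 20L,
                       n_events = 10000L, n_bead_events = 1000L,
                       beads_per_ul = 100, bead_events_per_peak = 500L,
                       bead_debris_events = 500L, bead_peak_sd = 0.05,
                       marker_sd = 0.12, scatter_sd = 0.05,
                       gain_range = c(0.8, 1.25), scatter_gains = 1,
                       lot_effect_range = c(0.8, 1.3), residual_sd = 0,
                       center_effect_range = c(1, 1),
                       sample_debris_frac = 0.02,
                       groups = c(healthy = 0.5, disease = 0.5),
                       disease_effects = list(disease = c(CD19 = 1.5)),
                       date_range = as.Date(c("2015-01-01", "2018-12-31")),
                       n_lots = 3L, n_calibrations = 7L, seed = 1L) {
  stopifnot(abs(sum(groups) - 1) < 1e-9, n_centers >= 1L)
  panel <- default_panel("panel1")
  markers <- panel$markers
  templates <- pop_templates_panel1()
  stopifnot(abs(sum(vapply(templates, `[[`, numeric(1), "weight")) - 1) < 1e-9)
  instruments <- data.frame(
    instrument_id = sprintf("instr%02d", seq_len(n_centers)),
    center_id = sprintf("center%02d", seq_len(n_centers)),
    vendor = ifelse(seq_len(n_centers) %% 2L == 1L, "BC", "BD"),
    scatter_gain = rep_len(scatter_gains, n_centers),
    stringsAsFactors = FALSE
  )
  gains <- with_seed(derive_seed(seed, 101L), {
    g <- matrix(stats::runif(n_centers * length(markers),
                             gain_range[1L], gain_range[2L]),
                n_centers, length(markers),
                dimnames = list(instruments$instrument_id, markers))
    g[1L, ] <- 1   # reference instrument
    g
  })
  lot_effects <- with_seed(derive_seed(seed, 202L), {
    le <- matrix(stats::runif(n_lots * length(markers),
                              lot_effect_range[1L], lot_effect_range[2L]),
                 n_lots, length(markers),
                 dimnames = list(sprintf("lot%d", seq_len(n_lots)), markers))
    le[1L, ] <- 1  # first lot is the anchor
    le
  })
  residual <- with_seed(derive_seed(seed, 303L), {
    matrix(10^stats::rnorm(n_centers * length(markers), 0, residual_sd),
           n_centers, length(markers),
           dimnames = list(instruments$instrument_id, markers))
  })
  center_effects <- with_seed(derive_seed(seed, 404L), {
    ce <- matrix(stats::runif(n_centers * length(markers),
                              center_effect_range[1L], center_effect_range[2L]),
                 n_centers, length(markers),
                 dimnames = list(instruments$center_id, markers))
    ce[1L, ] <- 1
    ce
  })
  span <- as.integer(diff(date_range))
  lot_starts <- date_range[1L] + floor(span * (seq_len(n_lots) - 1L) / n_lots)
  lot_periods <- data.frame(
    lot_id = sprintf("lot%d", seq_len(n_lots)),
    start = lot_starts,
    end = c(lot_starts[-1L], date_range[2L] + 1L)
  )
  calib_dates <- date_range[1L] +
    floor(span * seq_len(n_calibrations) / (n_calibrations + 1L))
  structure(list(
    panel = panel, markers = markers, templates = templates,
    instruments = instruments, gains = gains,
    lot_periods = lot_periods, calib_dates = calib_dates,
    lot_effects = lot_effects, residual = residual,
    center_effects = center_effects,
    spillover = default_spillover(markers),
    bead_peaks = 10^seq(2.0, 4.8, length.out = 8),
    n_centers = n_centers, n_samples_per_center = n_samples_per_center,
    n_events = n_events, n_bead_events = n_bead_events,
    beads_per_ul = beads_per_ul,
    bead_events_per_peak = bead_events_per_peak,
    bead_debris_events = bead_debris_events,
    bead_peak_sd = bead_peak_sd, marker_sd = marker_sd,
    scatter_sd = scatter_sd, sample_debris_frac = sample_debris_frac,
    groups = groups, disease_effects = disease_effects,
    date_range = date_range, seed = as.integer(seed)
  ), class = "sim_config")
}

# Log-normal templates for the panel-1 populations: mixture weight,
# scatter position and per-marker location, all in log10 units.
# Negative markers sit near 10^2.1, positives near 10^3.4-10^4, well
# clear of the 10^2.8-10^3.0 gating cuts relative to the marker sd.
pop_templates_panel1 <- function() {
  lymph <- c(FSC = 4.5, SSC = 3.6)
  mono <- c(FSC = 4.75, SSC = 4.15)
  gran <- c(FSC = 4.85, SSC = 4.7)
  mk <- function(...) {
    base <- c(CD3 = 2.1, CD4 = 2.1, CD8 = 2.1, CD19 = 2.1,
              CD56 = 2.1, CD16 = 2.1, CD14 = 2.1, CD15 = 2.1)
    up <- c(...)
    base[names(up)] <- up
    base
  }
  list(
    neutrophils = list(weight = 0.50, scatter = gran,
                       markers = mk(CD15 = 3.9, CD16 = 4.0, CD14 = 2.3)),
    eosinophils = list(weight = 0.03, scatter = gran,
                       markers = mk(CD15 = 3.6, CD16 = 2.5)),
    classical_monocytes = list(weight = 0.06, scatter = mono,
                               markers = mk(CD14 = 3.8, CD4 = 2.6)),
    intermediate_monocytes = list(weight = 0.015, scatter = mono,
                                  markers = mk(CD14 = 3.8, CD16 = 3.4, CD4 = 2.6)),
    nonclassical_monocytes = list(weight = 0.015, scatter = mono,
                                  markers = mk(CD14 = 2.3, CD16 = 3.6, CD4 = 2.6)),
    cd4_t_cells = list(weight = 0.15, scatter = lymph,
                       markers = mk(CD3 = 3.6, CD4 = 3.5)),
    cd8_t_cells = list(weight = 0.08, scatter = lymph,
                       markers = mk(CD3 = 3.6, CD8 = 3.7)),
    t_cells = list(weight = 0.022, scatter = lymph,   # CD4-CD8- T cells
                   markers = mk(CD3 = 3.6)),
    nk_like_t_cells = list(weight = 0.02, scatter = lymph,
                           markers = mk(CD3 = 3.6, CD56 = 3.3)),
    b_cells = list(weight = 0.05, scatter = lymph,
                   markers = mk(CD19 = 3.4)),
    nk_dim = list(weight = 0.05, scatter = lymph,
                  markers = mk(CD56 = 3.2, CD16 = 4.0)),
    nk_bright = list(weight = 0.008, scatter = lymph,
                     markers = mk(CD56 = 4.1, CD16 = 2.2))
  )
}

# Adjacent-channel spillover, moderate and invertible.
default_spillover <- function(markers) {
  n <- length(markers)
  S <- diag(n)
  for (i in seq_len(n - 1L)) {
    S[i, i + 1L] <- 0.04
    S[i + 1L, i] <- 0.02
  }
  spillover_matrix(S, markers)
}

# Seed plumbing: run `code` under a temporary RNG state so generators
# are reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  as.integer((as.numeric(seed) * 48271 + sum(parts * 7919)) %% 2147483647)
}

rlnorm10 <- function(n, mean_log10, sd_log10) {
  10^stats::rnorm(n, mean_log10, sd_log10)
}

#' Simulate a daily-QC rainbow bead acquisition
#'
#' Eight log-normal peaks per fluorescence channel at the template
#' locations scaled by the instrument's current per-channel gain, a
#' high-scatter bead cluster, and a low-scatter debris cluster.
#' Seed-deterministic: the same seed gives a bit-identical acquisition.
#'
#' @param cfg a [sim_config()].
#' @param instrument instrument id (row of `cfg$instruments`), used to
#'   look up gains unless `gains` is given.
#' @param date acquisition `Date`.
#' @param seed integer seed.
#' @param gains optional named per-channel gain vector overriding the
#'   instrument's registry gains (used for perturbation experiments).
#' @return an [event_matrix()] with `panel_id = "beads"`.
#' @export
simulate_beads <- function(cfg, instrument, date = cfg$date_range[1L],
                           seed = cfg$seed, gains = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  markers <- cfg$markers
  if (is.null(gains)) {
    gains <- cfg$gains[instrument, ]
  }
  gains <- rep_len(gains, length(markers))
  names(gains) <- markers
  n_peak_events <- 8L * cfg$bead_events_per_peak
  n <- n_peak_events + cfg$bead_debris_events
  with_seed(seed, {
    peak_of <- rep(seq_len(8L), each = cfg$bead_events_per_peak)
    values <- matrix(NA_real_, n, length(markers) + 2L,
                     dimnames = list(NULL, c("FSC", "SSC", markers)))
    values[seq_len(n_peak_events), "FSC"] <- rlnorm10(n_peak_events, 4.7, 0.04)
    values[seq_len(n_peak_events), "SSC"] <- rlnorm10(n_peak_events, 4.7, 0.04)
    for (m in markers) {
      mu <- log10(cfg$bead_peaks * gains[[m]])
      values[seq_len(n_peak_events), m] <-
        rlnorm10(n_peak_events, mu[peak_of], cfg$bead_peak_sd)
    }
    if (cfg$bead_debris_events > 0L) {
      idx <- (n_peak_events + 1L):n
      values[idx, "FSC"] <- rlnorm10(length(idx), 3.2, 0.1)
      values[idx, "SSC"] <- rlnorm10(length(idx), 3.0, 0.1)
      for (m in markers) values[idx, m] <- rlnorm10(length(idx), 1.5, 0.1)
    }
    row <- match(instrument, cfg$instruments$instrument_id)
    event_matrix(values,
                 scatter = c(TRUE, TRUE, rep(FALSE, length(markers))),
                 meta = list(
                   instrument_id = instrument,
                   center_id = if (!is.na(row)) cfg$instruments$center_id[row] else NA_character_,
                   acquisition_date = date, panel_id = "beads",
                   sample_id = sprintf("beads_%s_%s", instrument, format(date)),
                   vendor = if (!is.na(row)) cfg$instruments$vendor[row] else NA_character_))
  })
}

# Draw the true (pre-instrument) cell-level intensities of one sample.
draw_cells <- function(cfg, n, group, seed) {
  templates <- cfg$templates
  markers <- cfg$markers
  pops <- names(templates)
  w <- vapply(templates, `[[`, numeric(1), "weight") * (1 - cfg$sample_debris_frac)
  w <- c(w, debris = cfg$sample_debris_frac)
  with_seed(seed, {
    labels <- sample(names(w), n, replace = TRUE, prob = w)
    values <- matrix(NA_real_, n, length(markers) + 2L,
                     dimnames = list(NULL, c("FSC", "SSC", markers)))
    for (p in pops) {
      idx <- which(labels == p)
      if (!length(idx)) next
      tpl <- templates[[p]]
      values[idx, "FSC"] <- rlnorm10(length(idx), tpl$scatter[["FSC"]], cfg$scatter_sd)
      values[idx, "SSC"] <- rlnorm10(length(idx), tpl$scatter[["SSC"]], cfg$scatter_sd)
      for (m in markers) {
        values[idx, m] <- rlnorm10(length(idx), tpl$markers[[m]], cfg$marker_sd)
      }
    }
    idx <- which(labels == "debris")
    if (length(idx)) {
      values[idx, "FSC"] <- rlnorm10(length(idx), 3.2, 0.1)
      values[idx, "SSC"] <- rlnorm10(length(idx), 3.0, 0.1)
      for (m in markers) values[idx, m] <- rlnorm10(length(idx), 1.8, 0.15)
    }
    eff <- cfg$disease_effects[[group]]
    if (!is.null(eff)) {
      for (m in names(eff)) values[, m] <- values[, m] * eff[[m]]
    }
    list(values = values, labels = labels)
  })
}

# Pass true intensities through an instrument: antibody-lot effect and
# residual per-instrument response on the markers, then spillover
# mixing, then per-detector gains.
render_instrument <- function(values, cfg, instrument, date, gains = NULL) {
  markers <- cfg$markers
  row <- match(instrument, cfg$instruments$instrument_id)
  if (is.null(gains)) gains <- cfg$gains[instrument, ]
  gains <- stats::setNames(rep_len(gains, length(markers)), markers)
  lot <- cfg$lot_periods$lot_id[cfg$lot_periods$start <= date &
                                  date < cfg$lot_periods$end]
  if (length(lot) == 1L) {
    values[, markers] <- sweep(values[, markers, drop = FALSE], 2L,
                               cfg$lot_effects[lot, ], `*`)
  }
  if (!is.na(row)) {
    values[, markers] <- sweep(values[, markers, drop = FALSE], 2L,
                               cfg$residual[instrument, ], `*`)
    sg <- cfg$instruments$scatter_gain[row]
    values[, c("FSC", "SSC")] <- values[, c("FSC", "SSC"), drop = FALSE] * sg
  }
  values[, markers] <- values[, markers, drop = FALSE] %*%
    unclass(cfg$spillover)[markers, markers]
  values[, markers] <- sweep(values[, markers, drop = FALSE], 2L, gains, `*`)
  values
}

#' Simulate one stained sample as seen by one instrument
#'
#' Draws cell-level true intensities from the population mixture
#' (`cell_seed`), then renders them through the instrument: antibody-lot
#' effect for the acquisition date, per-instrument residual response,
#' spillover mixing, and per-channel detector gains. Counting beads are
#' appended at a known concentration with Poisson-sampled event count.
#' Rendering the same `cell_seed` through different instruments yields
#' the same underlying sample measured by each of them.
#'
#' @param cfg a [sim_config()].
#' @param instrument instrument id.
#' @param date acquisition `Date`.
#' @param group disease group (a name of `cfg$groups`).
#' @param sample_id sample identifier.
#' @param cell_seed seed for the cell-level draws (shared across
#'   instruments to re-acquire the same sample).
#' @param seed seed for the acquisition-level draws (counting-bead
#'   count).
#' @param gains optional per-channel gain override (perturbation
#'   experiments).
#' @return list with `em` (the [event_matrix()], `$SPILLOVER` keyword
#'   set) and `truth` (true labels incl. `"counting_beads"`, population
#'   fractions of cells, expected concentration in cells/uL, gains,
#'   lot).
#' @export
simulate_sample <- function(cfg, instrument, date = cfg$date_range[1L],
                            group = names(cfg$groups)[1L],
                            sample_id = "sample01", cell_seed = cfg$seed,
                            seed = cell_seed + 1L, gains = NULL) {
  stopifnot(inherits(cfg, "sim_config"), group %in% names(cfg$groups))
  markers <- cfg$markers
  cells <- draw_cells(cfg, cfg$n_events, group, cell_seed)
  bead_vals <- with_seed(derive_seed(seed, 7L), {
    nb <- stats::rpois(1L, cfg$n_bead_events)
    v <- matrix(NA_real_, nb, length(markers) + 2L,
                dimnames = list(NULL, c("FSC", "SSC", markers)))
    v[, "FSC"] <- rlnorm10(nb, 5.3, 0.03)
    v[, "SSC"] <- rlnorm10(nb, 5.3, 0.03)
    for (m in markers) v[, m] <- rlnorm10(nb, 4.3, 0.03)
    v
  })
  values <- rbind(cells$values, bead_vals)
  labels <- c(cells$labels, rep("counting_beads", nrow(bead_vals)))
  values <- render_instrument(values, cfg, instrument, date, gains = gains)
  row <- match(instrument, cfg$instruments$instrument_id)
  em <- event_matrix(
    values, scatter = c(TRUE, TRUE, rep(FALSE, length(markers))),
    meta = list(instrument_id = instrument,
                center_id = if (!is.na(row)) cfg$instruments$center_id[row] else NA_character_,
                acquisition_date = date, panel_id = "panel1",
                sample_id = sample_id,
                vendor = if (!is.na(row)) cfg$instruments$vendor[row] else NA_character_),
    keywords = list(`$SPILLOVER` = format_spillover(cfg$spillover)))
  cell_tab <- table(factor(cells$labels,
                           levels = c(names(cfg$templates), "debris")))
  n_cells <- sum(cell_tab) - cell_tab[["debris"]]
  truth <- list(
    labels = labels,
    fractions = as.numeric(cell_tab[names(cfg$templates)]) / n_cells,
    populations = names(cfg$templates),
    n_bead_events = nrow(bead_vals),
    concentration = cfg$n_events * (1 - cfg$sample_debris_frac) /
      cfg$n_bead_events * cfg$beads_per_ul,
    group = group, gains = if (is.null(gains)) cfg$gains[instrument, ] else gains,
    lot = cfg$lot_periods$lot_id[cfg$lot_periods$start <= date &
                                   date < cfg$lot_periods$end]
  )
  list(em = em, truth = truth)
}

#' Simulate a full multi-center cohort as an FCS file tree
#'
#' Orchestrates per-day bead and sample generation over the lot
#' schedule and writes everything the file-level pipeline consumes:
#' vendor-dialect FCS files (Beckman-style or BD-style detector names
#' according to each instrument's vendor), a `metadata.csv` manifest,
#' and ground-truth CSVs (per-sample true fractions, instrument gains,
#' lot effects).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, a list with `metadata` (the manifest data frame),
#'   `truth` (per-sample ground-truth list), and `dir`.
#' @export
simulate_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "beads"), showWarnings = FALSE)
  dir.create(file.path(dir, "samples"), showWarnings = FALSE)
  map <- default_channel_map("panel1")
  manifest <- list()
  truth <- list()
  span <- as.integer(diff(cfg$date_range))
  group_names <- names(cfg$groups)
  for (ci in seq_len(cfg$n_centers)) {
    instrument <- cfg$instruments$instrument_id[ci]
    vendor <- cfg$instruments$vendor[ci]
    for (si in seq_len(cfg$n_samples_per_center)) {
      date <- cfg$date_range[1L] +
        floor(span * (si - 1L) / max(1L, cfg$n_samples_per_center - 1L))
      sample_id <- sprintf("%s_s%03d", instrument, si)
      g_seed <- derive_seed(cfg$seed, ci * 1000L + si)
      group <- with_seed(g_seed, sample(group_names, 1L, prob = cfg$groups))
      bead_path <- file.path(dir, "beads",
                             sprintf("%s_%s.fcs", instrument, format(date)))
      if (!file.exists(bead_path)) {
        bem <- simulate_beads(cfg, instrument, date,
                              seed = derive_seed(cfg$seed, "beads", ci, si))
        write_fcs(vendor_dialect(bem, vendor, map), bead_path)
        manifest[[length(manifest) + 1L]] <- data.frame(
          file = file.path("beads", basename(bead_path)), kind = "beads",
          sample_id = bem$meta$sample_id, instrument_id = instrument,
          center_id = cfg$instruments$center_id[ci], date = format(date),
          panel_id = "beads", group = NA_character_, stringsAsFactors = FALSE)
      }
      sim <- simulate_sample(cfg, instrument, date, group, sample_id,
                             cell_seed = derive_seed(cfg$seed, "cells", ci, si))
      path <- file.path(dir, "samples", paste0(sample_id, ".fcs"))
      write_fcs(vendor_dialect(sim$em, vendor, map), path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = file.path("samples", basename(path)), kind = "sample",
        sample_id = sample_id, instrument_id = instrument,
        center_id = cfg$instruments$center_id[ci], date = format(date),
        panel_id = "panel1", group = group, stringsAsFactors = FALSE)
      truth[[sample_id]] <- sim$truth["fractions"]
      truth[[sample_id]]$populations <- sim$truth$populations
      truth[[sample_id]]$group <- group
    }
  }
  metadata <- do.call(rbind, manifest)
  utils::write.csv(metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  gains_df <- data.frame(instrument_id = rownames(cfg$gains),
                         cfg$gains, check.names = FALSE)
  utils::write.csv(gains_df, file.path(dir, "truth_gains.csv"), row.names = FALSE)
  lots_df <- data.frame(lot_id = rownames(cfg$lot_effects),
                        cfg$lot_effects, check.names = FALSE)
  utils::write.csv(lots_df, file.path(dir, "truth_lot_effects.csv"), row.names = FALSE)
  fr <- do.call(rbind, lapply(names(truth), function(s) {
    data.frame(sample_id = s, population = truth[[s]]$populations,
               fraction = truth[[s]]$fractions, stringsAsFactors = FALSE)
  }))
  utils::write.csv(fr, file.path(dir, "truth_fractions.csv"), row.names = FALSE)
  invisible(list(metadata = metadata, truth = truth, dir = dir))
}

# Rewrite canonical channel names in the vendor's detector dialect so
# the cohort exercises channel standardization on read.
vendor_dialect <- function(em, vendor, map) {
  markers <- map$canonical[!map$scatter]
  alts <- strsplit(map$pattern, "|", fixed = TRUE)
  names(alts) <- map$canonical
  pick <- if (vendor == "BC") 1L else 2L
  unescape <- function(s) gsub("\\\\", "", s)
  new_names <- vapply(em$channels, function(ch) {
    if (!ch %in% map$canonical) return(ch)
    unescape(alts[[ch]][pick])
  }, character(1))
  out <- em
  out$channels <- unname(new_names)
  colnames(out$values) <- out$channels
  out
}

#' Simulate a cohort table directly at the statistics level
#'
#' Generates the samples-by-features table that the MFI correction
#' steps operate on, without event-level simulation: per-sample
#' population frequencies around the template fractions, absolute
#' counts, and MFIs built as template MFI x antibody-lot effect x
#' per-center effect x disease effect x biological log-normal noise.
#' Center effects enter only the MFIs (frequencies carry no center
#' effect), mirroring where center effects actually live.
#'
#' @param cfg a [sim_config()]; `center_effect_range` and
#'   `lot_effect_range` control the injected batch/center effects.
#' @param seed integer seed.
#' @param bio_sd log10 sd of per-sample biological variation in MFIs.
#' @return a [cohort_table()] with `batch_id` assigned from the lot
#'   schedule.
#' @export
simulate_cohort_table <- function(cfg, seed = cfg$seed, bio_sd = 0.08) {
  stopifnot(inherits(cfg, "sim_config"))
  templates <- cfg$templates
  pops <- names(templates)
  markers <- cfg$markers
  fractions <- vapply(templates, `[[`, numeric(1), "weight")
  base_mfi <- t(vapply(templates, function(t) 10^t$markers[markers],
                       numeric(length(markers))))
  colnames(base_mfi) <- markers
  group_names <- names(cfg$groups)
  span <- as.integer(diff(cfg$date_range))
  total_conc <- 5000  # leukocytes/uL, typical whole blood
  rows <- list()
  with_seed(derive_seed(seed, 909L), {
    for (ci in seq_len(cfg$n_centers)) {
      instrument <- cfg$instruments$instrument_id[ci]
      center <- cfg$instruments$center_id[ci]
      ce <- cfg$center_effects[center, ]
      for (si in seq_len(cfg$n_samples_per_center)) {
        date <- cfg$date_range[1L] +
          floor(span * (si - 1L) / max(1L, cfg$n_samples_per_center - 1L))
        group <- sample(group_names, 1L, prob = cfg$groups)
        lot <- cfg$lot_periods$lot_id[cfg$lot_periods$start <= date &
                                        date < cfg$lot_periods$end]
        row <- data.frame(
          sample_id = sprintf("%s_s%03d", instrument, si),
          instrument_id = instrument, center_id = center,
          acquisition_date = date, panel_id = "panel1",
          batch_id = NA_character_, group = group, stringsAsFactors = FALSE)
        freq <- 100 * fractions *
          exp(stats::rnorm(length(pops), 0, 0.1))
        freq <- 100 * freq / sum(freq)
        for (p in seq_along(pops)) {
          row[[paste0("freq.", pops[p])]] <- freq[p]
          row[[paste0("count.", pops[p])]] <- freq[p] / 100 * total_conc *
            exp(stats::rnorm(1L, 0, 0.05))
        }
        eff <- cfg$disease_effects[[group]]
        for (p in pops) {
          for (m in markers) {
            v <- base_mfi[p, m] * cfg$lot_effects[lot, m] * ce[[m]] *
              10^stats::rnorm(1L, 0, bio_sd)
            if (!is.null(eff) && m %in% names(eff)) v <- v * eff[[m]]
            row[[paste0("mfi.", p, ".", m)]] <- v
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  })
  tab <- do.call(rbind, rows)
  tab$batch_id <- assign_batches(
    stats::setNames(tab$acquisition_date, tab$sample_id),
    cfg$lot_periods, cfg$calib_dates)
  cohort_table(tab)
}
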