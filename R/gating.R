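#' Hierarchical threshold gating of events
#'
#' Assigns every event the deepest population label whose predicate
#' chain it satisfies, walking the population tree from the scatter
#' level down. Events matching a parent but none of its children keep
#' the parent's label; events matching no top-level population stay
#' `"all"`. Where sibling predicates overlap, the earlier definition
#' wins, so gating is fully deterministic and permutation-equivariant
#' over events.
#'
#' Gating is intended to run on normalized, compensated data: the
#' thresholds live on the normalized reference scale, and normalization
#' is what makes a single threshold set valid across instruments.
#'
#' @param em an [event_matrix()].
#' @param defs ordered list of [population_def()]s (parents before
#'   children).
#' @param thresholds named list of per-marker cut-point vectors (see
#'   [default_thresholds()]).
#' @return factor of population labels, one per event, with levels
#'   `"all"` plus every defined population.
#' @export
gate_events <- function(em, defs, thresholds) {
  stopifnot(inherits(em, "event_matrix"))
  used <- unique(unlist(lapply(defs, function(d)
    vapply(d$when, `[[`, character(1), "marker"))))
  missing_ch <- setdiff(used, em$channels)
  if (length(missing_ch)) {
    stop(sprintf("marker(s) used in population definitions missing from data: %s",
                 paste(missing_ch, collapse = ", ")))
  }
  missing_th <- setdiff(used, names(thresholds))
  if (length(missing_th)) {
    stop(sprintf("missing threshold for marker(s): %s",
                 paste(missing_th, collapse = ", ")))
  }
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  n <- n_events(em)
  labels <- rep("all", n)
  children_of <- split(seq_along(defs),
                       vapply(defs, `[[`, character(1), "parent"))
  assign_level <- function(parent, mask) {
    kids <- children_of[[parent]]
    if (is.null(kids)) return(invisible(NULL))
    # reverse order so the earliest sibling wins on overlap
    for (k in rev(kids)) {
      d <- defs[[k]]
      m <- mask & predicate_mask(em, d$when, thresholds)
      labels[m] <<- d$name
    }
    for (k in kids) {
      d <- defs[[k]]
      assign_level(d$name, labels == d$name)
    }
  }
  assign_level("all", rep(TRUE, n))
  factor(labels, levels = c("all", names(defs)))
}

predicate_mask <- function(em, when, thresholds) {
  m <- rep(TRUE, n_events(em))
  for (cnd in when) {
    x <- channel_values(em, cnd$marker)
    cuts <- thresholds[[cnd$marker]]
    bad <- setdiff(cnd$cuts, names(cuts))
    if (length(bad)) {
      stop(sprintf("missing threshold cut '%s' for marker %s",
                   paste(bad, collapse = ","), cnd$marker))
    }
    t1 <- cuts[[cnd$cuts[1L]]]
    m <- m & switch(cnd$op,
      gt = x > t1,
      le = x <= t1,
      between = x > t1 & x <= cuts[[cnd$cuts[2L]]]
    )
  }
  m
}

# Deepest-label members of a population include all its descendants.
descendants <- function(defs, name) {
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  parents <- vapply(defs, `[[`, character(1), "parent")
  out <- name
  repeat {
    more <- names(defs)[parents %in% out & !names(defs) %in% out]
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

#' Absolute concentration from counting beads
#'
#' Counting beads of known concentration are spiked into every sample;
#' the cell concentration is
#' `cells/uL = (population events / bead events) * beads_per_volume`.
#'
#' @param population_events number of events in the population.
#' @param bead_events number of counting-bead events acquired.
#' @param beads_per_volume bead concentration (beads/uL) from the lot
#'   metadata.
#' @return cells/uL.
#' @export
absolute_count <- function(population_events, bead_events, beads_per_volume) {
  if (bead_events < 1L) stop("acquisition failure: zero counting-bead events")
  if (beads_per_volume <= 0) stop("beads_per_volume must be positive")
  (population_events / bead_events) * beads_per_volume
}

#' Per-population statistics of a gated sample
#'
#' Computes, for every defined population: event count, frequency as a
#' percent of its parent and of leukocytes (all events in the
#' cell-lineage scatter classes), absolute concentration via the
#' counting beads, and the arithmetic-mean linear-scale MFI of every
#' fluorescence marker. Populations with zero events are reported as 0
#' with a low-count flag rather than erroring.
#'
#' @param em the gated [event_matrix()].
#' @param labels factor from [gate_events()] or [predict_gates()].
#' @param defs the population definitions used.
#' @param beads_per_volume counting-bead concentration (beads/uL), or
#'   `NULL` to skip absolute counts.
#' @param bead_population label of the counting-bead population.
#' @param leukocyte_populations scatter classes whose union defines the
#'   leukocyte denominator.
#' @param min_events populations with fewer events than this are flagged
#'   `low_count` and their MFIs set to `NA`.
#' @return a `population_stats` object: data frame (`population`,
#'   `parent`, `n`, `freq_parent`, `freq_leukocytes`, `count`,
#'   `low_count`) with the MFI matrix in attribute `mfi`.
#' @export
population_stats <- function(em, labels, defs, beads_per_volume = NULL,
                             bead_population = "counting_beads",
                             leukocyte_populations = c("lymphocytes",
                                                       "monocytes",
                                                       "granulocytes"),
                             min_events = 10L) {
  stopifnot(inherits(em, "event_matrix"), length(labels) == n_events(em))
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  member_mask <- function(name) labels %in% descendants(defs, name)
  n_of <- function(name) {
    if (name == "all") n_events(em) else sum(member_mask(name))
  }
  n_leuk <- sum(vapply(leukocyte_populations, n_of, numeric(1)))
  n_beads <- if (bead_population %in% names(defs)) n_of(bead_population) else 0L
  fluo <- fluorescence_channels(em)
  pops <- names(defs)
  mfi <- matrix(NA_real_, length(pops), length(fluo),
                dimnames = list(pops, fluo))
  rows <- lapply(pops, function(p) {
    mask <- member_mask(p)
    n <- sum(mask)
    n_parent <- n_of(defs[[p]]$parent)
    if (n >= min_events) {
      mfi[p, ] <<- colMeans(em$values[mask, fluo, drop = FALSE])
    }
    cnt <- if (!is.null(beads_per_volume) && !p %in% c(bead_population, "debris")) {
      absolute_count(n, n_beads, beads_per_volume)
    } else NA_real_
    data.frame(
      population = p, parent = defs[[p]]$parent, n = n,
      freq_parent = if (n_parent > 0) 100 * n / n_parent else 0,
      freq_leukocytes = if (n_leuk > 0) 100 * n / n_leuk else 0,
      count = cnt, low_count = n < min_events,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(out, mfi = mfi, n_leukocytes = n_leuk, n_beads = n_beads,
            class = c("population_stats", "data.frame"))
}

#' Flatten population statistics to one cohort-table row
#'
#' Feature columns follow the `freq.<pop>` / `count.<pop>` /
#' `mfi.<pop>.<marker>` convention; the debris and counting-bead gates
#' are bookkeeping populations and are not exported as features.
#' Frequencies are stored as percent of leukocytes (percent-of-parent
#' remains available from [population_stats()]).
#'
#' @param stats a [population_stats()] object.
#' @param meta acquisition metadata list (from `em$meta`).
#' @param group optional disease-group label.
#' @param exclude populations not exported as features.
#' @return a one-row data frame.
#' @export
cohort_row <- function(stats, meta, group = NA_character_,
                       exclude = c("debris", "counting_beads", "all")) {
  stopifnot(inherits(stats, "population_stats"))
  keep <- !stats$population %in% exclude
  pops <- stats$population[keep]
  mfi <- attr(stats, "mfi")
  row <- data.frame(
    sample_id = meta$sample_id, instrument_id = meta$instrument_id,
    center_id = meta$center_id, acquisition_date = meta$acquisition_date,
    panel_id = meta$panel_id, batch_id = NA_character_, group = group,
    stringsAsFactors = FALSE
  )
  for (p in pops) {
    row[[paste0("freq.", p)]] <- stats$freq_leukocytes[stats$population == p]
    row[[paste0("count.", p)]] <- stats$count[stats$population == p]
  }
  for (p in pops) {
    for (mk in colnames(mfi)) {
      row[[paste0("mfi.", p, ".", mk)]] <- mfi[p, mk]
    }
  }
  row
}
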