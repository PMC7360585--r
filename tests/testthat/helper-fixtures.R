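# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures on disk.

# A small panel-1 simulation: enough events for stable peak detection
# and gating, small enough that the whole suite stays fast.
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_centers = 3L, n_samples_per_center = 4L, n_events = 4000L,
         n_bead_events = 500L, bead_events_per_peak = 300L,
         bead_debris_events = 200L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Minimal event matrix with explicit channel values.
tiny_em <- function(values, channels = colnames(values), scatter = NULL,
                    meta = list(sample_id = "t", instrument_id = "instr01")) {
  event_matrix(as.matrix(values), channel_names = channels,
               scatter = scatter, meta = meta)
}

# Deterministic 8-peak bead event matrix with known peak means on the
# linear scale (no noise) for exact-arithmetic checks.
exact_beads <- function(peaks = 10^seq(2, 4.8, length.out = 8),
                        per_peak = 60L, channels = c("CD3", "CD4")) {
  x <- rep(peaks, each = per_peak)
  values <- cbind(FSC = rep(5e4, length(x)), SSC = rep(5e4, length(x)))
  for (ch in channels) values <- cbind(values, x)
  colnames(values) <- c("FSC", "SSC", channels)
  tiny_em(values, meta = list(sample_id = "beads", panel_id = "beads"))
}
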