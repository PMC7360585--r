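#' Panel configuration
#'
#' A panel bundles everything instrument-independent about one staining
#' tube: the canonical channel order (which makes event matrices from
#' different vendors column-compatible), which channels are scatter, the
#' gating thresholds on the normalized reference scale, the population
#' hierarchy, and the frozen reference 8-peak bead targets that every
#' instrument is normalized onto.
#'
#' Panel 1 covers the major leukocyte lineages (T/B/NK lymphocytes,
#' monocyte subsets, neutrophils, eosinophils) with CD3, CD4, CD8, CD19,
#' CD56, CD16, CD14 and CD15. Panel 2 covers dendritic cells and
#' basophils (HLA-DR, a combined lineage dump channel, CD123, CD11c,
#' CD1c, CD141).
#'
#' Thresholds are stored per marker as named cut points (`pos`, and where
#' needed `hi`); population predicates reference cuts by name. Because
#' gating happens after bead-anchored normalization, a single threshold
#' set is valid across instruments.
#'
#' @param panel_id `"panel1"` or `"panel2"`.
#' @return a list with elements `panel_id`, `channels`, `scatter`,
#'   `markers`, `thresholds`, `populations`, `reference_peaks`.
#' @export
default_panel <- function(panel_id = c("panel1", "panel2")) {
  panel_id <- match.arg(panel_id)
  if (panel_id == "panel1") {
    markers <- c("CD3", "CD4", "CD8", "CD19", "CD56", "CD16", "CD14", "CD15")
  } else {
    markers <- c("HLA-DR", "Lin", "CD123", "CD11c", "CD1c", "CD141")
  }
  channels <- c("FSC", "SSC", markers)
  scatter <- channels %in% c("FSC", "SSC")
  thresholds <- default_thresholds(panel_id)
  populations <- default_populations(panel_id)
  list(panel_id = panel_id, channels = channels, scatter = scatter,
       markers = markers, thresholds = thresholds,
       populations = populations,
       reference_peaks = default_reference_peaks(markers))
}

#' Default gating thresholds (normalized reference scale, linear units)
#' @param panel_id `"panel1"` or `"panel2"`.
#' @return named list; each entry a named numeric vector of cut points.
#' @export
default_thresholds <- function(panel_id = c("panel1", "panel2")) {
  panel_id <- match.arg(panel_id)
  scatter_cuts <- list(
    FSC = c(pos = 10^3.9, hi = 10^5.1),
    SSC = c(pos = 10^3.9, hi = 10^4.45, bead = 10^5.05)
  )
  if (panel_id == "panel1") {
    c(scatter_cuts, list(
      CD3  = c(pos = 10^2.8),
      CD4  = c(pos = 10^2.8),
      CD8  = c(pos = 10^2.8),
      CD19 = c(pos = 10^2.8),
      CD56 = c(pos = 10^2.8, hi = 10^3.8),
      CD16 = c(pos = 10^2.8, hi = 10^3.6),
      CD14 = c(pos = 10^3.0),
      CD15 = c(pos = 10^2.8)
    ))
  } else {
    c(scatter_cuts, list(
      `HLA-DR` = c(pos = 10^2.8),
      Lin   = c(pos = 10^2.8),
      CD123 = c(pos = 10^2.8),
      CD11c = c(pos = 10^2.8),
      CD1c  = c(pos = 10^2.8),
      CD141 = c(pos = 10^2.8)
    ))
  }
}

#' Define one population of the gating hierarchy
#'
#' @param name population name.
#' @param parent name of the parent population (`"all"` for the scatter
#'   level).
#' @param when list of conditions; each condition is a list with `marker`,
#'   `op` (`"gt"`, `"le"` or `"between"`) and `cuts`, the name(s) of the
#'   cut point(s) in the marker's threshold vector. All conditions must
#'   hold (conjunction).
#' @return a `population_def` list.
#' @export
population_def <- function(name, parent, when) {
  stopifnot(is.character(name), is.character(parent))
  for (cond in when) {
    stopifnot(all(c("marker", "op", "cuts") %in% names(cond)))
    stopifnot(cond$op %in% c("gt", "le", "between"))
  }
  structure(list(name = name, parent = parent, when = when),
            class = "population_def")
}

cond <- function(marker, op, cuts = "pos") list(marker = marker, op = op, cuts = cuts)

#' Default population hierarchies
#'
#' Panel 1: scatter classes (debris, lymphocytes, monocytes,
#' granulocytes, counting beads), then CD3+CD19- T cells with
#' CD4/CD8/NK-like subsets, CD3-CD19+ B cells, CD3-CD56+ NK cells split
#' into CD56high CD16low and CD56low CD16high, CD14/CD16 monocyte
#' subsets, and CD15+CD16high neutrophils vs CD15+CD16low eosinophils.
#'
#' @param panel_id `"panel1"` or `"panel2"`.
#' @return ordered list of [population_def()]s (parents before children).
#' @export
default_populations <- function(panel_id = c("panel1", "panel2")) {
  panel_id <- match.arg(panel_id)
  scatter_level <- list(
    population_def("debris", "all", list(cond("FSC", "le", "pos"))),
    population_def("counting_beads", "all",
                   list(cond("FSC", "gt", "hi"), cond("SSC", "gt", "bead"))),
    population_def("lymphocytes", "all",
                   list(cond("FSC", "between", c("pos", "hi")),
                        cond("SSC", "le", "pos"))),
    population_def("monocytes", "all",
                   list(cond("FSC", "between", c("pos", "hi")),
                        cond("SSC", "between", c("pos", "hi")))),
    population_def("granulocytes", "all",
                   list(cond("FSC", "between", c("pos", "hi")),
                        cond("SSC", "between", c("hi", "bead"))))
  )
  if (panel_id == "panel1") {
    c(scatter_level, list(
      population_def("t_cells", "lymphocytes",
                     list(cond("CD3", "gt"), cond("CD19", "le"))),
      population_def("cd4_t_cells", "t_cells",
                     list(cond("CD4", "gt"), cond("CD8", "le"))),
      population_def("cd8_t_cells", "t_cells",
                     list(cond("CD8", "gt"), cond("CD4", "le"))),
      population_def("nk_like_t_cells", "t_cells",
                     list(cond("CD56", "gt"))),
      population_def("b_cells", "lymphocytes",
                     list(cond("CD3", "le"), cond("CD19", "gt"))),
      population_def("nk_cells", "lymphocytes",
                     list(cond("CD3", "le"), cond("CD19", "le"),
                          cond("CD56", "gt"))),
      population_def("nk_bright", "nk_cells",
                     list(cond("CD56", "gt", "hi"), cond("CD16", "le"))),
      population_def("nk_dim", "nk_cells",
                     list(cond("CD56", "between", c("pos", "hi")),
                          cond("CD16", "gt"))),
      population_def("classical_monocytes", "monocytes",
                     list(cond("CD14", "gt"), cond("CD16", "le"))),
      population_def("intermediate_monocytes", "monocytes",
                     list(cond("CD14", "gt"), cond("CD16", "gt"))),
      population_def("nonclassical_monocytes", "monocytes",
                     list(cond("CD14", "le"), cond("CD16", "gt"))),
      population_def("neutrophils", "granulocytes",
                     list(cond("CD15", "gt"), cond("CD16", "gt", "hi"))),
      population_def("eosinophils", "granulocytes",
                     list(cond("CD15", "gt"), cond("CD16", "le", "hi")))
    ))
  } else {
    c(scatter_level, list(
      population_def("basophils", "lymphocytes",
                     list(cond("HLA-DR", "le"), cond("CD123", "gt"))),
      population_def("pdc", "lymphocytes",
                     list(cond("HLA-DR", "gt"), cond("Lin", "le"),
                          cond("CD123", "gt"), cond("CD11c", "le"))),
      population_def("mdc", "lymphocytes",
                     list(cond("HLA-DR", "gt"), cond("Lin", "le"),
                          cond("CD123", "le"), cond("CD11c", "gt"))),
      population_def("mdc1", "mdc",
                     list(cond("CD1c", "gt"), cond("CD141", "le"))),
      population_def("mdc2", "mdc",
                     list(cond("CD1c", "le"), cond("CD141", "gt")))
    ))
  }
}

#' Frozen reference 8-peak bead targets
#'
#' The reference targets play the role of the initial cross-instrument
#' calibration: eight log-spaced peak MFIs per fluorescence channel, onto
#' which every instrument-day is mapped by [fit_affine()]. Defaults span
#' roughly 2.8 decades, as rainbow calibration beads do.
#'
#' @param markers character vector of fluorescence channel names.
#' @param peaks numeric vector of 8 ascending peak MFIs shared by all
#'   channels.
#' @return a reference [peak_set()] with one column per marker.
#' @export
default_reference_peaks <- function(markers,
                                    peaks = 10^seq(2.0, 4.8, length.out = 8)) {
  stopifnot(length(peaks) == 8L, all(diff(peaks) > 0))
  m <- matrix(rep(peaks, length(markers)), ncol = length(markers),
              dimnames = list(NULL, markers))
  peak_set(m, n_events_used = rep(NA_integer_, length(markers)),
           is_reference = TRUE, instrument_id = "reference",
           date = as.Date(NA))
}
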