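Package: cytoharm
Title: Harmonization of Multi-Center Flow Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standardization workflow for prospective multi-center,
    multi-instrument flow cytometry studies: reading and writing FCS
    (2.0/3.0/3.1) and dual-dataset LMD files with channel-name
    canonicalization, rainbow 8-peak bead quality control, bead-anchored
    per-channel affine normalization of event data onto a frozen reference,
    spillover compensation with a residual-spill diagnostic, hierarchical
    threshold gating plus a two-stage supervised gating model, absolute
    counting with counting beads, ratio-of-medians corrections of extracted
    marker MFIs (antibody lot within instrument, then instrument to
    reference), and harmonization diagnostics (CVs, center-effect PCA,
    median-equality tests). A seed-deterministic synthetic generator emits
    bead files and multi-center stained-sample cohorts with known ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
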