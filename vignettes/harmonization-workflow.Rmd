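---
title: "Harmonizing multi-center flow cytometry data with cytoharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-center flow cytometry data with cytoharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prospective multi-center immunophenotyping studies compare population
frequencies, absolute counts and marker mean fluorescence intensities
(MFIs) measured on fresh blood across many cytometers, vendors and
years. Even after all instruments have been physically set to common
target intensities, three instrumental effects corrupt MFIs over time:
photomultiplier (PMT) gain drift within an instrument, systematic
shifts between dried-antibody production lots, and residual
fluorochrome-dependent differences between optical benches.
Frequencies and counts, which depend only on events falling on the
correct side of a gate, are far more robust; MFIs are where center
effects concentrate.

cytoharm implements the full software side of a six-step
standardization workflow:

1. **Frozen reference targets** — 8-peak rainbow-bead MFIs per channel,
   standing in for the initial cross-instrument calibration.
2. **Bead-anchored normalization** — daily bead acquisitions are peak-
   detected and a per-channel affine map onto the reference targets is
   fitted and applied to that day's sample events.
3. **Compensation** — spillover is inverted programmatically, with a
   residual-spill diagnostic replacing the operator's visual check.
4. **Gating** — a deterministic threshold hierarchy assigns leukocyte
   populations; a two-stage supervised model (per-instrument scatter
   stage, shared marker stage) mimics learned gating.
5. **Antibody-batch correction** — within each instrument, per-feature
   MFI medians of every batch are aligned onto the first batch by a
   ratio of medians.
6. **Instrument correction** — per-feature medians of every instrument
   are aligned onto the reference instrument the same way.

Steps 5 and 6 act on the extracted statistics table, never on events,
so frequencies and counts pass through bit-identical.

## The model

### Normalization (step 2)

For each fluorescence channel, let $o_1 < \dots < o_8$ be the observed
bead peak MFIs and $r_1 < \dots < r_8$ the reference targets, matched
by rank (gain changes preserve peak order, so rank matching is the
only robust pairing). The transform is affine,
$x \mapsto \alpha x + \beta$, with $(\alpha, \beta)$ the weighted
least-squares solution of

$$\min_{\alpha,\beta} \sum_{k=1}^{8} w_k\,(\alpha o_k + \beta - r_k)^2 .$$

**Weighting.** The default is $w_k = 1/r_k^2$, i.e. relative least
squares. This is a deliberate design choice: the peaks span almost
three decades, and under unweighted least squares the bright peaks'
sampling noise moves the intercept by tens of intensity units at
almost no cost in the loss — enough to corrupt the dimmest peak by
more than half its value while $R^2$ still exceeds 0.999. Relative
weighting gives every peak equal say in its own units, so each peak is
corrected to within its own sampling error. `weights = "none"` and
`"inverse_reference"` are available for comparison.

A fit with $\alpha \le 0$ or $R^2 < 0.99$ raises an error: a bead run
that cannot be mapped onto the reference affinely is corrupted and
must not be silently accepted. Negative corrected intensities
(possible when $\beta < 0$) are kept, not clipped, because downstream
statistics are means and medians and clipping would bias them.

The transform fitted from a day's bead file applies to sample files
acquired that day on that instrument; date matching is exact by
default with a configurable ±N-day fallback. Scatter channels are left
unchanged: the daily bead QC tracks fluorescence gain, and the gating
model handles scatter differences per instrument instead.

### Peak detection

Bead events are debris-filtered by a forward-scatter floor
(`debris_fsc_min`, default $10^4$ linear units; simulated debris sits
near $10^{3.2}$ and beads near $10^{4.7}$). Each channel's positive
events are then partitioned into 8 clusters by one-dimensional k-means
on $\log_{10}$ intensity with quantile-spaced initial centers. This
initialization is deterministic and shift-equivariant, which yields
two properties the tests rely on: identical results under event
permutation, and exact multiplicative equivariance (scaling all
intensities by $g$ scales every peak MFI by exactly $g$). A channel
errors if any cluster holds under 1% of events or two cluster centers
sit closer than 0.1 decades — the signatures of a merged or split
peak. The peak statistic is the arithmetic mean of linear intensities
(the study's MFI convention); the median is available by option.

### Daily QC

Each bead acquisition's peaks are compared to the *instrument's own
internal reference* (its first acquisition): per-peak percent
deviation $100\,|o-r|/r$ must stay below 5% for every peak of every
fluorochrome. The normalization transform, by contrast, always targets
the shared frozen reference. The 5% rule is applied to all 8 peaks.

### Compensation (step 3)

With spillover matrix $S$ (entry $S_{ij}$ = fraction of channel-$i$
signal detected in channel $j$, unit diagonal), compensated events are
$x^{\top} S^{-1}$ (row-vector convention). $S$ comes from the file's
`$SPILLOVER` keyword when present, else from configuration; the
keyword wins because it travels with the acquisition. Matrices with
condition number above $10^6$ are rejected. There is no automatic
re-estimation: adjustments are explicit configuration overrides, so
provenance is never hidden. The `residual_spill()` diagnostic reports
the bright-vs-dim median slope of a secondary channel against a
primary one; the 0.01 flag threshold is a package convention, chosen
as roughly the visual limit of an acceptable compensation plot.

### Gating (step 4)

Populations are declarative predicates (conjunctions of
above/below/between conditions on named cut points) arranged in a tree
whose first level is scatter classes (debris, lymphocytes, monocytes,
granulocytes, counting beads). Every event receives the deepest label
whose predicate chain it satisfies; earlier siblings win where
predicates overlap, making gating fully deterministic. Thresholds live
on the normalized reference scale — normalization is precisely what
makes one threshold set valid across instruments.

The supervised mimic reproduces the two-step architecture of learned
gating: scatter signals differ strongly between cytometers, so stage 1
(scatter classes from FSC/SSC, on $\log_{10}$ features) is one
classifier per instrument, while stage 2 (marker-level populations
within each scatter class) is shared across instruments. The
classifier family is a configuration choice; the default is a
classification tree (`rpart`, deterministic given data, `cp = 0.001`,
`minbucket = 5`), with LDA as the alternative. An instrument unseen in
training falls back to threshold gating with a warning.

Absolute counts use spiked counting beads of known concentration:
$\text{cells}/\mu L = (n_{\text{pop}} / n_{\text{beads}}) \cdot
\text{beads}/\mu L$. Frequencies are reported both as percent of
parent and percent of leukocytes; the cohort table stores percent of
leukocytes.

### MFI corrections (steps 5 and 6)

Let $m_{b}(f)$ be the median of feature $f$ (a population × marker MFI
column) over the samples of batch $b$ within an instrument. The batch
coefficient is $c_b(f) = m_{b_1}(f) / m_b(f)$ with $b_1$ the
instrument's earliest batch, and each sample's $f$ is multiplied by
its batch's coefficient. Because the median is multiplicative
($\mathrm{med}(c\,x) = c\,\mathrm{med}(x)$), per-batch medians align
*exactly*, re-computing coefficients on corrected data gives exactly
1, and within any (instrument, batch) the ratio of disease-group
medians is untouched — the algebraic form of "correct the instrument,
keep the biology". Step 6 is the same construction across instruments
with a designated reference instrument.

Three conventions are worth stating. "MFI of all samples" is
summarized by the median (the alignment is explicitly of median
values); the mean is available for sensitivity analysis. Coefficients
are computed per (population, marker) feature rather than pooled per
channel, because lot effects are antibody-specific. And the pipeline
order is fixed — normalize, compensate, gate, batch-correct,
center-correct; `center_coefficients()` refuses to run on a table
whose batch correction has not been applied.

Step 6 assumes all centers recruited a comparable case mix; when group
labels are present, a chi-squared heterogeneity check warns if the mix
differs across instruments, since the correction is biased otherwise.

Batches themselves combine the antibody lot (half-open date periods; a
boundary date belongs to the period starting that day) with the
recalibration epoch (number of recalibration dates on or before the
acquisition date), so three lots and seven recalibrations can yield up
to 21 batches per instrument.

### Diagnostics

`cv()` is $100 \cdot \mathrm{sd}/\mathrm{mean}$ (sample SD).
`center_effect_pca()` z-scores a feature block, decomposes it by SVD,
fixes signs by the largest-loading-positive rule, and reports the
between-center share of PC1–2 score variance as a separability score
in $[0,1]$. `median_equality_test()` applies a Kruskal–Wallis test per
feature across instruments — the equality test is not prescribed
anywhere, and a rank test is the natural companion to a
median-aligning correction; this is documented as a package
convention. Constant features are dropped from the PCA with a warning;
features without two instruments of ≥3 samples are flagged
not-computed rather than tested.

## The synthetic generator

`sim_config()` describes a study; every random draw (instrument gains,
lot effects, cells, beads) derives from its single seed, so a config
*is* its ground truth and every generator function is bit-reproducible
under a fixed seed.

What it emulates, with defaults:

* **Study shape** — 11 centers/instruments (the first is the unit-gain
  reference), a 4-year inclusion window (2015-01-01 to 2018-12-31),
  3 antibody lots in consecutive periods, 7 recalibration dates.
* **Instruments** — per-channel fluorescence gains drawn uniformly in
  [0.8, 1.25]; optional per-instrument scatter gains (default 1);
  optional per-instrument × marker residual responses (default off)
  modeling optical-bench effects that bead normalization cannot see.
* **Panel-1 biology** — 12 leukocyte mixture components with
  log-normal scatter and marker intensities (location in $\log_{10}$
  units, marker SD 0.12 ≈ 32% linear CV, scatter SD 0.05), negatives
  near $10^{2.1}$, positives near $10^{3.4}$–$10^{4}$, well clear of
  the $10^{2.8}$–$10^{3.0}$ cuts. Mixture weights approximate normal
  blood (50% neutrophils, 23% T cells, 9% monocytes, 5% B, 6% NK, …),
  plus 2% debris.
* **Acquisition** — ~10,000 cell events per sample, counting beads at
  Poisson(1000) events and 100 beads/µL, adjacent-channel spillover
  (4% forward, 2% backward) injected into every stained sample so
  compensation is exercised rather than bypassed.
* **Beads** — 8 peaks per channel at $10^{2.0}$–$10^{4.8}$
  (log-spaced), 500 events/peak, peak SD 0.05 $\log_{10}$, plus a
  low-scatter debris cluster.
* **Batch and disease structure** — multiplicative per-marker lot
  effects in [0.8, 1.3] (lot 1 = 1), a 1.5× CD19 shift in the
  "disease" group (a persistent biological difference the corrections
  must not remove), and, for the statistics-level generator
  `simulate_cohort_table()`, per-center MFI effects that enter MFIs
  only — frequencies carry no center effect, mirroring where center
  effects actually appear.

What it does **not** emulate: autofluorescence, doublets, acquisition-
time drift within a file, heavy-tailed or skewed marker distributions,
spectral overlap beyond a fixed linear spillover, or the exact
distributions of any real cohort. Tests passing on this generator
therefore demonstrate the *algebra and plumbing* of the workflow —
exact median alignment, gain recovery, order invariances — and its
statistical behavior under idealized log-normal mixtures; they do not
certify performance on real files, where gating robustness and
compensation adequacy are the binding constraints.

## Numerical choices and degenerate inputs

* FCS I/O: float32 storage on write (round trips are exact to single
  precision); log-amplified integer files are linearized at read time
  via `$PnE`/`$PnR` ($v \mapsto f\,10^{dv/r}$, $f=0$ read as 1);
  dual-dataset LMD files yield their last (FCS 3.0) dataset, the
  full-resolution one on Beckman instruments; unparseable dates error
  rather than guess.
* Channel standardization matches whole detector names
  case-insensitively, requires exactly one match per channel, reports
  offending names (files get fixed, not excluded), and is idempotent.
* k-means: quantile initialization, no restarts needed (deterministic);
  occupancy < 1% or center separation < 0.1 decades is an error.
* Correction exactness is floating-point exactness: invariant tests
  assert equality at $10^{-9}$, not bitwise, because even-count
  medians average two scaled values.
* Zero-event populations report frequency 0 with a `low_count` flag
  (MFIs set to `NA` below 10 events); zero counting-bead events are an
  acquisition failure and error.

## Problem sizes

The test suite and acceptance script run everything at desk scale,
chosen as the smallest sizes at which the checked quantities are
stable: bead fits at 500 events/peak; single-sample experiments at
~10,000 events; the multi-instrument experiment at 11 instruments
sharing one underlying sample; correction-recovery checks at 50–60
samples per batch or center on the statistics-level generator; the
gating-concordance check at 60 samples of 2,500 events over two
instruments. A full 2,500-individual, multi-year cohort is emulated in
structure, never required.

## Known limitations

* The affine model corrects gain-like drift only; nonlinear detector
  response or per-decade compression would need spline or quantile
  normalization, which is out of scope.
* The supervised gating stage is a demonstration of the two-step
  architecture, not a reproduction of any production automaton's
  boundaries.
* The instrument correction is only unbiased under a shared case mix
  across centers; the chi-squared warning flags, but cannot fix,
  recruitment imbalance.
* Batch coefficients from small batches inherit the median's sampling
  noise; the exactness guarantees concern alignment, not estimation
  efficiency.
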