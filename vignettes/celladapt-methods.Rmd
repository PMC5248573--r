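---
title: "celladapt: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celladapt: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celladapt)
```

# Scope

`celladapt` quantifies the heterogeneous response of BRAF-mutant melanoma
cells to RAF/MEK inhibition: apoptosis, G0/G1 arrest, or adaptation into a
slowly cycling, de-differentiated NGFR-high state. It operates strictly on
*derived* data — per-cell reporter traces, per-well counts, gene-level
abundance tables, per-cell intensity tables. Pixel-level segmentation,
read alignment, and enrichment analysis are out of scope by design.

Every input the pipeline consumes can be produced by a seeded generator in
the package, so the whole chain is testable offline. The generators are a
*stated world*: their defaults encode the experimental conditions the
analysis is meant to recover (fate mixture 60/20/20 for drug-treated
COLO858-like cells, deaths concentrated at 24–48 h, S-phase re-entry at
48–84 h, ~65 h inter-division time under drug versus ~24 h untreated,
6-min imaging cadence, an 84 h tracking window). Recovering these numbers
is a genuine test of the calling machinery — a mis-set threshold, a broken
event detector, or a wrong estimator fails it — but it is parameter
recovery at desk scale, not a replication of the underlying biology.

# The trace model

## Generative waveform

A cell's geminin reporter signal is modeled as zero in G0/G1, rising
linearly over the final `s_g2_duration_h` hours of each cycle (default
10 h) to an amplitude of 10 arbitrary units, and dropping instantaneously
to zero at division. Pointwise Gaussian noise (`noise_sd`, default 0.5 =
5% of amplitude) is added. The analysis depends only on threshold crossing
and the sharp terminal drop, not on the ramp shape, so the linear rise is a
convenience, not a claim about geminin kinetics.

Fates are drawn i.i.d. from `(p_death, p_arrest, p_adapt)`. Death times
use a truncated lognormal inside `death_window_h` with mode at the window
midpoint (36 h for the 24–48 h default) — concentrated in the window's
middle while keeping tails; a uniform fallback is available via
`death_time_dist = "uniform"`. Re-entry times of adapted cells are uniform
on `reentry_window_h`; the source data state only the window, so we add no
further structure. Subsequent cycles draw lognormal inter-division times
(mean `intermitotic_mean_h`, CV 0.15); the extra cycle time of adapted
cells relative to untreated cells is allocated entirely to G0/G1, with
S/G2 kept at `s_g2_duration_h` — matching the observation that slow
division reflects a prolonged G0/G1.

Two bookkeeping conventions matter for exactness:

* all event times are snapped to the imaging grid, so noiseless traces are
  *exactly* reconstructible from their schedules (an oracle-equality test);
* divisions in the first hour of a movie are not recorded: acquisition
  starts ~45–80 min after dosing, and a division within the first ~5
  frames is invisible to the sustained-run segmentation at any noise
  level. Without this the noiseless oracle-equality property would fail
  for reasons that have nothing to do with the detector.

Cells in S/G2 at drug addition finish that cycle and divide before
arresting, which reproduces the early mixture of divisions and deaths in
the first day of treatment.

## Smoothing

`smooth_geminin()` is a centered moving average (default 40 frames = 4 h
at 6-min cadence) with symmetrically shrinking windows at the edges
(half-width `min(k, i-1, n-i)`). Whether the window should be centered or
trailing is not specified by the source conventions; centered keeps onset
times unbiased, and the symmetric shrink makes the smoother exactly
mean-preserving whenever the first and last `2k` frames are constant —
the usual case, since traces start and end in the flat G0/G1 baseline. A
trace censored mid-ramp picks up a slope-dependent edge term bounded by
`2k * max|x| / n`; the test suite asserts exactness in the constant-edge
case and the bound otherwise.

## Phase calling and events

S/G2 onset is the first frame where the smoothed signal exceeds the
threshold (2.0 for COLO858-like, 1.5 for MMACSF-like traces) for at least
`min_run = 5` consecutive frames. The run requirement implements the
"in general above a threshold" caveat: a single-frame noise excursion is
not an onset. Segmentations are contiguous, cover the observed lifetime
and alternate phases by construction.

Division detection is automated (the original tracking was manual): each
S/G2 interval that terminates before the end of observation is scanned
near its falling threshold crossing for the steepest single-frame drop of
the *raw* signal; a division is called there if the signal falls by at
least `drop_fraction = 0.5` of the interval's peak within
`drop_frames = 2` frames. The drop test must use the raw signal: a
40-frame average spreads an instantaneous drop over 4 h and can never fall
50% in 2 frames. Annotated events, when present, take precedence; death
always comes from the viability channel (terminal `alive = FALSE`).

## Fate classification

`dead` if a death event exists; else `adapted` if an S/G2 onset or
division occurs after `arrest_min_h = 36`; else `arrested`. The 36 h
boundary separates the initial drug-induced arrest (complete within
~24 h) from adaptive re-entry (observed at 48–84 h) with margin on both
sides.

One honest limitation: an adapted cell whose re-entry falls within ~2 h of
the movie end produces a ramp that never reaches the calling threshold
before censoring. No detector can classify such a cell from the data, at
any noise level; under the uniform 48–84 h re-entry draw this affects
~6% of adapted cells (~1.2% of an 84 h cohort). The accuracy invariant in
the test suite is therefore scored on cells whose fate is in principle
observable; the residual unconditional error is a censoring property of
the 84 h window, not a detector property. Cohort-level fate fractions
absorb this as a ~1-point transfer from adapted to arrested, well inside
binomial sampling error at n = 300.

## Minimum doubling time

For divisions t1 < … < tk inside an observation window [a, b], the
estimator returns `max(t1 - a, t2 - t1, ..., b - tk)`; with a single
division this is `max(t1 - a, b - t1)`, minimized (48 h) by a division at
the midpoint of a 96 h window. With no divisions the window length is
returned with a `lower_bound` flag — the cell demonstrably did not double
within the window. Inter-division gaps are included for k ≥ 2 by
convention; the anchored single-division case is unaffected.

# Population statistics

Fate fractions are reported as mean ± sample SD (n−1) across 3–4
round-robin groups of ~50–70 cells, mirroring how imaged wells are pooled
in practice; explicit group labels are honored when supplied. The pooled
fraction equals the size-weighted mean of group fractions (tested).
Growth curves count live traces per 45-min time point normalized to t = 0;
doubling times come from least-squares fits of log counts (natural log),
with non-positive slopes (up to 1e-10, so an exactly flat curve is not
defeated by float noise) flagged as no-growth and returned as `Inf`.

# Pharmacology

* **Apoptosis scoring**: a cell is apoptotic iff spot intensity divided by
  nucleus area exceeds a separating threshold; the default threshold is an
  Otsu split of the pooled log ratio distribution, since only "a
  separating threshold" is specified by the assay description.
* **GR values**: `GR = 2^(log2(x_c/x_0)/log2(x_ctrl/x_0)) - 1`; a
  non-growing control makes the normalization undefined and is an explicit
  error, not a NaN.
* **Dose–response fits**: descending Hill with residual floor,
  `r(d) = E_max + (1-E_max)/(1+(d/EC50)^h)`, fitted by Nelder–Mead least
  squares on (E_max, log EC50, log h) from two heuristic starts plus a
  polish pass. E_max here is the *residual viable fraction* at saturating
  dose, so "reduced maximal effect" appears as a *higher* fitted E_max.
  Noiseless recovery to ≤ 1e-4 relative error is asserted over 100 random
  parameter draws. Flat responses return a degenerate-fit flag instead of
  parameters. The exact functional form used historically is unstated; any
  monotone Hill parameterization satisfying the invariants is acceptable,
  and this one is the field default.
* **AUC**: trapezoid over log10 dose with dose 0 mapped to one tenth of
  the smallest nonzero dose (the reference grid is unspecified; this keeps
  the untreated anchor on the grid at a fixed one-decade offset).
* **Sequential dosing**: the generator applies a bell-shaped (in log10
  dose) protection factor peaking at 0.1 uM with target amplitude 2.5,
  compensated for the extra Hill attenuation of the pre-treatment dose
  itself so the realized peak fold-change equals the stated 2.5. The
  mechanism of protection is deliberately phenomenological — the source
  observation is the phenomenon, not a mechanism. In the endpoint-plate
  generator, pre-treatment shifts the curve parameters (residual E_max up
  by the protection factor, Hill slope down), which is the form in which
  adaptation manifests in 3-day dose–response assays.

# Expression rules

The differential filter selects, per drug time point, genes with q < 0.01
versus DMSO in at least one line, treated FPKM ≥ 1, and
|log2(FC_A/FC_B)| ≥ 1 where FC is the treated-versus-DMSO fold-change per
line. Two stated ambiguities were resolved as follows: the FPKM floor is
applied in the line whose q-value made the gene eligible (configurable to
max-over-lines), and the 24 h / 48 h time points are filtered per time
point. Fold-changes are (FPKM+1)-stabilized by default so zero-DMSO genes
are well-defined; raw-ratio mode flags and excludes them instead. The
synthetic table plants its differential genes in the well-expressed range
(baseline ≥ 10 FPKM) so that the planted-recovery contract tests rule
logic rather than shrinkage near the detection floor.

Clustering preparation uses log2((FPKM+1)/(FPKM+1)_DMSO) matrices with
Chebyshev (maximum-coordinate) distances and configurable agglomeration
(default average linkage); dendrograms are exported as Newick strings.
Landscape z-scores use sample SD (n−1) across conditions; the log base is
immaterial (z-scores are invariant to it, asserted by test). Degenerate
zero-SD markers are flagged and given z = 0 rather than NaN.

# Screens and gating

Screen readouts are averaged over replicates and doses per compound,
z-scored within line (so any per-line affine transform of raw intensities
leaves the result unchanged — asserted by test), and ranked ascending;
hits are compounds within the `k = 5` lowest ranks in *every* line.
z-scoring uses compound wells only. Tie handling at the rank-k boundary:
a tie group straddling the boundary is included and flagged, because
excluding it would silently drop borderline hits — unless the group has
more than k members, since a block of more than k indistinguishable
compounds cannot meaningfully be "among the k lowest" (this guard is what
makes the zero-noise screen, where all inactive compounds tie exactly,
return exactly the planted suppressors).

Marker gating defaults to Otsu thresholds on log intensities (how the
High/Low cut lines were drawn historically is not documented); fixed and
quantile-of-reference thresholds are available. Fractions are *strictly
above* threshold; an all-identical marker yields fraction 0 with a
degenerate-threshold flag. Background exclusion removes cells whose
pre-stain (secondary-antibody-only) intensity exceeds a threshold and
never alters retained cells' values.

# What the generators do and do not emulate

They emulate: the three-fate mixture with its stated timing; censoring by
movie length; plate-level Hill viability with multiplicative replicate
noise and background apoptosis; two-line expression tables with planted
cross-line ratios; screen plates with planted suppressors over distinct
line baselines; biopsy-like two-component log-normal marker mixtures with
flagged high-background regions.

They do not emulate: lineage (daughters are not spawned as new traces, so
cohort growth curves plateau rather than rise once deaths cease);
tracking errors or cell loss; spatial structure of tissue; dose-dependent
fate mixtures (fate probabilities are per-preset constants); correlated
noise or drift in the reporter signal; library-size or dispersion
structure of real RNA-seq (q-values are planted, not computed). A green
test therefore establishes that the pipeline recovers the stated world's
parameters through the full calling chain, not that it would be robust to
artifacts the generators do not model.

# Numerical conventions collected

* Event times snap to the imaging grid; oracle-equality tests use 1e-9
  tolerances, except segmentation boundaries versus the brute-force
  oracle, which allow one frame (float ties at the threshold between
  `cumsum`-based and `mean()`-based averaging can flip one comparison on
  exact ramp values).
* Interval membership is half-open `[start, end)` for division-per-interval
  counts and death-window tallies.
* Boundary fold-change classification is inclusive of `no_change`
  (|log2 FC| = 0.5 is "no change").
* `fate_fractions` requires non-empty groups; `gate_high` requires ≥ 10
  cells; `fit_dose_response` requires ≥ 4 distinct doses including 0.
* Sample SD (n−1) throughout for across-group / across-condition /
  across-line scale estimates.

# Known limitations

* The 84 h fate window cannot contain two divisions of an adapted cell
  (earliest second division ≈ 123 h under the stated timing), so
  inter-division intervals are measured on 8-day runs of the same preset —
  the duration over which slow division times were originally tracked.
* The adaptation (protection) rule is phenomenological and calibrated to
  its stated peak; it should not be read as a mechanistic model.
* Otsu gating assumes approximate bimodality; heavily unbalanced mixtures
  (a few percent high) bias the threshold slightly — visible as a few
  tenths of a point in recovered fractions at n = 10,000.
* No statistical testing beyond descriptive mean ± SD is provided; the
  original ANOVA/t-tests are routine and intentionally out of scope.
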