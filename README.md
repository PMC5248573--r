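# celladapt

Single-cell fate calling and drug-adaptation analytics for BRAF-mutant
melanoma imaging data.

## The problem

BRAF<sup>V600E</sup> melanoma cells exposed to RAF/MEK inhibitors
(vemurafenib, dabrafenib, trametinib) near the IC50 do not respond
uniformly: within the first 3–4 days some cells undergo apoptosis, some
arrest in G0/G1, and the remainder *adapt* — they re-enter the cell cycle
and keep dividing slowly in drug, de-differentiating into a neural-crest-like
NGFR-high state. Because this adaptation is reversible and sub-population
specific, it is invisible to bulk endpoint assays and has to be quantified
cell by cell from live-cell reporter traces, then connected to plate-level
pharmacology, expression profiling, compound screens and tissue staining.

`celladapt` implements that full analysis chain for people working with
geminin-reporter time-lapse data and high-content plate assays, paired with
seeded synthetic-data generators that emulate each assay so that every stage
of the pipeline is testable without any external download.

## What it computes

**Trace analysis.** The geminin signal of a cell is zero in G0/G1,
accumulates through S/G2 and collapses at division. Traces sampled every
6 min are smoothed with a centered 40-frame moving average; S/G2 onset is
the first sustained crossing of a threshold (2.0 for COLO858, 1.5 for
MMACSF), divisions are sharp drops of the raw signal at the end of an S/G2
interval, and death comes from the viability channel. Each cell is then
classified as **dead**, **arrested**, or **adapted** (an S/G2 onset or
division after 36 h, separating initial drug arrest from adaptive
re-entry). The minimum doubling time of a cell observed over a window
\[a, b\] with divisions t1 < … < tk is `max(t1 − a, t2 − t1, …, b − tk)`.

**Population statistics.** Fate fractions as mean ± SD over 3–4
round-robin groups of ~50–70 cells; percentage of cells dividing per time
interval; live-cell growth curves; log-linear doubling-time fits.

**Pharmacology.** Apoptosis scoring (spot intensity / nucleus area above a
separating threshold), relative viability, growth-rate inhibition
`GR = 2^(log2(x_c/x_0) / log2(x_ctrl/x_0)) − 1`, descending Hill fits
`r(d) = E_max + (1 − E_max) / (1 + (d/EC50)^h)` with AUC over log10 dose,
and sequential-dosing protection summaries.

**Expression and screens.** The cross-line differential filter (q < 0.01 in
at least one line, FPKM ≥ 1, |log2 of the fold-change ratio between lines|
≥ 1), fold-change classification at ±0.5 log2 units, Chebyshev-distance
clustering of log2((FPKM+1)/DMSO) matrices, z-scored NGFR/Ki-67 landscapes,
AUC-based marker correlation, screen hit selection (compounds within the
five lowest NGFR z-scores in every line) and Otsu gating of per-cell marker
tables with background-region exclusion.

## Worked example

```r
library(celladapt)

# 300 COLO858 cells, 1 uM vemurafenib, 84 h movie
panel <- simulate_fate_cohort(fate_preset("colo858_vem"), 300, seed = 1)
calls <- analyze_traces(panel, threshold = 2.0, window_frames = 40,
                        use_annotations = FALSE)
fate_fractions(calls, grouping = assign_groups(300, 4))
#> Fate fractions over 4 groups (mean +/- SD):
#>   dead       63.0% +/-  6.7%
#>   surviving  37.0% +/-  6.7%
#>   arrested   18.0% +/-  0.8%
#>   adapted    19.0% +/-  6.4%
```

The cohort was generated with 60/20/20% dead/arrested/adapted fates; the
pipeline (smoothing, phase calling, event detection, classification)
recovers 63/18/19% at this seed — within binomial sampling error at n = 300.

```r
sq <- simulate_sequential_plate(plate_preset_named("colo858_seq"), seed = 1)
sequential_dosing_summary(sq)
#>   pretreat_dose fold_change     sd n
#> 1         0.000       1.000 0.0560 4
#> 2         0.010       1.224 0.0417 4
#> 3         0.032       2.029 0.0763 4
#> 4         0.100       2.438 0.1680 4
#> 5         0.320       1.705 0.0361 4
#> 6         1.000       0.839 0.0548 4
```

Pre-treating with a sub-IC50 dose of drug protects against a subsequent
1 uM bolus; the fold-change in surviving cells peaks (~2.4-fold here,
2.5-fold in expectation) at 0.1 uM pre-treatment.

```r
gr_value(x_c = 200, x_0 = 100, x_ctrl = 400)$gr   # half-log case
#> [1] 0.4142136

bt <- simulate_biopsy_table(biopsy_preset_named("ontreat"), seed = 1)
gate_high(exclude_background(bt, attr(bt, "bg_threshold")))
#> Marker gating over 9485 cells:
#>   ngfr   threshold 1.235, 30.2% high
#>   ki67   threshold 1.205, 4.2% high
```

Otsu gating on the synthetic on-treatment biopsy recovers the planted 30%
NGFR-high / 4% Ki-67-high composition after excluding flagged
high-background regions.

## Command line

A thin CLI wraps the common steps:

```sh
Rscript inst/cli/celladapt analyze-traces --traces traces.csv --threshold 2.0 --window 40 --out calls.csv
Rscript inst/cli/celladapt screen-hits --screen screen.csv --k 5 --out hits.csv
Rscript inst/cli/celladapt gate --cells cells.csv --method otsu --out gate.json
```

See `vignettes/celladapt-methods.Rmd` for the model assumptions, parameter
choices and known limitations.
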