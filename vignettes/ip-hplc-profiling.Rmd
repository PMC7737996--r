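---
title: "IP-HPLC protein expression profiling: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IP-HPLC protein expression profiling: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iphplc)
```

## The measurement and its model

Immunoprecipitation HPLC (IP-HPLC) estimates the relative abundance of one
protein at a time: an antibody-loaded protein A/G column captures the
target from a lysate, the eluate is run over a reverse-phase column
(0.4 mL/min, 30 min) and detected by UV absorbance at 280 nm. The
instrument output is a chromatogram — absorbance in mAU on a uniform time
grid in minutes — whose target peak area (mAU·s) scales with the amount of
captured protein.

The pipeline turns a pair of such traces (treated and untreated-control
cells, plus a shared negative-control antibody trace per batch) into a
percent expression ratio:

1. **Peak window.** The dominant peak is located on the coarse
   baseline-corrected, lightly smoothed trace and its window extends to
   the 1%-of-apex-height crossings, widened by half of each half-width so
   slow tails stay inside the window.
2. **Baseline.** A straight line anchored on the medians of 0.2-min
   flanking segments either side of the window.
3. **Area.** Trapezoidal integration of signal − baseline over the
   window, converted minutes → seconds (× 60). Negative sub-areas are
   kept: zero-mean noise then cancels in expectation.
4. **Background subtraction.** The negative-control antibody's peak area
   estimates non-specific binding and is subtracted *in the area domain*.
   A negative net area is clamped to 0 and flagged; a clamped control run
   leaves the ratio undefined and the run is logged and skipped rather
   than poisoning the profile.
5. **Level and ratio.** The expression level is the square root of the
   net area; the reported quantity is 100 × treated level / control
   level. The square root makes ratios invariant to a common detector
   gain: √(ga)/√(gb) = √(a/b).

## Replicate aggregation and the convergence rule

Each (protein, timepoint) cell is measured on two to six paired runs.
Replicate ratios are consumed in arrival order: two always, then one more
while the sample SD exceeds 5 percentage points, stopping at six. The
aggregate is *converged* when the final SD is ≤ 5; an unconverged cell is
still reported, flagged. The standard error is sd/√n — the conventional
SEM; the alternative sd/√(2n) reading of the garbled printed formula in
our source material was rejected as non-standard. Replication is applied
per protein (the most conservative reading of "repeated two to six
times").

Worked example: ratios arriving 100, 110 have SD 7.07, so a third run is
taken; (100, 110, 105) has SD exactly 5.0 → converged, mean 105.0,
SE 2.887.

## Change bins and housekeeping QC

Deviations of the aggregated ratio from 100% are binned: |Δ| < 5 minimal,
5 ≤ |Δ| < 10 slight, 10 ≤ |Δ| < 20 significant, |Δ| ≥ 20 marked.
Boundary membership is not stated anywhere authoritative; we assign
boundaries to the larger-magnitude bin (a 5.0-point change is "slight"),
the only choice consistent with "less than ±5%" describing the minimal
bin.

Housekeeping proteins (α-tubulin, β-actin, GAPDH — stored ASCII-safe as
`alpha-tubulin`, `beta-actin`, `GAPDH`) are assumed non-responsive. A
timepoint passes QC only if all three deviate ≤ 5 points from 100%;
failures name the offending proteins and are attached to the results
rather than aborting the run, so an analyst always sees the full profile
with its QC verdict.

## The antibody panel registry

The packaged registry transcribes the study panel: 232 distinct antisera
occupying 280 slots in 20 categories (19 signaling-pathway groups plus
housekeeping controls), with 46 slots marked as cross-category overlaps.
Overlapping antibodies are stored once with multi-category membership,
never duplicated. Category order fixes plotting order everywhere
downstream.

Three reconstruction points are worth knowing:

* **Count tensions.** Two printed count cells disagree with their own
  enumerated rows (downregulated inflammatory proteins: 25 printed vs 26
  listed; ER stress-related proteins: 11 printed vs 12 listed). We keep
  the enumerated membership — the membership is the substance, the count
  column is derived arithmetic — and `load_panel()` warns with both
  numbers. The related "233 antisera" vs 278 − 46 = 232 tension is
  recorded in the fixture header (`stated_antisera`), not resolved.
* **Representative subset.** The 116-protein star-plot subset is not
  enumerable from the available text. The fixture flags exactly 116
  proteins, allocated over the 19 groups proportionally to group size
  (largest-remainder), taking members in registry order, each protein
  flagged once under its first group. This is a documented
  reconstruction; any other 116-protein selection plugs in by editing the
  `representative` column.
* **Names.** Epitope/alias parentheticals are dropped and Greek letters
  transliterated, so names are stable across encodings.

## The synthetic-data generator

No raw traces are deposited with the study, so validation rests on a
generator that emulates the measurement process with exact ground truth:

* **Peaks** are exponentially modified Gaussians *parameterized by area*
  (EMG preserves area under tailing, so the truth stays exact for any
  tail constant τ). Evaluation is in log space via `pnorm(log.p = TRUE)`
  to stay finite for small τ; τ below 10⁻⁶σ falls back to the Gaussian.
* **Traces** add a linear baseline and i.i.d. Gaussian detector noise on
  a 30-min grid at 0.01-min steps (280 nm, 0.4 mL/min carried as
  metadata). Defaults: target peak at 12 min, σ = 0.1 min, τ = 0.05 min.
* **Experiments** place a control net area of 10 000 mAU·s per antibody
  (level 100), treated areas at `level_fold²` × control so that the
  measured ratio is exactly 100 × fold when noise is off, a shared
  negative-control background of 150 mAU·s, multiplicative lognormal
  replicate variation (mean-1, given CV), baseline drift 0.02 mAU/min
  over offset 1 mAU, and detector noise SD 0.2 mAU. The instrument noise
  magnitude is not stated anywhere; these values were chosen once to give
  realistic-looking traces (apex SNR ≈ 300 for the default area,
  background peak SNR ≈ 30) and are free parameters of the generator.
* **Housekeeping** antibodies are forced to fold 1 at all timepoints —
  the generator refuses anything else, because downstream QC treats their
  stability as an axiom.
* Everything is a pure function of (parameters, seed); the global RNG
  state is saved and restored around each generator call.

What the generator does **not** emulate: retention-time drift between
runs, co-eluting/overlapping analytes, column degradation, detector
nonlinearity and IP capture-efficiency differences between antibodies.
Passing recovery tests therefore demonstrate that the *algorithmic* chain
is unbiased and gain-invariant under the stated noise model — not that
the assay itself is accurate on real lysates.

## Pathway summaries and figures

Per protein, the *extremum change* is the largest-magnitude signed
deviation from 100% across 8/16/24 h (ties to the earliest timepoint).
Group summaries average member extrema — overlap proteins count in every
group listing them — and call a group activated above +5 points,
inactivated below −5, mixed otherwise; the threshold deliberately reuses
the minimal-change bound and is a single parameter. Line graphs draw one
polyline per protein against culture time with the control line at 100%,
sharing one y scale across batch-rendered groups. Star plots draw one
radial axis per protein in registry order, the control ring at 100%, and
either one polygon per timepoint (default) or a single extremum series
(the summary figure's "maximum or minimum" phrasing is ambiguous between
the two, so both are provided). The radial maximum is 10% above the
largest plotted value and is recorded, with the axis count and series,
in a `.meta.txt` sidecar so tests can inspect structure without parsing
images.

## Numerical choices and degenerate inputs

* Trapezoidal rule over spline integration: exact for the piecewise-linear
  data the detector delivers, and auditable.
* Robust noise estimate: 1.4826 × MAD of the first-differenced trace /√2.
* Peak detection smooths with a 5-sample moving average before apex
  finding; with ~3000 samples per trace, the expected maximum of raw
  noise alone exceeds 3σ, so an unsmoothed 3σ apex rule would "detect"
  peaks in blank traces.
* A peak apex must exceed 3 × noise; blank traces raise "no peak
  detected".
* Windows shorter than 3 samples, windows touching the trace edge
  (no baseline flank), non-increasing time grids, and traces under 8
  samples are errors, not warnings.
* Results TSVs round percent values to one decimal (the reporting
  precision) with deterministic row order, so identical tables produce
  byte-identical files.

## Problem sizes used by the tests

The shipped tests validate integration at the 0.01-min default grid and
run pipeline-level recovery on panel subsets (about a dozen antibodies,
six replicates) at a 0.02-min grid; the acceptance script profiles the
full 232-antibody panel at the 0.02-min grid. These sizes give the
recovery checks comfortable statistical room (mean absolute ratio error
< 2 points at CV 2%, n = 6) while keeping a full run in tens of seconds.

## Known limitations

Single-peak quantification only (no deconvolution of overlapping
analytes, no retention alignment across batches); linear baselines; the
negative-control subtraction is area-domain, per the assay's published
description, so point-wise background structure is invisible to it; and
the representative star-plot subset is a reconstruction, as described
above.
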