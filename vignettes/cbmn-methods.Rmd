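---
title: "Automated CBMN scoring: models, parameters and design choices"
author: "cbmnassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CBMN scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmnassay)
```

# The assay and what the package computes

The in vitro cytokinesis-block micronucleus (CBMN) assay reads out
chromosomal damage in cultured cells. Cytochalasin B blocks cytokinesis, so
cells that completed one mitosis appear *binucleated*; a lagging chromosome
or acentric fragment left outside the daughter nuclei forms a
*micronucleus* (MN), a small extranuclear chromatin body. Genotoxicity is
expressed as the percentage of binucleated cells carrying at least one
micronucleus, and cytotoxicity/cytostasis as

- cell-number method: $\%\,\mathrm{Cyt}_{CN} = 100\,(N_u - N_t)/N_u$ for
  untreated and treated cell yields $N_u, N_t$;
- CBPI method: $\mathrm{CBPI} = (N_1 + 2N_2 + 3N_3)/(N_1+N_2+N_3)$ over
  mono-, bi- and polynucleated counts, and
  $\%\,\mathrm{Cyt}_{CBPI} = 100 - 100\,(\mathrm{CBPI}_t - 1)/(\mathrm{CBPI}_c - 1)$.

CBPI is the mean number of completed cycles and lies in $[1, 3]$; a
published variant of the formula carries a stray factor 100, which is
dimensionally inconsistent with the cytostasis equation and with the
conventional 1.5-2-cycle range, so the package uses the plain ratio.

Two scoring routes are implemented, mirroring the two instruments used for
automated CBMN work:

1. **Widefield microscopy route** (`runMicroscopyPipeline()`): a
   CellProfiler-style three-block pipeline on DNA-stained field images —
   nuclei as primary objects, cells as secondary objects by fixed-distance
   expansion, cytoplasm as the doughnut-shaped difference, then
   micronucleus calls by area/compactness with parent assignment.
2. **Imaging-flow-style route** (`scoreTiles()` + `applyGates()`): per-cell
   two-channel tiles, morphological masks combined by Boolean logic, ten
   scalar features, and a sequential gate chain ending in the accepted
   binucleated-cell (BNC) population with an MN spot-count histogram.

Because no raw image data are published for this assay design, the package
ships a ground-truthed synthetic generator; every claim the test suite
makes is a *parameter-recovery* claim: images are generated at known
condition values and the pipelines must measure those values back.

# The synthetic generator and its presets

`presetTable()` encodes one `ConditionPreset` per experimental condition of
the emulated study: negative control (NC), mitomycin C at 0.025/0.125/0.25
ug/mL, a plant leaf extract at 50/100/200 ug/mL, and the extract + MMC
combinations. The anchors are the printed condition summaries:

- binucleated percentage (e.g. 40.75% for NC, 25.83% for MMC-0.25);
- micronucleus frequency among binucleated cells (1.00% NC, 5.60% MMC-0.025;
  the combination at 50 ug/mL + MMC uses the reported 34% reduction,
  i.e. $0.056 \times 0.66 = 0.03696$);
- percent cytotoxicity by both methods, giving the survival fraction
  ($1 - \mathrm{Cyt}_{CN}/100$) and, through inversion of the cytostasis
  equation against the NC CBPI, the polynucleated fraction (or the
  binucleated fraction where no percentage was printed).

Quantities the study does not print are documented package defaults chosen
once: polynucleated fraction 0.02, MN count distribution 0.85/0.12/0.03
over 1-3 micronuclei, MN rates for the two higher MMC doses (0.09, 0.12,
continuing the printed dose trend), and the combination presets'
binucleated fractions (0.40/0.38/0.37, qualitatively above MMC alone as
reported). The flow route reports only a 2.2-fold MMC/NC induction, with no
absolute baseline; the `NC-FLOW`/`MMC-FLOW` presets use 8% and 17.6%.
Automated imaging-flow MN scoring is known to run severalfold above visual
microscopy baselines, and at a few thousand tiles per condition this
baseline keeps the binomial noise of the fold estimate well inside its
acceptance band; the 2.2 ratio itself is exact.

## Image model

A field is rendered on a 16-bit-like scale: background 300, per-cell
nucleus intensity uniform in 12000-20000. Cells sit at Poisson-disc-sampled
anchors (Bridson sampling at 7.2 nucleus radii minimum spacing, which makes
micronucleus parentage geometrically unambiguous); mononucleated cells are
one ellipse (axis ratio 1-1.3, radius 18 +/- 1.5 px truncated to
[15.5, 20.5]), binucleated cells two near-equal ellipses whose centres are
1.6-2.1 radii apart — touching but distinct, the classical appearance of a
cytochalasin-blocked daughter pair — and polynucleated cells three ellipses
at 1.2-1.35 radii from the anchor. Micronuclei (radius ratio 0.18, i.e.
within the classical 1/16-1/3 diameter convention) are placed only in
binucleated cells, 1.5-1.9 nucleus radii from their host nucleus centroid
and never touching any nucleus; they are drawn at the top of the intensity
range (18000-20000), reflecting the dense staining of condensed
micronuclear chromatin. The clean image is degraded by a Gaussian
point-spread proxy (sigma 2 px), Poisson shot noise (0.02 expected counts
per intensity unit), and Gaussian read noise (3% of the dynamic range).

Single-cell tiles (128 x 128, two channels: brightfield proxy and DNA)
reuse the same nucleus model and add controlled spoilers at 5% each:
out-of-focus tiles (blur sigma 9), doublets (two cells in frame), and
debris (dim speckle, no nucleus), so every gate of the chain has something
to reject.

What the generator does **not** emulate: chromatin texture, nucleoplasmic
bridges and nuclear buds, apoptotic morphology, uneven illumination,
overlapping cell clumps beyond the touching-nuclei case, and 3-D structure.
Passing recovery tests therefore demonstrates that the algorithms are
correct and unbiased under this geometry and noise model — not that the
default thresholds transfer to any particular real microscope without
recalibration.

# The microscopy pipeline

Stages and their tunable parameters (`microscopyConfig()`), all in pixels
or dimensionless:

- **Preprocess**: Gaussian smoothing (sigma 1.5) then a 3x3 median filter.
- **Threshold**: global Otsu on the smoothed field, hole filling. One
  threshold pass is shared between nucleus segmentation and MN detection.
- **Declumping**: only components whose area exceeds 1.55x the expected
  nucleus area, or exceed 0.9x with eccentricity above 0.75, are split, by
  a distance-transform watershed inside the component's bounding box with
  h-maxima suppression at 5% of the expected radius. The selective
  triggering keeps single round nuclei untouched and is an order of
  magnitude faster than declumping the whole field.
- **Nucleus filter**: area in [0.3, 3] x expected area, eccentricity <=
  0.92, border-touching objects excluded (partial cells appear in no
  count).
- **Grouping**: nuclei whose expanded regions overlap, whose centroid
  distance is at most 3x the mean equivalent radius, and whose area ratio
  is at most 2 form one cell; 1/2/>=3 members give mono/bi/poly; an
  adjacent pair violating the area-ratio rule marks the group `rejected`
  (confluent cluster), excluded from every count. The expansion distance is
  30 px: the annulus must cover the 1.5-1.9-radius band in which
  micronuclei occur (a 10 px annulus would orphan essentially all of
  them).
- **MN detection**: thresholded components with area in [1/300, 1/9] of
  the expected nucleus area and compactness (perimeter^2 / 4 pi area) <=
  1.6. Because labelling is 8-connected, a spot touching a nucleus belongs
  to the nucleus component and can never be called. The 1/300 floor admits
  the few-pixel caps that the smallest blurred micronuclei leave above the
  global threshold; with the background sitting ~15 standard deviations
  below the threshold after filtering, noise cannot produce a false spot
  (0 false positives across the fixture sets).
- **Assignment**: a call inside exactly one cell's expanded region gets
  that parent; inside several, the nearest nucleus edge wins with ties to
  the lower cell id; polynucleated and rejected parents are treated as
  none. Only mono- and binucleated parents are valid, and frequency
  statistics use binucleated parents only.

All numeric defaults were calibrated once against ground-truthed synthetic
fixtures (class-recovery cross-tabulations and MN sensitivity/false-positive
counts) and then frozen; the tests do not depend on them tightly, and
`microscopyConfig()` exposes every cutoff.

# The flow-style route

`buildMasks()` mirrors the classical instrument-software mask functions:
`threshold` (DNA >= Otsu), `dilate`, `spot` (white top-hat, radius 6,
thresholded at 5% of the dynamic range), `range` (spot components within
the MN area window), `levelset` (intensity region growing refining the
nuclear boundary — same role as a level-set evolution at desk-scale cost),
`nuclear`, and `micronuclei = range AND NOT dilate(nuclear)`, which makes
MN/nuclear disjointness structural.

`computeTileFeatures()` gives every gating parameter an explicit open
definition (the vendor's formulas are proprietary): gradient RMS of the
brightfield Sobel magnitude normalised by mean intensity (focus);
minor/major aspect ratios from unweighted and intensity-weighted second
moments; nuclear-mask area and integrated intensity; lobe count as merged
local maxima of the smoothed DNA channel (sigma 7 — about half a nucleus
radius, so each nucleus carries exactly one dome; maxima closer than one MN
diameter merge); co-occurrence homogeneity (Haralick inverse difference
moment, 8 gray levels, distance 1, 4 directions averaged); minor-axis
extent of the moment-aligned bounding box (width); mask compactness; and
the MN spot count under the same area/compactness rules as the microscopy
route.

`applyGates()` applies the published gate order — focus, lobe count == 2,
brightfield aspect ratio > 0.5, DNA area window, homogeneity/width cut,
and the final aspect-ratio-intensity x compactness box — and histograms the
BNC spot counts into 0/1/2/3 bins (larger counts truncate to 3 with a
warning). The published thresholds 0.5 / 10 / 15 are in the vendor's units;
the package's defaults are on its own feature scales, and
`calibrateGates()` re-fits them by coordinate-wise grid search maximising
balanced accuracy against tile truth labels, deterministically. On held-out
seeds the calibrated chain identifies binucleated cells with balanced
accuracy above 0.95.

# Numerical and statistical choices

- **IC50**: least-squares 4-parameter logistic on log10 concentration,
  multi-started from three fixed initialisations (best SSE wins), bottom
  bounded in [-50, 90] — leaving the lower plateau free avoids the
  truncation bias a bottom >= 0 constraint induces when the top
  concentration only reaches ~2.6x the midpoint. Two IC50 conventions are
  reported: the absolute 50%-of-control crossing (`ic50`, the headline
  value, standard MTT practice) and the 4PL midpoint (`ic50_rel`). Over
  100 seeded simulations at the classical two-fold 9.4-600 ug/mL grid with
  5% noise, recovery bias is below 1% and RMSE about 6%.
- **Group comparison**: one-way ANOVA + Tukey HSD against a named control
  (homoscedastic normal model, as the use of Tukey implies; no Welch
  correction). Type-I error at alpha = 0.05 sits at its nominal level over
  500 null simulations with three replicates per group.
- **MN frequency denominators**: per binucleated cell by default (the
  OECD-consistent convention); per total cells available as an option,
  since both conventions appear in published CBMN reports.
- **Determinism**: every generator takes an explicit seed and restores the
  caller's RNG state; experiment-level streams derive from a master seed
  via a string hash (`childSeed()`), so conditions and replicates are
  independent and order-insensitive. Two runs of `runExperiment()` under
  one master seed produce byte-identical tables.
- **Degenerate inputs**: blank images give empty object sets (not errors);
  an infeasible packing, a zero denominator, an all-plateau dose-response
  and single-class calibration labels raise explicit errors.

# Problem sizes

The recovery checks in the test suite score roughly 1000+ binucleated
cells per condition (three seeded replicates of 1800 x 1800 px fields at
100 cells per untreated field) for the frequency endpoints, the protocol's
minimum of 1000 binucleated cells per replicate for the antigenotoxicity
contrast, and 4000-6000 tiles per condition for the flow-route contrasts;
`scripts/acceptance.R` uses the same design with slightly larger field
counts. These sizes put the binomial sampling error of each recovered
quantity comfortably inside its comparison band while keeping a full run
on a single CPU in the tens of minutes.

# Known limitations

- Nucleation classes beyond three nuclei are not generated, and rejected
  (confluent) groups are simply excluded, as in the emulated design.
- The expansion-based cell model has no membrane evidence; at high
  confluency real cytoplasm boundaries would not be annular, and the
  area-ratio rejection rule only approximates the visual "doubtful case"
  criterion.
- MN frequencies are recovered per condition; the package does not model
  donor/run random effects, so its ANOVA treats replicates as exchangeable.
- The flow-route features are open re-definitions, not the vendor's; their
  absolute values are not comparable to instrument exports without
  `calibrateGates()`.
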