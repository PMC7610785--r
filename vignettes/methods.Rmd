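---
title: "Methods: quantifying deuterium-labelled EV uptake in Raman hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying deuterium-labelled EV uptake in Raman hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanev)
```

## The measurement model

A confocal Raman image is a cube of spectra: at each of H×W pixels
(0.5 µm sampling by default) the instrument records intensity over B
wavenumber bins, here 0–3700 cm⁻¹ at 11 cm⁻¹ spacing (337 bins). Each
pixel spectrum is modelled as

  signal(ν) = Σ_c m_c · s_c(ν) + g · b(ν) + s₀(ν) + a · d(ν) + ε(ν)

where `s_c` are subcellular component signatures (sums of Gaussian peaks)
gated by spatial masks `m_c`, `b` a slowly varying autofluorescence
baseline with a smooth spatial scale `g`, `s₀` a spatially uniform system
background (substrate, buffer, optics), `d` the C–D band of a deuterium
label centred at 2140 cm⁻¹, `a` its per-pixel amplitude (nonzero only at
EV deposits), and `ε` zero-mean Gaussian noise per bin. EVs (~120 nm) are
far below the pixel size, so a deposit is modelled as one pixel (or a few
adjacent pixels for a cluster), not an extended object.

The pipeline inverts this model in four fixed steps, in this order:

1. **Crop** to 400–3600 cm⁻¹ (drops the laser line and detector edges;
   the low cutoff is configurable because instruments differ).
2. **'Shape' baseline removal** — the `g·b` term. The baseline estimate is
   the morphological opening (erosion, then dilation, with a flat
   structuring window of 500 cm⁻¹) of the spectrum, smoothed with the same
   window. Peaks narrower than the window survive subtraction; trends
   broader than it are removed. `corrected + baseline` reconstructs the
   input exactly.
3. **Area normalisation** — each pixel spectrum scaled to unit trapezoidal
   integral, making pixels comparable for imaging despite focus and
   density variation. All-zero pixels are flagged, not scaled.
4. **System background subtraction** — the `s₀` term: the mean spectrum of
   cell-exterior pixels is subtracted everywhere. The exterior mask is
   derived automatically (Otsu on the whole-cell C–H band of the corrected
   cube, dilated 2 px) unless supplied.

## Numerical choices in the baseline filter

Two refinements around the opening proved necessary and are standard for
morphological (rolling-ball-type) baseline estimators:

- **Pre-smoothing (5 bins ≈ 55 cm⁻¹)** before the erosion. A raw erosion
  tracks individual noise minima, which skews the corrected noise to the
  right and roughly triples the false-positive rate of any k·SD detection
  threshold downstream. The baseline is still subtracted from the *raw*
  spectrum, so reconstruction stays exact.
- **Per-spectrum linear detrend** around the opening. A flat structuring
  element run over a slanted background bulges under peaks (the erosion
  minimum lands beyond the peak at a cost set by the local slope), which
  cost up to ~6% of peak area on realistic slopes. Removing the
  least-squares line first and adding it back afterwards reduces peak-area
  errors to below 1.5% for peaks with FWHM under shape_size/5 on
  polynomial baselines up to order 3.

Residual ripple of the filter is of order 10⁻² of the baseline amplitude;
it is the accuracy floor for all "noise-free" statements below.

## Two branches: imaging units vs amplitude-faithful units

Per-pixel area normalisation is right for *display* but wrong for
*quantification*: a cell-interior pixel (large total area: cell + background)
is scaled down more than an exterior pixel (background only), so normalised
intensities are not proportional to planted amplitudes across pixels. The
pipeline therefore keeps two products of the same preprocessing run:

- the **normalised, background-subtracted cube** — used for univariate
  band images, composites, and extracted spectra (and hence PCA);
- the **corrected, background-subtracted but unnormalised cube**
  (`quant_cube` attribute) — used for deuterium detection and the
  inside/outside signal partition, where intensity proportionality is the
  point.

With normalisation inside the quantification path, a planted 80% inside
fraction is systematically recovered several points low; with the
amplitude-faithful branch it is exact up to filter ripple.

## Detection, distances, partition

- **Segmentation**: Otsu threshold on the min–max-scaled whole-cell
  (2800–3000 cm⁻¹) map, binary closing (radius 1), largest connected
  component, hole filling. The membrane is the 8-connected boundary of the
  mask. The recipe is a deliberate design choice; it is exposed rather than
  hard-wired into the science.
- **Detection**: a pixel is deuterium-positive if its 2025–2275 cm⁻¹
  band integral exceeds the exterior mean by more than k·SD of the
  exterior, k = 3 (the conventional 3-sigma rule; no instrument threshold
  exists to inherit). If the exterior SD is exactly zero (noise-free
  data), the threshold falls back, with a warning, to the 0.999 exterior
  quantile. The pipeline's default additionally prunes *isolated*
  positives (no positive 8-neighbour): real deposits at 500 nm sampling
  are clusters of adjacent pixels, so single-pixel exceedances are almost
  surely noise. The raw detector (no pruning) is available and is what the
  single-pixel recovery tests exercise.
- **Distances**: exact Euclidean centre-to-centre distance from each
  positive pixel to the nearest membrane pixel, in µm, signed + inside /
  − outside / 0 on the membrane. Computed by direct search (no grid
  approximation); the tests hold it to exact agreement with a brute-force
  double loop on hundreds of random masks.
- **Partition**: inside percentage = Σ map over positive pixels with
  signed distance ≥ 0, over Σ map on all positive pixels; membrane pixels
  count as inside ("associated with" the cell). Undefined splits (no
  positives, or non-positive total) are flagged, never silently zeroed.

## Trapping ratios

Per-vesicle deuteration is I(2140)/I(1440), each intensity the maximum
corrected value within ±15 cm⁻¹ of the nominal position — a window, not a
single bin, because an 11 cm⁻¹ grid rarely lands on the band centre.
Numerators at or below a noise floor (3·SD of signal-free silent-region
bins, 1800–2000 and 2300–2500 cm⁻¹) report 0: no detectable deuterium.
Non-positive denominators flag the record as undefined. The local-maximum
estimator has a small positive bias under noise (the max of several noisy
bins); at the generator's default peak widths (C–H σ = 15, C–D σ = 20
cm⁻¹) and noise (1% of the C–H amplitude) the bias stays within
sampling error at n = 200. Hypothesis testing across time-point cohorts is
deliberately out of scope; cohort summaries report n, mean, SD and a
seeded bootstrap percentile CI only.

## PCA

Mean-centred, no variance scaling (spectra are already area-normalised),
computed by SVD. Signs are fixed by making each loading's
largest-magnitude element positive, so scores and plots are reproducible
run to run. Cohort separation is |Δmean| / pooled SD on PC1. Identical
inputs yield zero explained variance, not an error.

## What the phantom generator emulates — and what it does not

The generator produces: an elliptical cell with nucleus, nucleoli, lipid
droplets and cytoplasmic protein signature; a polynomial (order 3)
autofluorescence baseline with a broad hump and ±10% smooth spatial
gradient; a uniform system background whose bands (1150, 1795,
3300 cm⁻¹) deliberately avoid both the silent region and all component
band windows; planted EV deposits with known placement (inside / membrane /
outside), amplitude, and optional 2-pixel clustering; i.i.d. Gaussian bin
noise. All randomness flows from one explicit seed; identical parameters
give bit-identical cubes.

Default conditions (chosen once, as realistic for fixed cells on an MgF₂
substrate, and then left alone): 48×48 px field at 0.5 µm/px, component
amplitudes ~1, baseline amplitude 2, system amplitude 1, noise SD 0.05,
EV amplitude 0.5 (amplitude SNR 10; the detection experiments use noise
0.1 for SNR 5), C–D width σ = 30 cm⁻¹ in-cell.

Not emulated: optical point-spread and confocality, cosmic rays,
wavenumber calibration error, signal-dependent (shot) noise beyond the
optional mode, spectral crowding between components, and cell-to-cell
biological variability. Passing tests therefore demonstrate the
*computational* correctness and calibration of the pipeline under its
stated model, not robustness to every instrumental artefact of real data.

## Degenerate inputs and tie-breaks

All-zero spectra: flagged empty, returned unchanged. Constant whole-cell
maps: segmentation refuses. Empty exterior masks: error. Exterior SD = 0:
quantile fallback with warning. No positive pixels: partition and report
flagged, extraction returns an empty result with a warning. FWHM windows
that never fall below half height: width capped at the window; window
maxima at the edge handled by edge crossings. Two equal-size components in
segmentation: `which.max` keeps the first (deterministic).

## Problem sizes

The test-suite and acceptance experiments use 48×48×337 phantoms (20 of
them for detection calibration), 200 trap spectra per cohort, 200 random
masks for the distance oracle, and 60 spectra for the PCA separation —
sizes at which every statistical check has comfortable power while a
full run of the suite stays around two minutes.

## Known limitations

- The "shape" filter's window (500 cm⁻¹) is interpreted as a wavenumber
  width; the original commercial filter's parameter is undocumented, so
  absolute agreement with vendor software is not claimed.
- Peak areas degrade (beyond ~5%) for peaks wider than about a fifth of
  the filter window or on backgrounds with strong curvature at the window
  scale.
- The inside/outside partition attributes each pixel wholly by the sign of
  its membrane distance; partial-volume effects at the membrane are not
  modelled (membrane pixels count as associated).
- The local-maximum ratio estimator is positively biased at very low
  signal-to-noise; below the noise floor it reports 0 by design.
- Z-stacks are processed per slice with pooled statistics; no volumetric
  rendering or 3D connectivity is attempted.
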