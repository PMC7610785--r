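# ramanev

Imaging and quantification of deuterium-labelled extracellular vesicles
(EVs) in Raman hyperspectral images of cells.

EVs are ~120 nm lipid-bilayer vesicles that cells secrete and take up.
Because their composition mirrors their parent cells, they are nearly
invisible to label-free imaging once internalised. Growing parent cells on
deuterated nutrients (D₂O, deuterated choline or glucose) replaces C–H
bonds with C–D bonds, whose stretch vibrations near 2140 cm⁻¹ fall in the
Raman *silent region* (1800–2800 cm⁻¹) where no endogenous biomolecule
scatters. Labelled EVs can then be located inside unlabelled cells directly
from hyperspectral Raman images, and their uptake quantified.

`ramanev` is the full computational side of that experiment, for
spectroscopists and cell biologists working with confocal Raman microscopes
(or wanting to test such pipelines without one):

- **Preprocessing** of H×W×B image cubes: cropping, a morphological
  "shape" autofluorescence filter (opening with a flat 500 cm⁻¹ window,
  smoothed), area-under-curve normalisation, and system background
  subtraction from cell-exterior spectra.
- **Univariate band imaging** with the standard subcellular windows —
  nuclei 775–805, nucleoli 985–1015, lipids 1425–1485, proteins 1635–1685,
  deuterium 2025–2275, whole cell 2800–3000 cm⁻¹ — each map the per-pixel
  trapezoidal integral over the window, plus a deuterium FWHM metric
  (sharper C–D peak ⇒ greater relative deuterium content; the width
  `window/FWHM` score rises with content).
- **Single-EV trapping analytics**: per-vesicle deuteration as the ratio
  of peak intensity at 2140 cm⁻¹ (C–D) to 1440 cm⁻¹ (C–H), with cohort
  summaries and bootstrap CIs.
- **Uptake quantification**: Otsu segmentation of the cell from the
  whole-cell band, mean + 3·SD detection of deuterium-positive pixels
  against cell-exterior statistics, signed Euclidean distance of each
  positive pixel to the nearest membrane pixel (positive inside, negative
  outside, 0 on the membrane), and the intensity-weighted percentage of
  deuterium signal inside vs outside the cell.
- **Chemometrics**: mean-centred PCA (via SVD, deterministic sign
  convention) of extracted deuterium-positive spectra, with a
  standardised-mean-difference separation statistic on PC1.
- **Synthetic data**: hyperspectral cell phantoms (subcellular components,
  polynomial autofluorescence, system background, planted sub-resolution EV
  deposits with known placement and amplitude) and trap spectra with
  programmed ratios, so every stage is testable against ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R     # phantoms + trap spectra -> results/data
Rscript analysis/04_uptake.R       # full uptake quantification
```

simulates three cell phantoms — EVs planted deep in the cytoplasm
(`internalised`), at the membrane (`surface`), and mostly off-cell
(`low`) — and prints:

```
       cell_id       cohort n_positive pct_inside pct_outside
1 internalised internalised         14      85.86       14.14
2      surface      surface         15      74.05       25.95
3          low          low         10      20.03       79.97
  median_distance_um no_deuterium_signal
1              2.708               FALSE
2              0.000               FALSE
3             -3.384               FALSE
```

Read: in the internalised phantom, 14 deuterium-positive pixels were
detected and 85.9% of the deuterium intensity lies inside (or on) the cell,
with a median signed membrane distance of +2.7 µm (deep in the cell); the
surface cohort sits at the membrane (median 0 µm); the low-uptake cohort is
dominated by exterior signal (negative median). Both orderings match the
planted ground truth. `analysis/03_trapping.R` likewise recovers programmed
C–D/C–H ratios of 0 / 0.3 / 0.5 as cohort means 0.0003 / 0.2995 / 0.4996,
and `analysis/05_chemometrics.R` separates internalised from surface-bound
deuterium spectra on PC1 by ~50 pooled SDs with the PC1 loading peaking at
2138 cm⁻¹, inside the C–D window.

The same computations are available directly, e.g.:

```r
library(ramanev)
axis <- make_axis(0, 3700, 11)            # the 337-bin instrument grid
sim  <- simulate_cell_cube(phantom_spec(n_inside = 5, seed = 1), axis)
rep  <- quantify_uptake(sim$cube)         # segment, detect, distances, split
rep$pct_inside; rep$distances
```

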