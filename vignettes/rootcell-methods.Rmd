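---
title: "Methods: how rootcell measures root cross-section anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how rootcell measures root cross-section anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A transverse section through a young cereal root is a set of concentric
tissue cylinders: epidermis, exodermis and a dense sclerenchyma band on the
outside; several cortical cell layers; and a stele (vascular cylinder)
bounded by the pericycle and containing the metaxylem vessels, with one to a
few large central metaxylem vessels near the axis. Under UV epifluorescence
the cell walls autofluoresce, so the informative signal is a network of
bright curves on dark tissue. The package reduces such an image to ten
numbers: four measured areas (root, stele, central metaxylem, cortex), two
derived areas (external layers, cortex proper), two vessel counts, a layer
count and a set of per-file cell counts.

Two structural assumptions underlie everything: (i) one root per image,
roughly centered, not truncated by more than one image border; (ii) walls are
locally the brightest structures at their radius (for bright-field images the
polarity is inverted on load, restoring this).

## Area measurements

Every selection starts from the fixed preprocessing chain: grayscale
conversion (standard luminance weights for RGB), Gaussian filter, linear
percentile contrast stretch, threshold, and a morphological closing to smooth
the selection ("enlarge then decrease"). The automatic threshold maximizes
the between-class variance over all 255 possible 8-bit cuts (Otsu); when a
range of cuts ties — the histogram has an empty gap between classes — the
midpoint of the tied range is used, which places the cut centrally in the gap
instead of hugging the lower mode. A manual override is available per image,
mirroring the supervised usage the tool descends from.

- **Root**: largest connected foreground component, holes filled, closed.
  Rejected if empty or touching two or more borders (truncated section).
- **Stele**: the stele boundary itself is rarely separable by threshold, so
  the stele is modelled as an oval: an ellipse centered at the root centroid
  whose orientation and axis ratio come from the root mask's second central
  moments, sized so that root area / stele area equals the `stele_proportion`
  parameter (default 4, the conventional value for these sections; for a
  circular root this is a concentric disk). An ellipse escaping the root is
  shrunk 2% per step until contained, with a warning.
- **Central metaxylem**: inside the stele (eroded by 4 px so the pericycle
  wall cannot interfere), the *unsmoothed* contrast-enhanced image is
  re-thresholded on stele pixels only; components are closed, hole-filled and
  kept if area ≥ `min_cmx_area` (80 px) and circularity 4πA/P² ≥ 0.5.
  Thresholding the unsmoothed image matters: vessel walls are only ~2 px
  thick, and a tissue-scale blur flattens the wall ridge so far that the
  filled disc inflates by over 20%. Pixel noise is absorbed by the closing
  and the size/circularity filters instead. `manual_ncm` overrides the count;
  the peripheral metaxylem count `NM` is user-supplied only (`manual_nm`) and
  reported as missing — never zero — when absent.
- **Cortex**: in polar coordinates about the stele centroid, each angle's
  outermost strong band of radial thickness ≥ 4 px within the outer 35% of
  the local root radius is taken as the sclerenchyma; the cortex boundary is
  the band's inner edge, median-filtered over angle (width 9). A band
  qualifies only if the window's Otsu cut exceeds 1.25× the window median —
  otherwise the annulus holds no bright band at all and the selection falls
  back to the root eroded by a nominal external-layer thickness (20 px), with
  a warning (also triggered when more than 25% of angles lack a band).

Derived areas are exact subtractions: `ELA = ROOTA − cortex_measured`,
`CTXA = cortex_measured − STELEA`; with a spatial calibration `c` (µm/px)
each area is scaled by `c²`.

## Counting in polar coordinates

The image (Gaussian-smoothed, contrast-enhanced, polarity-normalized) is
resampled about the stele centroid into a (radius, angle) grid — 1 px radial
step, 720 angular samples (0.5°) by default, bilinear interpolation — so the
stele sits at the top and the epidermis at the bottom. Counting is strictly
1D: maxima of intensity profiles, where a maximum is a sample (or plateau,
reported at its center) strictly above its neighbors whose *prominence* — its
height above the higher of the two bounding minima reachable without crossing
a larger value — is at least the `noise_tolerance` (default 20 of 255; raise
to ~30 for noisy material). At the ends of a non-periodic profile the missing
side is waived; full-circle profiles are treated circularly with the seam
counted once.

**Layers.** `n_layer_lines` (default 3) radial lines span from just inside
the stele boundary into the sclerenchyma band. A span crossing *k* layers
crosses *k* + 1 periclinal walls, so the per-line count is `maxima − 1`
(exposed as `layer_offset`); `NCL` is the mean, possibly fractional. Two
placement refinements replace the supervision of the original workflow, both
deterministic in `rng_seed`: candidate angles near each evenly spaced anchor
are scored by mean profile intensity and the cleanest is used (a line running
along an anticlinal wall has an elevated baseline that fills in the saddles
between wall maxima); and each profile is truncated at the outermost
attainment of its maximum, so the sclerenchyma band — whose descent may be
cut anywhere by the ±2 px jitter of the cortex boundary — always registers as
a terminal maximum rather than a truncated shoulder with spurious low
prominence.

**Cells per file.** File radii are the midpoints between consecutive
periclinal walls (averaged over the lines that found the modal wall count),
outermost first, up to `n_cell_files` (default 6); explicit radii in the
configuration override this. Each file's full-circle angular profile is
counted periodically — one anticlinal wall per cell. A partial span of
coverage `c` is counted non-periodically and extrapolated as
`round_half_up(raw / c)`; coverage 1 is the identity by construction.

# The phantom generator

`generate_phantom()` renders the concentric anatomy with exact ground truth:
tissue rings bounded by bright periclinal walls (drawn just inside each
boundary radius), a dense sclerenchyma annulus, cortex layers subdivided by
anticlinal walls with ±10% angular jitter, and bright-walled vessel rings;
then seeded Gaussian noise, clipped to 8 bits. Bright-field phantoms are the
inverted rendering (inversion before noise). Ground truth comes from the same
rasterized label map used for rendering — not analytic formulas — so
segmentation accuracy is tested free of rasterization bias. Defaults model a
6-day-old cereal radicle at roughly 0.5 µm/px: root radius 120 px, stele at
half the root radius (the proportion-4 convention), sclerenchyma at 5/6 of
the root radius, walls 220 / tissue 60 / background 10.

`phantom_suite()` draws reproducible batches: root radius 80–160 px, 3–6
cortex layers, 12–64 cells per file, 1–4 central vessels, noise σ 0–15. Two
couplings keep the draws anatomically plausible: the layer count is capped at
`floor(radius / 24)` so each layer is at least ~8 px (about one cell) deep —
cortical cell depth is roughly constant, so only thick roots carry many
layers — and multi-vessel configurations cap the vessel radius by stele size
(several large central vessels occur in thick-rooted material).

What the phantom does *not* emulate: uneven illumination, section damage and
folds, out-of-focus blur gradients, photorealistic texture, multiple roots
per frame. Passing the phantom tests therefore demonstrates the correctness
of the geometry, counting and bookkeeping under realistic contrast and noise,
not robustness to every acquisition artifact; real material with poor
contrast is expected to need the per-image overrides (threshold, noise
tolerance, manual counts) that the batch configuration provides.

# Numerical conventions and degenerate inputs

- Rounding is half-up everywhere (counts, extrapolation, quantization).
- Coordinates are 1-based (row, col), origin top-left, the R convention,
  also in the ROI JSON. Angle 0 points along +col and increases
  counter-clockwise.
- Areas are foreground pixel counts; 16-bit inputs are min–max rescaled to
  8 bits on load; polar samples outside the source image are 0.
- Equal-area largest-component ties break toward the smaller centroid row,
  then column. All randomness (line placement, phantom jitter/noise) derives
  from explicit integer seeds; identical inputs give bit-identical outputs,
  including the TSV/JSON files of a batch run.
- Degenerate cases: an all-foreground/background threshold flags a warning
  carried downstream; a blank image aborts that image (the batch continues,
  exit status 2); a layer line with no maxima is excluded with a warning, and
  the run aborts only if every line is excluded; fewer candidate file radii
  than requested yields a shorter `NCF` vector plus a warning.

# Problem sizes used by the test suite

The suite validates on 512×512 default phantoms, a 20-phantom seeded suite
(384×384) for area recovery, 100 seeded noisy phantoms (noise σ 10,
tolerance 30) for count robustness, and 1000 random profiles against a
brute-force prominence oracle; the whole suite runs in about a minute on one
core. These sizes were chosen to exercise the full parameter ranges of the
generator while keeping the suite fast enough to run on every change.

# Known limitations

- One root per image; no oblique or longitudinal sections.
- The stele is an assumed oval tied to the proportion parameter, not a
  segmented boundary; varieties deviating from the proportion need the
  parameter adjusted per batch.
- Cell files are counted, not segmented; there is no per-cell 2D geometry.
- File identities (exodermis vs. successive cortex files) are positional
  (`NCF1..k`, outermost first); naming them is left to the analyst or the
  configuration.
- `NM` has no automatic detector in this version; it is a pass-through of
  the user's count.
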