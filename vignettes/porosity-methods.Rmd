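---
title: "Dual-resolution CT porosity analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-resolution CT porosity analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroct)
```

## The measurement model

Apple parenchyma is a two-phase medium at CT resolution: liquid-filled cells
and cell-wall material on one side, gas-filled intercellular space on the
other. Reconstructed CT attenuation (stored as signed 16-bit grey values)
mixes the two phases linearly within a voxel, so the gas volume fraction —
the *porosity*, in percent — is an affine function of grey value. `poroct`
anchors that line at two physical references: fruit juice, which contains no
gas (0% porosity), and open air (100%). With the shipped reference pair
(juice at grey 49, air at grey −1007) the model is

$$\phi(g) = \frac{100\,(g - g_{\text{juice}})}{g_{\text{air}} - g_{\text{juice}}}
         = -0.0947\,g + 4.64 \;\;[\%].$$

The model is fitted by `fit_two_point()` and deliberately **unclamped**:
voxels denser than juice (seeds, stone cells) map to negative porosity and
stay diagnosable. Clamping to $[0, 100]$ is an explicit option of
`apply_calibration()` and is on by default for reporting maps. One grey unit
corresponds to $100/1056 \approx 0.095$ porosity points, which is the
quantization floor of everything downstream.

Assumptions worth stating: the scanner's rescale header has already been
applied (the DICOM reader does this per file); beam hardening and scatter
are not corrected; the anchors are cultivar- and scanner-specific, which is
why they are configuration values rather than constants.

## Macro scale: fruits and regions

`segment_fruits()` separates tissue from background air with a histogram
(Otsu) threshold, fills internal holes — gas-filled cavities belong to the
fruit extent — labels 26-connected components, and discards components below
`min_volume_mm3` (default 500 mm³, far below any real fruit but above
speckle). Because Otsu *always* finds a split, an automatic threshold is
additionally required to separate classes by at least `min_contrast`
(default 100 grey units, about one tenth of the juice–air distance);
an air-only scene therefore reports "no fruit" instead of segmenting noise.

`classify_regions()` assigns each fruit voxel to an anatomical region by
porosity band: seeds 0–10%, core 5–15%, cortex 15–30%, cavities at or above
`cavity_min` (default 90%, tolerant of noise and partial-volume voxels; an
exact 100% band would miss most real cavity voxels). Three numerical choices
matter:

* **Smoothing.** Bands are applied to a local ball average (default radius
  1 mm) restricted to the fruit mask, so the labels are not salt-and-pepper
  under voxel noise and background air does not bleed into surface voxels.
* **Seed/core overlap.** The seed and core bands overlap in 5–10%. The
  package gates seed/core eligibility by normalized radial position
  (`inner_fraction`, default 0.35 of the fruit's equivalent radius — seeds
  and core are central structures), and inside the gate resolves the overlap
  toward the nearer band midpoint.
* **Unassigned voxels** (e.g. smoothed values between the cortex band and
  the cavity threshold) take the label of the nearest assigned voxel of the
  same fruit, by multi-source breadth-first search, so the regions always
  partition the mask. That partition is asserted in the tests, and
  whole-fruit porosity equals the voxel-weighted mean of the regional means
  to numerical precision.

Whole-fruit porosity **includes cavity voxels by default**: the cavity is
internal air space and the band structure puts whole-fruit means near the
top of the tissue band, consistent with how whole-fruit values in the
20–30% range arise from cortex values around 22–26%. `include_cavity =
FALSE` is available for tissue-only means.

Line profiles use trilinear interpolation between voxel centres — the
standard choice for anisotropic medical volumes; voxel centres sit at
$(i - \tfrac12)\,h$ so a volume spans $[0, nh]$ mm per axis.

## Micro scale: cells and pores

High-resolution ROIs (0.5 mm cubes at 6.6 µm voxels, ~76 voxels per edge)
contain three grey phases: air-filled pores (dark), the cell-wall/juice
matrix, and cell interiors (bright). After contrast enhancement
(`percentile_stretch`, a monotone map of the 1st–99th percentile range onto
$[0,1]$, which provably preserves Otsu class order; CLAHE is available as
`adaptive_equalize`), `detect_blobs()` binarizes and splits objects:

* **Thresholding.** A single two-class Otsu threshold cannot serve both
  polarities on a three-phase image — whichever gap it picks, one polarity
  ends up merged with the matrix. The package therefore adds a two-threshold
  (three-class) Otsu mode, `multi_otsu`, with dark = below the lower
  threshold and bright = above the upper. It is the default in
  `analyze_roi()` and the right mode for cellular ROIs; plain `otsu` remains
  the default in `detect_blobs()` for two-phase images, and `fixed` takes an
  explicit cut.
* **Splitting.** Touching objects are split by a marker-based watershed
  (priority flood) on the exact Euclidean distance transform, with
  anisotropic spacing support. Markers are distance local maxima, collapsed
  over plateaus and greedily suppressed so that surviving markers are at
  least the minimum admissible diameter apart *within each connected
  component* — every component keeps its global maximum, so no object can
  vanish.
* **Morphometrics.** Each object is summarized by its equivalent-sphere
  diameter $d = 2\,(3 V / 4\pi)^{1/3}$. Objects outside the admissible
  diameter range are dropped as speckle or unsplittable clumps; objects
  touching the ROI boundary are kept but flagged. Mean diameters use
  interior objects only; cell counts half-weight boundary objects (unbiased
  to first order for convex objects, and simpler than a guard zone in a
  76-voxel cube); the pore volume ratio uses all pore voxels including
  boundary objects, and ROI porosity is 100 × that ratio.

The sunny/shady comparison (`paired_position_test()`) is a per-metric paired
two-sided t-test, reported as sunny − shady. A planted positional offset of
+1.71 is interpreted as **percentage points** of porosity, not relative
percent. Identical arms (all differences zero) and metrics constant in both
arms yield an `NA` p-value marker rather than an error.

## The composite quality index

Traits are standardized with the **population** standard deviation
(`zscore()`, divisor $n$; the sample divisor is available), PCA is run on
the standardized matrix (`quality_pca()`), and component signs are fixed so
each component's largest-magnitude loading is positive — PCA signs are
otherwise arbitrary and would break reproducibility. The index is
$Q = \sum_i w_i z_i$ with weights derived from the loading structure. The
weight rule is one concrete reading of "higher weights for stronger
loadings": $w_i \propto \sum_{j \le k} |l_{ij}| \cdot \mathrm{varfrac}_j$
over the first $k = 2$ components, normalized to sum to one; a
`pc1_only` strategy ($w_i \propto |l_{i1}|$) is provided as an alternative.
Weights are nonnegative by construction; whether negative weights should be
allowed is genuinely open, and the nonnegative choice keeps $Q$ monotone in
every trait's z-score. Because z-scoring removes location and scale, $Q$ is
invariant under affine rescaling of any raw trait column (asserted to
1e-9).

Groups for the radar chart follow loading dominance with a margin
(`assign_groups()`, default 0.2): PC1-dominated traits form group A,
PC2-dominated traits group C, and traits with comparable loadings group B.
`radar_export()` min–max scales per-treatment trait means to $[0,1]$ across
levels and orders axes A, then B, then C, alphabetical within a block;
a trait with equal means across levels cannot be scaled and is exported as
0 with a `degenerate` flag.

## What the synthetic generators emulate — and what they do not

All validation runs on synthetic phantoms with exact ground truth, because
the package's claims are about *recovery*: simulate known structure, run the
full pipeline, compare.

**Fruit phantoms** (`make_fruit_phantom()`) are axis-aligned ellipsoids
(default semi-axes 17 × 15 × 15 mm — a scaled-down fruit that fits a 128³
grid at the low-resolution spacing of 0.5 × 0.339 × 0.339 mm) with a core
cylinder, a ring of five seeds, a ring of five cavity lobes, and cortex
elsewhere; per-region porosity (defaults 5 / 10 / 22 / 100%) plus Gaussian
intra-region jitter (SD 1 point — enough to exercise the smoothing in
region classification without swamping the bands). `target_whole_mean`
re-solves the cortex porosity from the voxelized region volumes so the
volume-weighted mixture hits a requested whole-fruit mean exactly; the
solved value must stay inside the cortex band. The forward model
(`porosity_to_grey()`) inverts the calibration, adds Gaussian grey noise
(σ = 10 grey units in the validation runs, about 1% of the juice–air
range), rounds and clamps to int16. Not emulated: partial-volume surface
voxels, beam hardening, reconstruction artifacts, anatomical asymmetry. A
passing recovery therefore shows the *pipeline arithmetic* is right under
realistic noise, not that segmentation is robust to scanner artifacts.

**Cell phantoms** (`make_cell_phantom()`) place non-overlapping spheres
(cells; diameter ~ N(69, 2²) µm) by random sequential adsorption into a
0.5 mm cube at 6.6 µm voxels, fully interior by default, until a target
packing fraction (default 0.30) or an exact count is reached. Interior-only
RSA saturates near packing 0.29 in this geometry, so a run that reaches 90%
of the target volume is accepted and the achieved fraction is reported; a
shortfall beyond that is an error. Dark pore spheres (diameter ~ N(40, 8²)
µm) are then placed in the interstitial space — they may overlap each other
(real intercellular channels are connected networks), never cells — until
the painted pore voxel count reaches the target porosity (default 0.20 of
the cube), so the true pore volume is exact under overlap. The remaining
interstice is a juice-like matrix at an intermediate grey (defaults: cells
300, matrix 49, pores −1007, noise σ = 30). RSA spheres are not a
biological tessellation: cell shape, wall thickness and anisotropy are out
of scope, so diameter/density recovery validates the detector, not
parenchyma realism — the reported parenchyma cell density and diameter
would imply a packing fraction below 0.3, which the generator treats as an
explicit parameter rather than a derived truth.

**Quality tables** (`make_quality_table()`) draw two standardized latent
factors per sample; group-A traits load on factor 1 (0.92), group-C on
factor 2 (0.72), group-B on both (0.62 / 0.42). Treatment levels shift the
factor means (effect patterns are orthogonal across levels so treatments do
not correlate the factors), and residual noise brings every trait to unit
variance, so the planted loadings live on the correlation scale that PCA of
z-scores sees. Two design details keep the planted groups identifiable:
group-B traits alternate the sign of their factor-2 loading (identical
signs would form a coherent "bridge" direction and the leading components
would rotate ~45° toward a general factor), and group-C traits carry a
small compensating factor-1 loading that cancels the residual coupling from
the odd number of B traits. The planted asymmetry (factor 1 > factor 2)
mirrors a two-component structure with PC1 near 45% and PC2 near 25% of
variance. The `truth` attribute carries the planted groups, factor scores
and the top-2 eigenvalue fractions of the population correlation matrix
implied by the construction.

## Problem sizes and determinism

The shipped validation uses: a single 128³ fruit scene (~2.1 M voxels,
~280 k fruit voxels) for macro recovery; 0.5 mm / 6.6 µm cell phantoms
(76³ ≈ 440 k voxels, ~215 cells) for micro recovery; 9 phantom pairs for
the positional comparison, with the 100-replicate significance check run at
the metric level (the paired test consumes per-ROI metrics, and the planted
offset plus pair noise fully determine their distribution); 1000 null
simulations for the ANOVA type-I rate; and 20 seeds for the quality-group
recovery. Unit tests use coarser 64³ fruit phantoms and 0.3 mm cell cubes.

Every generator is bit-deterministic given its seed: seeded draws run under
a scoped RNG that saves and restores the caller's `.Random.seed` (forcing
the seed argument first, so a caller may compute seeds from the outer
stream). The pipeline summary JSON contains the seed and a configuration
hash but no timestamps, so identical runs produce byte-identical summaries.

## Known limitations

* No real scans ship with the package; all quantitative claims are
  parameter-recovery claims on phantoms.
* The DICOM reader supports uncompressed, single-frame, Explicit VR
  little-endian series only — exactly what the bundled writer produces and
  what reconstructed CT series commonly use. Compressed, multi-frame or
  sequence-bearing files are rejected.
* Region classification assumes centrally located seeds/core and
  band-separable tissue; fruits with atypical porosity profiles would need
  re-tuned bands.
* `adaptive_equalize` operates slice-wise (2D CLAHE per slice), not as a
  true 3D adaptive equalization.
* Blob splitting relies on distance-transform geometry; heavily non-convex
  cells would be over-split.
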