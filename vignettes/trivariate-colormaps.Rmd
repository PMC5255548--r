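---
title: "Tri-variate CIELAB color coding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-variate CIELAB color coding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trivarmap)
```

## The visualization model

Three co-registered parametric maps, each normalized to $[0,1]$, are
treated as coordinates $(u, v, w)$ in a unit cube. A tri-variate color
map assigns a CIELAB color to every cube point by trilinear
interpolation of eight anchor colors at the corners, and each image
pixel is painted with the color of its coordinate triple.

Working in CIELAB is the load-bearing assumption: CIELAB is calibrated
so that the Euclidean distance

$$\Delta E_{76} = \sqrt{(\Delta L^*)^2 + (\Delta a^*)^2 + (\Delta b^*)^2}$$

approximates the perceived difference between two colors. Linear
interpolation **in CIELAB** (not in display RGB) therefore keeps the
mapping from signal changes to perceived color changes approximately
linear everywhere in the cube. We use the plain CIE76 distance rather
than CIEDE2000 throughout, because the method's contrast statistic is
defined as the Euclidean distance in CIELAB and the interpolation is
linear in exactly that metric; mixing in a non-Euclidean formula would
break the correspondence between the two.

The `"equal_lightness"` anchors obey three constraints:

1. black $(L^*{=}0,a^*{=}0,b^*{=}0)$ at $(0,0,0)$ and white
   $(100,0,0)$ at $(1,1,1)$ are the extreme points of the map;
2. the six chromatic anchors lie on the $L^* = 50$ plane, so hue — not
   lightness — discriminates *which* channels are elevated, while
   lightness encodes overall signal;
3. the convex hull of the anchors should be large, so the map spans
   many discriminable colors. `validate_colormap()` reports this hull
   volume (computed exactly over the 8 anchors); it is reported, not
   optimized — anchor placement is taken as given.

Under the sRGB/D65 interpretation of the published anchor hex codes
the six chromatic anchors have $L^*$ between roughly 51.2 and 52.2.
The validation tolerance is $|L^* - 50| \le 5$: wide enough to absorb
the difference between RGB working-space conventions (see below),
narrow enough that a genuinely unbalanced map such as the
`"full_spectrum"` preset fails it.

### Rotation

Which channel drives which hue is arbitrary, so the cube may be
"rotated": any permutation of the three axes combined with per-axis
inversions (the discrete symmetries of the cube that keep the
black–white diagonal fixed as a set). This is implemented as corner
re-indexing, which is algebraically identical to evaluating the
original map at transformed coordinates but keeps corner lookup and
corner-fidelity trivially exact. A continuous rotation is deliberately
not offered: reassigning channels to hues only requires the discrete
group, and arbitrary rotations would move anchors off the $L^*=50$
plane. With the identity assignment and channels ordered (b800, ADC,
PBF), the prostate tumor signature (high, low, high) lands on the
magenta anchor — a reddish hue ($a^* > 0$), which human observers
detect efficiently even when desaturated.

## Color conversions

Anchor hex codes are interpreted in sRGB with D65 white by default.
The published anchors are bare hex codes, and whether they were
authored under sRGB or Adobe RGB (1998) is not recorded; sRGB is the
universal display default, the choice shifts anchor $L^*$ by well
under the validation tolerance, and Adobe RGB (1998) remains
selectable (`space = "adobe1998"`, gamma 563/256 with the published
primaries matrix). The sRGB path delegates to
`grDevices::convertColor()`; the test suite holds it against a
standalone textbook implementation (IEC 61966-2-1 transfer + Lindbloom
matrices), with agreement below 0.5 ΔE — the residual reflecting only
the precision at which different sources print the same matrices.

Interpolated CIELAB colors can fall outside the display gamut.
Rendering clips each RGB component to $[0,1]$ and flags the pixel
(`out_of_gamut`); clipping is adequate here because interpolated colors
stay inside the anchor convex hull, which is nearly gamut-contained by
construction. Out-of-gamut detection uses a $10^{-6}$ component
tolerance so that round-off at exactly-representable anchor colors is
not flagged.

## Preprocessing

Each channel passes through four stages, in this order:

| stage | default | rationale |
|---|---|---|
| resample to reference grid | on (prostate), off (rat kidney) | statistics must be computed on the analysis grid |
| quantile winsorization | 1%/99% (prostate), 2%/98% (rat) | MR maps have heavy-tailed outliers; the small-animal protocol is noisier |
| normalize to $[0,1]$ | always | cube coordinates require the unit interval |
| percentile contrast stretch | 1% saturated | maximizes usable dynamic range per channel |

Decisions worth recording:

* **"Outlier removal" is winsorization**, not deletion: a fused image
  needs a value at every voxel, so out-of-range pixels are clamped to
  the quantile bounds.
* **Quantile convention** is the sorted-order statistic with linear
  interpolation between closest ranks (`stats::quantile` type 7);
  quantile definitions differ across software, so this is pinned and
  tested against a hand-written oracle.
* **"1 % maximally saturated"** is read as the symmetric
  stretch-limits convention — 0.5 % driven to 0 and 0.5 % to 1 — the
  behavior of the common `stretchlim`-style tools; an asymmetric
  variant (the full fraction per tail) is available via
  `symmetric_saturation = FALSE`.
* **Constant images** normalize to 0.5 everywhere with a warning: any
  constant is equally uninformative and 0.5 avoids biasing the fused
  color toward an anchor.
* **Resampling** maps 0-based voxel indices through
  `origin + direction %*% (index * spacing)`; out-of-field positions
  get 0, and `"nearest"` interpolation is available so binary masks
  survive resampling with their value set intact.

## Perceptual-contrast analysis

The reference point is the mean tumor color (component-wise mean of
$(L^*, a^*, b^*)$ over the tumor ROI), computed **per sample** from
that sample's own mask — the statistic asks whether *this* image's
tumor is separable, not whether tumors share an absolute color. The
report compares the median ΔE to the reference within the tumor mask
against the median within the non-tumor mask. Only masked pixels enter
the medians and histograms; pixels outside both ROIs are not ranked.
Medians use the standard sample median (mean of the central pair for
even counts); histograms default to 50 bins over $[0, \max \Delta E]$
across both regions.

## Synthetic phantoms

The package validates its pipeline on generated phantoms rather than
patient data.

* `make_prostate_phantom()` draws an elliptical organ with a circular
  lesion whose per-channel levels follow the carcinoma signature —
  lesion (0.85, 0.15, 0.80) vs. background (0.25, 0.75, 0.20) for
  (b800, ADC, PBF)-like channels — plus additive Gaussian noise
  (σ = 0.05 on the unit scale) and disjoint tumor / non-tumor masks.
  The levels are fixture parameters chosen to reproduce the
  qualitative red-lesion-on-blue-green-background appearance; the
  default grid is 96 × 96 pixels, enough to give ROI statistics a few
  thousand pixels while keeping the full 14-sample contrast experiment
  under a minute.
* `make_kidney_phantom()` builds two elliptical kidneys with
  concentric bands — medulla high in tubular flow, cortex high in
  plasma volume — and a "disrupted" variant in which one kidney's
  pixels are randomly permuted, collapsing its band-mean contrast
  while the contralateral kidney keeps the regular stratification.
* Noise is additive Gaussian, not Rician: the phantoms exercise the
  visualization pipeline, not MR physics. Values are clamped to
  $[0,1]$ after noise, which slightly biases region means near the
  interval ends; the region-mean tests budget for this explicitly.

Generators are pure functions of their spec and seed (the global RNG
stream is saved and restored), so fixtures are bitwise reproducible.

What passing phantom tests shows — and does not. The 14-seed contrast
experiment shows that when three channels carry a consistent
lesion-vs-background signature at realistic noise, the fused image
separates the regions by color in every run. It does not show that
real prostate lesions, with partial-volume effects, coil shading,
registration error and biological heterogeneity, will separate as
cleanly; that question needs patient data.

## Observer metrics

`diagnostic_metrics()` computes the four standard ratios and rounds
half-away-from-zero to two decimals, the convention under which every
published cell of the reference reader study reproduces exactly (28/28
cells; base R's banker's rounding differs at exact halves). The
segment scheme type records the reading grid (four transversal planes
divided into sectors); the printed total of 28 segments is the
default, while the verbal plane/sector description (summing to 30) can
be supplied explicitly — the module computes on whatever counts it is
given and does not enforce a total, since per-observer totals in the
source data (416 = 13 × 32) match neither 13 × 28 nor 13 × 30.
The contingency CSVs shipped under `inst/extdata/` keep the source's
own row labels; note that its "Radiologist 4/5 color" count rows
correspond to the "Radiologist 3/4 color" rows of its metrics table
(the count arithmetic confirms the mapping).

## Numerical and I/O choices

* Trilinear interpolation is evaluated as an 8-term weighted sum of
  corners; corner weights are products of $x_i$ or $1-x_i$, so corner
  reproduction is exact to machine precision. Coordinates outside
  $[0,1]$ are clamped with a warning rather than extrapolated.
* The anchor-hull volume enumerates supporting planes over all point
  triples (56 for 8 anchors), collects coplanar face polygons, and
  sums centroid pyramids — exact for these tiny sets, and
  cross-checked in the tests against an independent computational-
  geometry implementation on frozen fixtures. Degenerate (coplanar)
  sets report volume 0.
* NIfTI is the imaging interchange format (spacing in the pixdim,
  orientation and origin in the sform, so geometry round-trips);
  single-slice PNG is accepted with unit-spacing defaults for masks
  and quick looks. DICOM series are not parsed; convert with any
  standard tool (e.g. `dcm2niix`) first.
* Fused images are written as 8-bit RGB PNG with provenance (channel
  names, colormap, axis assignment, preprocessing) embedded as a text
  chunk and duplicated in a JSON sidecar, or as a float NIfTI RGB
  volume.
* The anatomical overlay is linear alpha blending in display RGB
  (default α = 0.5), the standard fusion convention of radiology
  viewers; α = 1 gives the color-only rendering used when no
  anatomical underlay is wanted.

## Known limitations

* CIE76 underestimates perceptual differences for highly saturated
  colors relative to CIEDE2000; this is inherent to the method's
  definition, not an implementation choice.
* Gamut clipping slightly distorts colors near the gamut boundary on
  displays narrower than the anchors assume.
* The equal-lightness constraint is only approximate (±2.3 $L^*$ units
  under sRGB); exact equality would require re-deriving anchor hexes
  per working space.
* Phantoms are 2-D; the pipeline accepts 3-D volumes, but the shipped
  generators and contrast experiment operate slice-wise.
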