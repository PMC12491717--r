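---
title: "Models and methods behind pelletscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pelletscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pelletscope` implements an image-based measurement chain for monitoring
pellet size and shape during fluid-bed layering. This vignette explains
the models behind each stage, the parameters that matter and their
defaults, and what the synthetic validation does and does not establish
about real process data.

## The measurement problem

In drug layering, a spray liquid deposits onto fluidized inert cores, so
particle diameter grows over time; the process should stop once the
batch's volume-weighted median diameter (D50) reaches specification. An
endoscopic camera sees a dense, fast particle flow in which particles
overlap and most are out of focus. Usable size data therefore comes only
from particles that are simultaneously in focus and fully visible; the
measurement chain must find them, outline them, convert outlines into
calibrated diameters, and aggregate those into distribution statistics
stable enough for endpoint decisions.

## Synthetic scenes

The generator produces the ground-truth-annotated data every other stage
is tested against.

**Geometry.** The camera looks along z at a focal plane `z = 0`; the
observable slab extends `slab_depth_um` (default 300 µm) on either side,
a shallow window of the kind a probe with its own illumination actually
sees. Particles get uniform positions in the slab; diameters are i.i.d.
from a configurable distribution (lognormal by default; a sieved
250–355 µm core fraction is modelled as lognormal with median 315 µm and
`sdlog` 0.05, a realistic width for a sieved cut). A particle is *in
focus* iff `|z| <= focus_tolerance_um` (default 150 µm), and *fully
visible* iff at least 90% of its disc is un-occluded by nearer particles
(z-buffer over pixel centers) and it does not touch the frame border —
the explicit counterpart of the annotation rule that partially visible
particles are not counted.

**Resolution.** The sensor is 900×900 px. The default calibration is
6 µm/px, giving a 5.4 mm field in which the documented 10–15 pellets per
frame fit with mostly visible outlines; at substantially finer
calibration a single 500 µm pellet would cover a large fraction of the
frame, which is inconsistent with the documented particle counts. With
24 particles per slab, about half in focus, a frame carries roughly
8–12 measurable pellets.

**Rendering.** Particles are shaded discs: an ambient rim contrast of
0.38 plus a Lambertian term of 0.35 toward the center and a small
off-center specular highlight, over a background of 0.16 with a gentle
linear illumination gradient. Contrast is attenuated with depth
(9×10⁻⁴ per µm of |z|) as light falls off away from the focal region.
Defocus is a per-particle Gaussian blur with
`sigma_px = blur_coeff · |z| / um_per_px` (default `blur_coeff` 0.12),
chosen for separability and a single tunable parameter. Compositing runs
far-to-near with premultiplied alpha, so nearer particles occlude
farther ones exactly when unblurred. Additive Gaussian sensor noise
(sd 0.02) finishes the frame. Everything is deterministic given the
configuration seed.

**Layering runs.** A tracer batch of core diameters evolves through
alternating spray and dry phases. Sprayed mass deposits as a layer of
*equal thickness* across particles (mass capture proportional to surface
area), converted via a density proxy and the batch's total surface area;
thickness is frozen during dry phases. A logistic efficiency over the
cumulative sprayed mass fraction (midpoint 0.25, steepness 10) makes the
D50 trajectory S-shaped: slow at first while liquid fills surface pores,
then near-linear, then saturating. Defaults (500 g cores, four 150 g
spray phases, density proxy 1.25 g/cm³) give ≈20% D50 growth over a run
— a plausible magnitude for a layering campaign. The growth law
guarantees every particle's diameter sequence is non-decreasing, which
the tests assert as an invariant.

## The classical detector

The reference system uses a trained segmentation network; this package
substitutes a classical stage with the same contract so the pipeline is
testable end to end.

1. A robust plane fit (least squares on below-median pixels) removes the
   illumination gradient; Otsu's threshold yields the foreground mask.
2. Touching blobs are split by watershed on the distance transform —
   necessary because dense flow constantly produces merged blobs.
3. Every instance gets a **focus score**: the mean Sobel gradient
   magnitude over a 3 px boundary band, measured against the background
   so that watershed chords (which carry no image edge by construction)
   do not dilute the score. Defocus attenuates edge gradients
   monotonically, which makes this scalar a usable surrogate for the
   network's learned focus discrimination.
4. Candidates partly bounded by a featureless chord are rejected via
   **edge coverage**: the fraction of contour vertices whose local
   gradient reaches half the contour's upper-quartile gradient must be
   at least 0.7. This mirrors the fully-visible-outline rule: hiding 10%
   of a disc's area already removes about a quarter of its boundary arc,
   so 0.7 is the arc equivalent of the 90% visible-area criterion.
5. Instances touching the border, or outside the area bounds, are
   removed; contours are resampled at ~2 px, smoothed with a circular
   moving average (pixel-chain contours otherwise carry a staircase
   perimeter that biases circularity low), and expanded outward by half
   a pixel (boundary-pixel centers sit half a pixel inside the edge).

**Calibration.** The focus-score threshold cannot be meaningfully
calibrated on isolated discs: inside a dense scene the score of an
in-focus particle runs systematically lower because blurred neighbours
raise the local background around its edge. `calibrate_focus_threshold()`
therefore segments a few whole synthetic frames without a focus cut,
labels each candidate by overlap (IoU ≥ 0.5) with in-focus fully-visible
truth, and picks the threshold maximizing the balanced operating point
min(precision, recall). The normalization range for reported confidences
comes from isolated reference discs at the focal plane and the slab edge.

The separate confidence filter (`filter_by_confidence()`, default 0.45,
inclusive keep) is the downstream cut applied to externally produced
detections with semantic confidences; the classical path filters on raw
focus scores during segmentation.

## Morphometry

The primary path measures polygon vertices directly — shoelace area,
Euclidean perimeter — to minimize perimeter discretization bias; a
raster path (pixel-center rasterization, 8-connected labeling, traced
mask contour) exists for mask-based workflows and for quantifying the
resolution effect: coarser outlines depress circularity because the
squared perimeter dominates `C = 4πA/P²`. ECD is defined from area
(area-equivalent diameter), consistent with its use as the projected
counterpart of an equivalent spherical diameter. The aspect ratio uses
the direct algebraic ellipse-specific least-squares fit
(Halir–Flusser formulation) on the outline vertices, falling back to the
second-central-moment ellipse when the conic fit is degenerate
(`method = "moments"` in the result). Coordinates are 0-based, x right,
y down, pixel centers at integers; polygons close implicitly.

## PSD statistics

**Weighted quantiles.** Volume weighting assigns `w_i ∝ d_i³`. With
diameters sorted ascending, the quantile at probability q interpolates
diameter linearly against the cumulative-weight midpoints
`c_i = Σ_{j<i} w_j + w_i/2`, clamped to the observed range. This
convention is pinned by an independent brute-force oracle in the tests.
D10/D50/D90 are the 0.1/0.5/0.9 quantiles and
`span = (D90 − D10)/D50` — the definition uniquely consistent with the
shipped reference table of D-values and spans at two decimals.

**KS comparison.** The two-sample statistic is computed exactly over the
merged sorted values; the p-value uses the asymptotic Kolmogorov series
with the small-sample correction
`λ = (√n_e + 0.12 + 0.11/√n_e)·D`, `n_e = n₁n₂/(n₁+n₂)`. The test runs
on raw (number-based) diameter samples: a weighted-ECDF KS has no
standard null distribution, so weighting is deliberately not applied.
Calibration is verified empirically: under the null the rejection rate
at α = 0.05 stays within [0.03, 0.07] (n = 500 per sample, 1000
replicates), and a 10% median shift at n = 5000 is detected essentially
always.

**Monitoring.** Windows are tumbling (disjoint) batches of
`window_particles` consecutive measurements — monitor points are then
statistically independent, unlike a sliding window. The in-line
convention of 5000 particles per distribution is the default; endpoint
detection additionally requires `consecutive_windows` (default 3)
successive windows at or above the D50 specification before the flag
fires, once, at the completing window. Streams shorter than one window
yield an empty series with a warning rather than an error.

## GLCM texture

`compute_glcm()` quantizes to `n_levels` gray levels (default 8,
per-image min–max linear; a fixed range is available for cross-image
comparability, which averaging features over several pellets at a
reference point implicitly assumes) and counts level pairs at each
offset, normalized to sum 1. Features follow the standard definitions;
correlation of a degenerate (zero-variance) GLCM is reported as `NaN`
rather than a fabricated 0 or 1. The qualitative property that coating
smoothing lowers contrast and raises homogeneity is asserted on
blurred-noise fixtures with fixed-range quantization — with per-image
min–max the ranges would shift and the property is not guaranteed.
Absolute feature values for any particular micrograph set are not
reproducible here (no images are shipped); only formula correctness and
the monotone smoothing behaviour are validated.

## Detection evaluation

Matching is greedy in descending confidence: each detection takes the
still-unmatched same-frame truth with the highest IoU at or above the
threshold. AP uses 101-point interpolated precision over the recall
grid; mAP50-95 averages the 0.50–0.95 (step 0.05) thresholds. Both
follow the convention of the ecosystem in which "mAP50-95" is the
headline metric; an exhaustive naive re-computation over all operating
points serves as the oracle in tests. Precision/recall/F1 are reported
at the operating point including all detections, matching how a single
P/R pair is usually printed for a trained model. IoU is polygon-exact by
default (polygon clipping), with a raster mode at 1 px resolution;
mask-style IoU is the natural choice for instance segmentation.

## Problem sizes used in tests

Tests and the acceptance script run scenes at 450×450 px and 12 µm/px —
the same 5.4 mm physical field as the default sensor, sampled coarser —
with 6–10 frames per condition, giving 60–160 measured particles per
D50 estimate (sampling noise well under the 5% recovery tolerance), and
layering-trend checks at 6 frames per spray checkpoint (D50 noise ≈1%
against growth steps of 4–8%). KS calibration uses 1000 null replicates
(binomial s.e. ≈0.7% around 5%) and 200 shifted replicates. These sizes
were chosen for statistical resolution; larger scenes change runtime,
not conclusions.

## What the synthetic validation does not show

The generator emulates geometry, defocus, occlusion, illumination and
sensor noise — not fluid dynamics, motion blur, agglomerates, color, or
the appearance variety of real pellets. Passing tests therefore
establish that the measurement chain is correct *given* scenes whose
imaging model roughly matches reality, not that the classical detector
would match a trained network on real video: its focus threshold is
calibrated per scene configuration and would need recalibration for a
real optical setup. Reference p-values comparing real measurement
systems cannot be recomputed without the underlying samples; the package
instead validates the KS machinery itself. Shape trends over a real
layering run (nearly constant circularity ≈0.96 and aspect ratio ≈0.87)
are reproduced only in the sense that the synthetic pellets are
near-circular and measured as such.
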