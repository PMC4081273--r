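---
title: "Methods: algorithms, conventions and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: algorithms, conventions and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microimage)
```

`microimage` is a compact, self-contained suite of classic 2-D image
processing algorithms with three end-to-end applications: measuring
bright particles ("coins") in a micrograph-like scene, registering and
mosaicking two overlapping views of a scene with binary features, and
tracking crack fronts in a drying-drop image stack through a
space--time diagram.  Every algorithm is implemented in base R, and
every pipeline runs on the package's own synthetic scene generators,
which carry exact ground truth.  This vignette records the model
behind each component, the conventions and tunable parameters, and the
numerical choices a maintainer would otherwise have to reverse
engineer.

## The sample-type contract

Images are numeric matrices (or rows × cols × channels arrays) tagged
as either `"u8"` (integer samples in 0..255) or `"float"` (samples in
[0, 1]).  Every operation states its contract in these terms, and
`to_float()` / `to_ubyte()` convert between them: `v/255` one way,
`round(255 v)` the other, rounding halves away from zero so that
`0.5 -> 128` deterministically on every platform.  The map is a
bijection on the 256 u8 levels; the suite asserts the round trip
exhaustively.  Signed float images in [-1, 1] are deliberately not
produced anywhere: the only value outside [0, 1] that ever appears is
the warp background sentinel `-1`, and it is consumed by `add_alpha()`
before any arithmetic that assumes the contract.  Keeping a single
unsigned contract everywhere removes a whole class of range bugs at
the cost of not supporting signed intermediate images, which none of
the pipelines need.

Parameter sets quoted for 8-bit images — the classic coin-measurement
settings use an adaptive-threshold offset of -15 and edge thresholds
of 10 and 80 — are divided by 255 when a pipeline runs under the float
contract, so the printed numbers keep their meaning regardless of the
sample type of the input.

## Coordinates

Pixels are indexed `(row, col)`, 1-based, as is natural in R.
Geometric transforms act on points `(x, y) = (col, row)` in 0-based
continuous coordinates — the convention of the registration
literature.  The conversion happens in exactly two places: inside
`warp()`, and where keypoint tables are turned into correspondence
lists for `ransac()`.  Keeping the flip confined to that boundary
mirrors how the field's code is actually written and avoids the
classic row/column transposition bug.

## Filtering and edge detection

Gaussian smoothing is separable with the kernel truncated at 4σ and
symmetric (reflect) boundary handling, which conserves the image mean;
the tests assert DC preservation and unit impulse mass.  The public
`sobel()` returns the magnitude of the 3×3 Sobel pair with each kernel
scaled by 1/4, so a unit step yields a bounded response of 1
independent of image size.

`canny()` follows the conventional chain: smooth at σ, differentiate
with the *unnormalized* Sobel pair, thin by non-maximum suppression
with linear interpolation of the two magnitudes that flank each pixel
along its gradient direction, then apply double-threshold hysteresis
(8-connected linking, so diagonal contours stay closed).  The choice
of the unnormalized gradient inside Canny is deliberate and is the
convention of the lineage this package follows: it is what makes the
classic printed thresholds (10 and 80 on an 8-bit image, i.e. 10/255
and 80/255 under the float contract) sit *between* the noise floor and
the response of a moderate-contrast edge at σ = 3.  With the
1/4-normalized gradient those thresholds would be unreachable and the
classic parameter set meaningless.  Non-maximum suppression keeps a
pixel when its magnitude is `>=` the interpolated magnitude on one
side and strictly `>` on the other; the asymmetry resolves two-pixel
plateau ties so ridges are at most one pixel wide across the
gradient.

`threshold_adaptive()` computes the local threshold as a
Gaussian-weighted mean over an odd `block_size` window with σ fixed at
`(block_size - 1)/6` — the conventional "99.7% of the mass inside the
window" choice — minus `offset`.  The rank `median_filter()` is
restricted to u8 images and uses the digital *disk* footprint (all
offsets with Euclidean norm ≤ radius).  A disk of radius 1 is the
5-pixel cross, which preserves 1-px axis-aligned lines — the defining
behavioral contrast with Gaussian smoothing — whereas a square 3×3
window would erase them (3 of 9 pixels can never reach the median).

## Features: FAST, Harris, ORB, matching

`detect_fast()` implements the FAST-9 segment test: a pixel is a
corner when at least 9 contiguous pixels of its 16-pixel Bresenham
circle of radius 3 are all brighter than center + threshold or all
darker than center − threshold.  Corners are scored with the Harris
response (k = 0.04, structure tensor smoothed at σ = 1) and localized
to sub-pixel precision by a quadratic fit of the Harris surface in the
3×3 neighborhood, with offsets clipped to half a pixel.  Sub-pixel
localization matters: registration accuracy is limited by keypoint
quantization noise, and the quadratic refinement removes most of it.

`orb_detect_and_extract()` runs FAST on an image pyramid (8 levels,
downscale 1.2 — the convention of the original binary-feature work),
keeps the `n_keypoints` strongest corners by Harris score, assigns
each an orientation from the intensity centroid of its circular 31-px
patch (θ = atan2(m01, m10)), and extracts a 256-bit descriptor by
pairwise intensity comparisons.  The comparison-point table is drawn
once from an isotropic Gaussian (sd = patch/5, redrawn into the
radius-13 disk) under a fixed seed and is identical in every build;
descriptors are rotated by θ discretized to 12° bins (30 entries), the
standard lookup granularity.  Cross-implementation descriptor equality
with other libraries is explicitly not a goal — what the tests pin is
self-consistent matching quality, e.g. that an image matched to its
own 90°-rotated copy yields Hamming distances far below the 128-bit
random expectation.  `match_descriptors()` is brute force with
lowest-index tie-breaks; with `cross_check = TRUE` only mutual nearest
neighbors survive, which makes the match set a partial one-to-one
mapping.

## Transforms, estimation, RANSAC

`geom_transform` objects are 3×3 homogeneous matrices with a kind
lattice (similarity ⊂ affine ⊂ projective); composition is written
`transform_compose(a, b)` = "apply a, then b", fixed by the stitching
geometry rather than by operator-notation convention, which is the
order bug this API is designed to prevent.  Estimation uses the
closed-form similarity fit (Umeyama), linear least squares for affine,
and the Hartley-normalized direct linear transform for homographies;
exact correspondences are reproduced to 1e-8 (measured: ~1e-13).

`ransac()` draws `max_trials` minimal subsets (a fixed count, default
1000, rather than adaptive stopping — determinism is worth more here
than the saved iterations), counts inliers by Euclidean reprojection
residual, breaks ties by total inlier residual, and re-estimates on
the winning consensus set.  Degenerate subsets are redrawn without
consuming the budget, up to a 10× cap.

## Warping and Hough transforms

`warp()` takes the *inverse* mapping: for each output pixel it samples
the input at `inverse_map(x, y)` by bilinear interpolation.  At exact
integer coordinates bilinear interpolation is the identity, so
identity and integer-translation warps are lossless — a property the
tests assert bit-exactly.  Out-of-bounds samples become `cval`
(`mode = "constant"`) or clamp to the border (`mode = "edge"`);
`rescale()` uses edge clamping so that upscaling does not manufacture
a `cval` border, and pre-smooths with σ = (1/factor − 1)/2 when
downscaling, a simple anti-aliasing rule that makes results
reproducible.

`hough_line()` votes at ρ = x cos θ + y sin θ on a unit ρ grid over
±diagonal with 180 angles in [−π/2, π/2); vote conservation
(accumulator total = ON pixels × angles) is a tested invariant.
`hough_circle()` accumulates center candidates along the rasterized
circle of each candidate radius around every ON pixel, and ranks peaks
across radii by count/(2πR); the normalization removes the
large-radius bias that raw counts have.  Because the midpoint-circle
rasterizer is symmetric under negation, a drawn circle votes all of
its perimeter pixels onto its exact center, which is why recovery on
rasterized circles is pixel-exact.

## Measurement

`label()` is two-pass union-find with components renumbered in
row-major first-encounter order (deterministic labels); connectivity 1
is the 4-neighborhood, 2 the 8-neighborhood.  It is checked against an
independent breadth-first flood-fill oracle on all 512 3×3 binary
images for both connectivities and on seeded random 64×64 images.
`regionprops()` reports area, the *half-open* bounding box (so width =
max_col − min_col, matching how rectangles are conventionally drawn
from these boxes), centroid, raw and central moments to order 3,
eccentricity `sqrt(1 − λmin/λmax)` of the second-moment ellipse, and a
Freeman chain-code perimeter (Moore boundary tracing; axial steps 1,
diagonal √2; a single pixel has perimeter 0).  A degenerate 1-px-wide
bar has eccentricity exactly 1; the value is defined by the formula,
not clipped.

`profile_line()` samples at unit spacing from source to destination,
both inclusive — when the length is not an integer the final partial
step contributes the endpoint itself — and averages `linewidth`
parallel lines offset perpendicular to the segment.  On lattice-
aligned endpoints the samples are exact, which the ramp test pins.

## The synthetic study conditions

The generators are first-class, tested code; their defaults *are* the
study conditions, chosen once:

* `make_coins_scene()`: background 0.2, disks peaking at 0.8 with a
  smooth radial falloff to ≈0.6 at the rim, additive Gaussian noise
  σ = 0.02 (the classic parameter regime assumes at most 0.05),
  non-overlapping placement with retry and a capacity error.  The
  0.6-vs-0.2 rim contrast is what makes the printed coin parameters
  (block 95, offset −15, min_distance 20, Canny σ = 3 with 10/255 and
  80/255) operate as intended.
* `make_textured_pair()`: one smoothed uniform-noise texture
  (smoothing σ = 3, intensities normalized to [0.05, 0.95]) rendered
  at identity and through a known transform; the canvas is padded by
  exactly the extent the transform needs, so the second view never
  samples undefined content, and the stated overlap fraction is
  enforced.  Identity transforms reproduce the first view
  bit-identically; integer translations are exact up to 1e-6.
* `make_crack_stack()`: a bright drop (0.9) with a sharp rim on a dark
  field (0.1); cracks are dark 1-px-wide radial lines at rejection-
  sampled angles (minimum separation max(0.25, 8/R) rad) that appear
  in the first half of the stack and grow linearly from rim to
  center.  Cracks are rasterized 4-connected: a 4-connected path
  cannot cross an 8-connected closed curve without sharing a pixel,
  so every crack that has passed the sampling circle is guaranteed to
  register as a dip in the space--time diagram — with 8-connected
  lines a crack can slip diagonally "between" the circle's pixels.

All generators are pure functions of (parameters, seed) with a
private RNG stream, so fixtures are bit-reproducible and never
disturb the caller's random state.

What passing tests on these scenes shows — and does not show: the
scenes exercise the printed parameter regimes, sub-pixel registration
accuracy, and the full code paths of all three pipelines, but they
are far cleaner than real micrographs.  They have no uneven
illumination (except where a test constructs it), no texture on the
objects, no motion blur, no exposure difference between views, and
noise that is exactly Gaussian.  Success here validates the
algorithms and their composition, not field robustness.

## Pipeline-level choices

The coin pipeline reports the regions of the labeled Canny edge map:
each coin's closed contour is one 8-connected component, so the region
count is the coin count and each truth center falls inside exactly one
bounding box.  The histogram uses 255 unit-width bins over the u8
levels (edges 0..255, last bin closed), computed on the u8 rendering
of the input.

The panorama pipeline runs at a working scale (default 0.25, the
classic downscaled setting; the registration benchmarks in this
package run at scale 1 on 200×200 scenes, where sub-pixel accuracy is
measurable), matches cross-checked ORB descriptors, estimates a
homography with RANSAC (min_samples 4, residual threshold 2 px), then
sharpens the consensus model by refitting on progressively tighter
inlier sets (residual_threshold divided by 2, 4, 6, stopping when
fewer than max(8, 4·min_samples) matches remain).  A consensus smaller
than max(3·min_samples, 10) raises a registration error naming the
stage — unrelated scenes must fail loudly, not produce a garbage
mosaic.  The mosaic extent is the bounding box of both images' warped
corners; both views are warped with a −1 background sentinel,
alpha-masked, summed and divided by the per-pixel image count.
Blending stops at that alpha average by design; multi-resolution
spline blending is out of scope.

The crack pipeline detects the drop contact line on the first frame
(Canny at σ = 1, thresholds 0.1/0.3 float — the rim contrast is 0.8,
far above them), searches radii between a sixth and half of the image
side by default, draws the concentric sampling circle at
`annulus_fraction` (default 0.75 — inside the rim but far enough out
to catch cracks early; the value is exposed as a parameter), and
collects per-frame intensities ordered by angle.  Rows are frames,
columns are angles: cracks appear as dark traces whose onset row is
their appearance time.

## Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale problems:
256×256 coin scenes, 200×200 registration pairs, 128×128 crack
stacks of 10 frames, 64×64 oracle comparisons (50–100 seeded
replicates), 600 exact estimation sets, and 100 seeded RANSAC
problems with 100 trials each.  These sizes were chosen so the whole
suite re-runs in a couple of minutes while every stochastic claim
still rests on enough replicates to be stable across seeds; all
randomness flows through explicit seeds, so reruns are bit-identical.

## Known limitations

* Grayscale processing only beyond the gray/RGB conversions; no color
  pipelines, no signed or 16-bit images (16-bit PNM is rejected, not
  converted).
* Bilinear interpolation only; no higher-order splines.
* The ORB descriptor table is this package's own fixed pattern;
  descriptors are not interchangeable with other implementations.
* Two-view mosaics only; no exposure compensation or multi-image
  bundle adjustment.
* The perimeter estimator and the RANSAC stopping rule are contracts
  of this package (chain-code weights 1/√2; fixed trial count), stated
  here because the field has several conventions.
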