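# microimage

A compact, self-contained toolkit of classic 2-D image processing
algorithms in base R, built for quantitative microscopy-style analyses
that need to be auditable end to end: every algorithm — from the PNM
reader to the homography estimator — is implemented in this package,
tested against independent oracles, and exercised by three complete
pipelines that run on the package's own synthetic scenes with exact
ground truth.

It is aimed at scientists and method developers who want the standard
building blocks — edge detection, local thresholding, binary features,
robust transform estimation, Hough transforms, connected-component
measurement — as plain, inspectable R functions operating on ordinary
matrices, rather than as bindings to an opaque compiled library.

## What is inside

* **Sample-type contract** — images are matrices tagged `"u8"`
  (integers 0..255) or `"float"` (values in [0, 1]); `to_float()` and
  `to_ubyte()` convert exactly (`v/255`, `round(255 v)` half away from
  zero), and the round trip is the identity on all 256 levels.
* **I/O** — bit-exact binary PNM (P5/P6) read/write and lazily loaded,
  cached, lexicographically ordered image collections.
* **Synthesis** — Bresenham lines, midpoint circles, and three scene
  generators with ground truth: noisy coin scenes, textured image
  pairs under a known planar transform, and drying-drop crack stacks.
* **Filters** — separable Gaussian, Sobel magnitude, disk-footprint
  median (u8), difference of Gaussians, Canny with non-maximum
  suppression and hysteresis, adaptive Gaussian-mean thresholding.
* **Features** — distance-suppressed local maxima, FAST-9 corners with
  Harris scores and sub-pixel refinement, ORB keypoints with 256-bit
  rotated binary descriptors, brute-force Hamming matching with
  cross-check.
* **Transforms** — similarity/affine/projective 3×3 transforms with
  estimation (Umeyama, least squares, Hartley-normalized DLT),
  inverse-mapping bilinear warps, rescaling, line and circle Hough
  transforms.
* **Measurement** — union-find connected components, region properties
  (area, half-open bbox, centroid, moments, eccentricity, chain-code
  perimeter), line-profile sampling, and generic RANSAC.
* **Pipelines** — `coins_pipeline()`, `stitch_pair()`,
  `crack_spacetime()`, plus a CLI (`inst/cli/microimage.R`) with
  `synth`, `coins`, `panorama` and `cracks` subcommands.

The core model in the registration pipeline is the planar homography:
a point correspondence x' ~ H x with H a 3×3 matrix acting on
homogeneous (x, y, 1) coordinates, estimated from cross-checked ORB
matches by RANSAC (minimal subsets of 4, Euclidean reprojection
residual ≤ 2 px) and polished by least squares on the consensus set.
The measurement pipelines rest on the Canny edge model (gradient
ridges of a Gaussian-smoothed image, kept by two-level hysteresis) and
on parameter-space voting (Hough) for lines and circles.

## Worked example

Twelve synthetic coins, measured with the classic printed parameter
set (95-px adaptive block, offset −15, peak distance 20, Canny σ = 3
with thresholds 10/255 and 80/255):

```r
library(microimage)

sc  <- make_coins_scene(12, seed = 3)
rep <- coins_pipeline(sc$image)
rep
#> <coin_report> 12 region(s), 27 peak(s)

head(rep$regions[, c("label", "area", "min_row", "min_col",
                     "max_row", "max_col", "eccentricity")], 4)
#>   label area min_row min_col max_row max_col eccentricity
#> 1     1  120      10      34      44      67    0.2507...
#> 2     2  128      26     165      62     200    0.1777...
#> 3     3  100      44     129      73     159    0.2005...
#> 4     4  147      61      16     101      56    0.1532...
```

Each of the 12 labeled regions is the closed edge contour of one coin;
every ground-truth center falls inside exactly one bounding box (the
boxes are half-open, so width is `max_col - min_col`).  The areas are
contour pixel counts, not disk areas, and the near-zero eccentricities
say the contours are nearly circular.

Registering two views of a textured scene related by a known
homography:

```r
H <- matrix(c(1.02,  0.03, -14,
             -0.02,  0.98,   9,
              5e-5, -4e-5,   1), 3, 3, byrow = TRUE)
pp  <- make_textured_pair(shape = c(200, 200),
                          transform = transform_from_matrix(H), seed = 1)
res <- stitch_pair(pp$image1, pp$image2, scale = 1, seed = 1)
res
#> <panorama_result> 570/614 inlier matches, mosaic 207 x 215

round(res$model$matrix, 5)
#>          [,1]     [,2]      [,3]
#> [1,]  1.02502  0.03129 -14.34151
#> [2,] -0.01770  0.98476   8.62923
#> [3,]  0.00007 -0.00003   1.00000
```

The estimated matrix reproduces the true homography to a maximum
corner reprojection error around half a pixel; the mosaic is the
alpha-averaged pair of warped views.

Reducing a 10-frame drying-drop stack to a space–time diagram:

```r
st  <- make_crack_stack(seed = 1)
sdg <- crack_spacetime(st$frames)
sdg
#> <spacetime_diagram> 10 frame(s) x 168 samples, drop (64, 64) r=40
```

The drop contact line is recovered exactly (truth: center (64, 64),
radius 40); each row of `sdg$matrix` is one frame sampled along the
concentric circle at 0.75 × radius, and the six cracks appear as dark
dips at their true angular positions.

See `vignettes/methods.Rmd` for the algorithms, conventions,
parameter choices and the limits of what the synthetic scenes can
show.

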