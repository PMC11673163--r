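---
title: "Keypoint stability and detector-threshold tuning for 2D slice registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keypoint stability and detector-threshold tuning for 2D slice registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package answers

Feature-based registration of tomographic slices detects keypoints in two
images, matches their descriptors, and fits a geometric transform to the
matched pairs. A difference-of-Gaussians (DoG) detector filters its raw
scale-space extrema through two thresholds: a **contrast threshold** (minimum
interpolated |D| at the fitted extremum, on the [0, 1] intensity scale;
conventional default 0.04) and an **eigenvalue-ratio threshold** (maximum
ratio of the principal curvatures of D, which discards poorly localized
edge responses; conventional default 10). These defaults were tuned for
natural photographs, not X-ray slices.

`siftstab` asks: *which keypoints survive a known geometric transformation,
and do the two threshold quantities predict that survival?* If they do, the
thresholds can be retuned to keep only stable keypoints — fewer descriptors
to compute and match, with registration quality preserved.

The package implements the full chain: a from-scratch DoG/SIFT-style
detector with both thresholds exposed, a randomized affine transform lab,
a per-keypoint **stability rate**, a statistical protocol relating stability
to keypoint properties, a 4-degree-of-freedom registration benchmark, and a
threshold sweep that scores good-match rate, difference-image RMSE, and the
keypoint count relative to the defaults.

## Stability of a keypoint

Given a reference slice and a set of transforms `T_1 .. T_n` (known exactly,
because we apply them ourselves), keypoints are detected once in the
reference and once in every warped image. A reference keypoint counts as
*re-detected* under `T_i` if some test keypoint lies within a tolerance
(default 5 px) of its mapped position. Its stability rate is

    stability = occurrences / n_transforms,

so a keypoint re-found under 6 of 12 transforms has stability 0.5. Three
conventions matter and are fixed here:

* **Octave-level check.** The distance is taken on the *test* keypoint's
  octave grid — both positions divided by `2^octave_test` — rather than in
  base coordinates. Taking the test side avoids having to re-derive which
  octave a reference keypoint "should" land in after a scaling transform.
* **No octave-index agreement is required**: a 1.5x upscale legitimately
  moves a keypoint one octave up.
* **One-to-one greedy assignment** by ascending distance, so one test
  keypoint can never certify two reference keypoints. Greedy is
  deterministic and auditable; an optimal assignment would differ only in
  contrived tie geometries.

The correlations of interest are stability vs. contrast (expected positive:
near-threshold contrast flickers under resampling) and stability vs.
eigenvalue ratio (expected negative: edge-like responses are poorly
localized along their ridge).

## The detector

The detector follows Lowe's architecture with every choice written down:

* Scale space: base smoothing `sigma0 = 1.6` assuming 0.5 px of input blur,
  `s = 3` intervals per octave (`k = 2^(1/3)`), `s + 3` Gaussian levels per
  octave, next octave from the level at `2*sigma0` by keeping every other
  pixel (floor halving). Octave count defaults to
  `floor(log2(min_dim)) - 3`. **No initial 2x upsampling**: there is no
  octave −1, so features with characteristic scale below ~2 px are outside
  the detector's reach. This keeps octave bookkeeping trivial, at the cost
  of the finest features.
* DoG levels are adjacent differences `D[i] = G[i+1] - G[i]` (`s + 2` per
  octave).
* Extrema must be strictly greater (or strictly smaller) than all
  neighbors; equal-valued neighbors disqualify, so plateaus yield nothing.
  The neighborhood is configurable: the full 3x3x3 shell (26 neighbors,
  the default) or the 6-connected axis neighborhood `2(n+1)` with `n = 2`.
  Both are first-class because the literature uses both; the 6-connected
  rule admits strictly more extrema (fewer constraints).
* Refinement is the usual second-order Taylor fit, at most 5 re-centering
  iterations, rejecting candidates that wander out of the interior
  (border margin 5 px at octave resolution, levels 1..s only). The
  interpolated contrast `|D(x_hat)|` is compared **directly** against the
  contrast threshold on the [0, 1] intensity scale — some implementations
  divide the threshold by `s` first; we do not, and the thresholds quoted
  throughout the package are on this direct scale.
* The edge test recovers the actual eigenvalue ratio
  `r = lambda_max / lambda_min` by solving `tr^2/det = (r+1)^2/r`, rather
  than thresholding the `tr^2/det` proxy. The ratio itself is stored on
  every keypoint because it is one of the two properties the stability
  analysis correlates. Candidates with `det <= 0` or curvature sign
  inconsistent with the extremum are rejected as edge-like.
* Orientation: 36-bin gradient histogram, magnitude- and
  Gaussian-weighted (window 1.5x scale), smoothed twice with a circular
  (1,1,1)/3 kernel; peaks at >= 80% of the maximum each spawn a keypoint,
  with parabolic peak interpolation. Angles are measured from +x (columns)
  toward +y (rows).
* Descriptor: 4x4 spatial cells x 8 orientation bins with trilinear
  soft-assignment, cell width 3x scale, Gaussian-weighted; L2-normalize,
  clamp at 0.2, renormalize. Flat windows yield the all-zero descriptor,
  kept as an explicit degenerate.

Because the scale space, DoG, and extremum scan do not depend on the two
thresholds, `sift_pyramid()` caches them and `keypoints_from_pyramid()`
re-runs only refinement. A threshold sweep therefore pays the pyramid cost
once per image. This also guarantees the monotonicity contract by
construction: stricter thresholds filter the *same* candidate set, so the
keypoint set at (0.06, 8) is a subset of the set at (0.04, 10).

## The transform lab

Twelve families `T0..T11` combine translation (±10 px), rotation (1–5° or
30–45°), and uniform scaling (0.7–0.9 or 1.1–1.5); each family draws its
parameters uniformly (continuously) from its ranges. The notation
`rand(a:b)` in the protocol could be read as integer sampling; continuous
sampling is the default because an integer lattice would collapse the lab
onto a handful of distinct transforms, and an integer mode is available by
flag. One fixed set of 12 transforms, drawn once from a seed, is shared by
all images of a study.

Rotation and scaling are taken **about the image centre**, not the origin.
This is the single most consequential convention in the package: a 30–45°
rotation about the raster origin would expel most of the anatomy from the
frame, making every keypoint "unstable" for reasons that have nothing to do
with the detector. Warping uses inverse mapping with bilinear
interpolation, zero fill, and same-size output; coordinates are 0-based
pixel centres with x = column.

## Registration benchmark

Matching is mutual-nearest-neighbour cross-checking on Euclidean descriptor
distance (k = 1 both ways, ties to the lowest index). Lowe's ratio test is
implemented nowhere because the cross-check replaces it in this design.
The matched pairs feed a closed-form least-squares similarity fit
(4 degrees of freedom: tx, ty, angle, uniform scale), wrapped in RANSAC
(2-point minimal samples, 3 px inlier threshold, up to 1000 iterations with
adaptive early termination at 99.9% confidence, fixed seed, final refit on
the inliers). Cross-checked matches still contain outliers, and an
unguarded least-squares fit is fragile to them; a pure least-squares mode
exists for clean benchmarks.

Quality scores:

* **Good-match rate** (benchmark mode, ground truth known): the fraction of
  matched pairs whose reference keypoint maps to within tolerance of its
  matched test keypoint. The tolerance defaults to the same 5 px as the
  stability check — the one tolerance in evidence in the protocol.
* **Difference-image RMSE**: warp the reference by the estimated transform,
  subtract from the test image, RMSE over the valid-overlap mask (pixels
  whose pull-back lands inside the source). Scoring the full frame instead
  would charge the zero-filled border against alignment quality; a
  full-frame flag exists for sensitivity analysis.
* **Minimum-keypoint rule**: a run in which either image yields fewer than
  10 keypoints is flagged as failed rather than scored — too few keypoints
  inexorably distort the fit — and failed runs are counted and excluded
  from sweep medians.

## Statistical protocol

Normality is tested with Shapiro–Wilk below 5000 samples and
Kolmogorov–Smirnov otherwise (against a normal with sample-estimated mean
and SD — a Lilliefors-style usage whose nominal p-values are conservative;
documented, not corrected). A sample of exactly 5000 goes to the KS branch.
Correlation uses Pearson when both variables pass normality and Spearman
otherwise — the standard pairing of method to distribution; rank
correlation is what the stability data actually get, since stability rates
live on a lattice. Descriptives are mean ± SD or median and IQR under the
same gate, with type-7 (linear interpolation) quartiles. Significance is
p < 0.05 throughout, with no multiple-testing correction by design.

## The phantom generator

The study's CBCT slices are private, so the package generates synthetic
slices with the features a detector actually responds to:

* a dark background (air) at 0.05 and an elliptical soft-tissue body at
  0.35 with low-frequency Gaussian-field texture;
* large bone-like primitives: filled ellipses and annuli ("cortical bone"
  rims at 0.78–0.97 around 0.55 interiors), painted in order;
* **trabecular spots**: smooth Gaussian blobs, bright and dark, with
  characteristic scales 2–9 px — inside the scale range the pyramid
  covers — a fraction strongly elongated (axis ratio up to 4), giving a
  genuine population of high eigenvalue-ratio keypoints;
* **dense fragments**: small hard bright discs (the high-contrast band);
* **bone-contour arcs**: curved ridges with Gaussian cross-section and
  smoothly tapered ends. The near-straight ones have crest lengths chosen
  so their eigenvalue ratio sits near the rejection threshold — the
  population whose localization along the crest is genuinely poor;
* additive Gaussian noise (default SD 0.02 on [0, 1]), clipped.

Rendering is deterministic per seed, and the sampled layout is attached to
the image so the noiseless composite can be reconstructed analytically — the
test suite compares the renderer against an independent per-pixel oracle.
Collections drawn with `generate_dataset()` use distinct seeds and enforce
pairwise normalized cross-correlation < 0.95, standing in for the visual
"keep only dissimilar slices" screening that a human would do.

Design note: an earlier version of the generator placed high-contrast
fiducial-bead discs on the background ring outside the body, as physical QA
phantoms do. They were removed: under the larger scalings and rotations the
periphery leaves the frame, so the brightest features were systematically
lost for geometric reasons, confounding position with contrast. The
replacement (fragments distributed through the body) keeps the contrast
spectrum without tying it to eccentric positions.

What the phantoms deliberately do **not** emulate: beam hardening, ring and
streak artifacts, scanner-specific noise spectra, and anatomical
plausibility. A passing phantom study therefore demonstrates that the
pipeline's machinery behaves as specified and that the documented
stability–property relationships emerge from resampling physics alone; it
does not certify effect sizes on clinical data.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `contrast_thresh` | 0.04 | [0,1] intensity | minimum interpolated DoG contrast |
| `evr_thresh` | 10 | ratio >= 1 | maximum principal-curvature ratio |
| `sigma0` | 1.6 | px | base smoothing |
| `s` | 3 | — | intervals per octave (`k = 2^(1/s)`) |
| `n_octaves` | `floor(log2(min_dim)) - 3` | — | pyramid depth |
| `border` | 5 | px (octave) | extremum exclusion margin |
| `tol_px` | 5 | px (octave grid) | stability / good-match tolerance |
| `min_keypoints` | 10 | — | minimum per image for a valid run |
| contrast grid | 0.02–0.14 step 0.02 | — | sweep axis (defaults required present) |
| evr grid | 3–12 step 1 | — | sweep axis |

## Numerical choices and degenerate inputs

* Strict inequalities in the extremum scan break plateau ties by rejecting
  them, avoiding duplicate candidates.
* Refinement solves the 3x3 system by Cramer's rule; a singular Hessian is
  a divergence rejection. Finite differences are exact on quadratics, which
  the oracle tests exploit (recovery of a planted extremum to 1e-6).
* The eigenvalue-ratio inversion `r = (t + sqrt(t^2 - 4))/2` with
  `t = tr^2/det - 2` is clamped at `t^2 - 4 >= 0` against rounding.
* Equal-distance ties in matching resolve to the lowest index; RANSAC
  skips coincident minimal samples.
* A constant sample is "degenerate, not normal" in the normality test; a
  zero-variance variable makes the correlation report not-computable rather
  than an error; an empty match set scores a good-match rate of 0.
* 17-significant-digit JSON serialization round-trips transforms exactly.

## Study sizes used by the tests and the acceptance script

The shipped studies run at desk scale, chosen so the full suite completes
in a few minutes of one CPU: 256 px phantoms; 12 slices x 12 transforms for
the stability correlations (~700 keypoint records); 24 seeded trials (2 per
family) for transform recovery; 4 slices x 12 transforms x the full default
grids for the threshold sweep; 27 x 12 only as a bookkeeping check. At
~700 records the contrast correlation is comfortably significant, while the
(weaker) eigenvalue-ratio correlation is close enough to the 5% boundary
that an unlucky seed can miss it; the packaged studies use a fixed seed and
state this rather than enlarging the study.

## Known limitations

* No DICOM reader: image input is PNG/TIFF (plus in-memory matrices).
* No 2x upsampled octave, so sub-2 px features are invisible by design.
* Stability is purely geometric; descriptor similarity plays no role in
  the re-detection decision.
* The sweep explores one threshold axis at a time (the other at its
  default) plus an explicit combined pair, not the full grid product.
* Phantom realism ends at geometry + additive noise, as described above.
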