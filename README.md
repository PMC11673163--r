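# siftstab

Keypoint stability and detector-threshold tuning for feature-based
registration of 2D tomographic slices.

## The problem

Feature-based registration of CT/CBCT slices detects scale-space keypoints
in two images, matches their descriptors, and fits a geometric transform to
the matches. The difference-of-Gaussians (SIFT-style) detector filters its
raw extrema with two thresholds whose conventional defaults (contrast 0.04,
eigenvalue ratio 10) were tuned for photographs, not X-ray slices. This
package provides the machinery to ask, quantitatively, which keypoints are
worth keeping:

* a from-scratch DoG keypoint detector + descriptor with the **contrast
  threshold** (minimum interpolated |D| on the [0, 1] intensity scale) and
  **eigenvalue-ratio threshold** (maximum principal-curvature ratio of D,
  the edge-response filter) exposed as first-class parameters;
* a transform lab that draws randomized similarity transforms (translation
  ±10 px, rotations up to 45°, scalings 0.7–1.5) from 12 standard families
  and warps images and point sets by them;
* the per-keypoint **stability rate**: out of `n` applied transforms, the
  fraction under which the keypoint is re-detected within 5 px (checked on
  the octave grid, one-to-one greedy assignment) —
  `stability = occurrences / n_transforms`;
* a statistical protocol (normality-gated Pearson/Spearman, p < 0.05)
  correlating stability with keypoint contrast and eigenvalue ratio;
* a registration benchmark: mutual-nearest-neighbour (cross-check)
  descriptor matching, RANSAC-wrapped closed-form 4-DOF similarity fit,
  good-match rate against the known truth, difference-image RMSE over the
  valid overlap, and a minimum-10-keypoints validity rule;
* a threshold sweep over contrast {0.02..0.14} and eigenvalue ratio
  {3..12} reporting median good-match rate, median RMSE, and keypoint
  counts normalized to the defaults, with per-axis optimum selection;
* a synthetic CBCT-like **phantom generator** (bone-like annuli and discs,
  trabecular blobs, ridge arcs, soft-tissue texture, additive noise) so the
  entire analysis is reproducible without clinical data.

## Worked example

Register a phantom against a known warp of itself and recover the
transform:

```r
library(siftstab)

img <- generate_phantom(phantom_spec(256, 256, seed = 3))
tr  <- similarity_transform(tx = 3, ty = -2, angle = 10, scale = 1.1,
                            centre = c(127.5, 127.5))
moved <- warp_image(img, tr)

res <- register_pair(img, moved, tr_true = tr)
res
#> registration_result, status: ok
#>   keypoints ref/test: 58 / 60, matches: 52
#>   estimated: tx=16.91 ty=-36.98 angle=10.03 deg scale=1.0998
#>   rmse: 0.00466
#>   good match rate: 0.942

sapply(transform_params(res$estimated, centre = c(127.5, 127.5)), round, 3)
#>     tx     ty  angle  scale
#>  3.084 -1.986 10.026  1.100
```

Reading the output: 58 and 60 keypoints pass the default thresholds in the
two images; 52 descriptor matches survive the cross-check; 94% of them are
consistent with the true transform within 5 px; the fitted similarity
matches the planted (3, −2, 10°, 1.1) to within a tenth of a pixel/degree;
and the residual difference image has RMSE 0.005 on the [0, 1] intensity
scale (essentially interpolation noise). The `estimated:` line shows the
raw matrix translation about the origin; `transform_params()` re-expresses
it about the image centre used to build the truth.

The stability side of the package:

```r
imgs <- generate_dataset(12, phantom_spec(256, 256, seed = 1))
trs  <- default_transform_set(501, centre = c(127.5, 127.5))
recs <- do.call(rbind, lapply(imgs, compute_stability, transforms = trs))
stability_vs_property(recs)$contrast
#> spearman correlation: rho = 0.1397, p = 0.0002009, n = 704 (significant at 0.05)
```

Keypoint contrast correlates positively with stability (and eigenvalue
ratio negatively): near-threshold keypoints are the ones that flicker under
resampling, which is the rationale for tuning both thresholds rather than
trusting their photographic defaults.

A thin CLI over the same functions lives at `inst/scripts/siftstab`
(subcommands `phantom`, `detect`, `stability`, `sweep`, `register`;
PNG/TIFF input).

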