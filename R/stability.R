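#' Geometric correspondence of keypoints under a known transform
#'
#' Each reference keypoint's base coordinates are mapped by `tr`, then the
#' distance to every test keypoint is taken on the *test* keypoint's octave
#' grid (both coordinates divided by `2^octave_test`), matching the
#' convention that the coordinate check happens at octave level. A reference
#' keypoint counts as re-detected if a test keypoint lies within `tol_px`
#' on that grid; assignment is one-to-one, greedy by ascending distance, so
#' no test keypoint is consumed twice. Octave indices are not required to
#' match (scaling transforms legitimately move keypoints across octaves).
#'
#' @param ref_kps,test_kps keypoint data.frames with `x_base`, `y_base`,
#'   `octave` columns.
#' @param tr the `affine2d` mapping reference base coordinates into the
#'   test image.
#' @param tol_px correspondence tolerance in pixels (default 5).
#' @return logical vector, one flag per reference keypoint.
#' @export
correspond <- function(ref_kps, tr, test_kps, tol_px = 5) {
  stopifnot(tol_px > 0)
  nr <- nrow(ref_kps); nt <- nrow(test_kps)
  if (nr == 0) return(logical(0))
  if (nt == 0) return(rep(FALSE, nr))
  mapped <- map_points(cbind(ref_kps$x_base, ref_kps$y_base), tr)
  fac <- 2^test_kps$octave
  # distances on each test keypoint's octave grid
  dx <- outer(mapped[, 1], test_kps$x_base, "-") / rep(fac, each = nr)
  dy <- outer(mapped[, 2], test_kps$y_base, "-") / rep(fac, each = nr)
  d <- sqrt(dx^2 + dy^2)
  detected <- rep(FALSE, nr)
  used <- rep(FALSE, nt)
  ord <- order(d)
  for (idx in ord) {
    if (d[idx] > tol_px) break
    i <- (idx - 1L) %% nr + 1L
    j <- (idx - 1L) %/% nr + 1L
    if (detected[i] || used[j]) next
    detected[i] <- TRUE
    used[j] <- TRUE
  }
  detected
}

#' Per-keypoint stability over a set of transforms
#'
#' Detects keypoints once in the reference image, then once in each warped
#' image, and counts for every reference keypoint in how many transformed
#' images it is re-detected (within `tol_px`, octave-level check). The
#' stability rate is occurrences divided by the number of transforms, so a
#' keypoint found under 6 of 12 transforms has rate 0.5. Records carry the
#' reference keypoint's contrast and eigenvalue ratio for downstream
#' correlation.
#'
#' @param ref_img reference image matrix.
#' @param transforms list of `affine2d`.
#' @param contrast_thresh,evr_thresh detection thresholds.
#' @param config a [sift_config()].
#' @param tol_px correspondence tolerance in pixels.
#' @param image_id identifier stored in the records.
#' @return data.frame of stability records: `image_id`, `x_base`, `y_base`,
#'   `octave`, `contrast`, `evr`, `occurrences`, `n_transforms`,
#'   `stability_rate`.
#' @export
compute_stability <- function(ref_img, transforms, contrast_thresh = 0.04,
                              evr_thresh = 10, config = sift_config(),
                              tol_px = 5, image_id = "image") {
  stopifnot(length(transforms) >= 1)
  ref_kps <- detect_keypoints(ref_img, contrast_thresh, evr_thresh, config)
  n <- nrow(ref_kps)
  if (n == 0) {
    warning("no reference keypoints detected; returning empty record set")
    return(data.frame(image_id = character(), x_base = numeric(),
                      y_base = numeric(), octave = integer(),
                      contrast = numeric(), evr = numeric(),
                      occurrences = integer(), n_transforms = integer(),
                      stability_rate = numeric()))
  }
  occ <- integer(n)
  for (tr in transforms) {
    warped <- warp_image(ref_img, tr)
    test_kps <- detect_keypoints(warped, contrast_thresh, evr_thresh, config)
    occ <- occ + as.integer(correspond(ref_kps, tr, test_kps, tol_px))
  }
  data.frame(image_id = image_id,
             x_base = ref_kps$x_base, y_base = ref_kps$y_base,
             octave = ref_kps$octave, contrast = ref_kps$contrast,
             evr = ref_kps$evr, occurrences = occ,
             n_transforms = length(transforms),
             stability_rate = occ / length(transforms))
}

#' Correlate stability with keypoint properties
#'
#' Runs the normality-gated correlation protocol (see [correlation()]) for
#' stability rate against contrast and against eigenvalue ratio.
#'
#' @param records stability record data.frame from [compute_stability()]
#'   (several images' records may be row-bound).
#' @return list with elements `contrast` and `evr`, each a correlation
#'   report.
#' @export
stability_vs_property <- function(records) {
  stopifnot(nrow(records) >= 3)
  list(contrast = correlation(records$contrast, records$stability_rate),
       evr = correlation(records$evr, records$stability_rate))
}

#' Write stability records to CSV
#' @param records data.frame from [compute_stability()].
#' @param path output file.
#' @export
write_stability_csv <- function(records, path)
  write.csv(records, path, row.names = FALSE)
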