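#' Locate candidate extrema in a DoG stack
#'
#' A sample is a candidate if it is strictly greater than every neighbor or
#' strictly less than every neighbor (equal-valued neighbors disqualify it,
#' so plateaus yield no duplicates). Only interior difference levels
#' (1..s on the stack) and samples at least `border` px from the raster edge
#' are scanned. The `"linf"` neighborhood is the full 3x3x3 shell
#' (26 members); `"l1"` is the axis-connected set (6 members in 2D + scale).
#'
#' @param dog a [build_dog()] stack.
#' @param neighborhood `"linf"` or `"l1"`.
#' @param border margin in pixels at octave resolution.
#' @return data.frame with 0-based `octave`, `level`, `row`, `col`.
#' @export
detect_extrema <- function(dog, neighborhood = c("linf", "l1"), border = 5L) {
  stopifnot(inherits(dog, "dog_stack"))
  neighborhood <- match.arg(neighborhood)
  out <- lapply(seq_along(dog$octaves), function(o) {
    arr <- dog$octaves[[o]]
    dm <- dim(arr)
    if (min(dm[1:2]) <= 2L * border) return(NULL)
    cand <- find_extrema_cpp(as.vector(arr), dm[1], dm[2], dm[3],
                             as.integer(border), neighborhood == "l1")
    if (nrow(cand) == 0) return(NULL)
    data.frame(octave = o - 1L, level = cand[, 1], row = cand[, 2],
               col = cand[, 3])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(octave = integer(), level = integer(),
                      row = integer(), col = integer())
  out
}

# Neighbor offset sets used by the extremum scan; exposed for auditing.
neighborhood_offsets <- function(neighborhood = c("linf", "l1")) {
  neighborhood <- match.arg(neighborhood)
  if (neighborhood == "l1") {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- expand.grid(dr = -1:1, dc = -1:1, dl = -1:1)
    as.matrix(g[!(g$dr == 0 & g$dc == 0 & g$dl == 0), ])
  }
}

#' Refine candidate extrema into keypoints
#'
#' Each candidate is fitted with a second-order Taylor expansion of the DoG
#' around the sample; the quadratic's extremum gives sub-pixel/sub-scale
#' offsets. If an offset exceeds 0.5 the candidate moves to the neighboring
#' sample and the fit repeats (up to `max_iter` times; failure to settle is
#' a `diverged` rejection). Accepted keypoints store the interpolated
#' contrast `|D(x_hat)|` (on the [0, 1] intensity scale, compared directly
#' with `contrast_thresh`) and the eigenvalue ratio
#' `lambda_max / lambda_min` of the 2x2 spatial Hessian (recovered from
#' `tr^2 / det`, rejected as `edge_like` above `evr_thresh` or when the
#' curvatures are inconsistent with an extremum).
#'
#' @param dog a [build_dog()] stack.
#' @param candidates data.frame from [detect_extrema()].
#' @param contrast_thresh minimum interpolated contrast (default 0.04).
#' @param evr_thresh maximum eigenvalue ratio (default 10).
#' @param border,max_iter see [sift_config()].
#' @return list with `keypoints` (a data.frame: `x_base`, `y_base`,
#'   `octave`, `level`, `sigma`, `sigma_oct`, `x_oct`, `y_oct`, `contrast`,
#'   `evr`, `orientation`) and `rejections` (counts by reason).
#' @export
refine_keypoints <- function(dog, candidates, contrast_thresh = 0.04,
                             evr_thresh = 10, border = 5L, max_iter = 5L) {
  stopifnot(inherits(dog, "dog_stack"), contrast_thresh >= 0, evr_thresh >= 1)
  kp <- list(); rej <- c(diverged = 0L, low_contrast = 0L, edge_like = 0L)
  for (o in sort(unique(candidates$octave))) {
    sub <- candidates[candidates$octave == o, , drop = FALSE]
    arr <- dog$octaves[[o + 1L]]
    dm <- dim(arr)
    res <- refine_candidates_cpp(as.vector(arr), dm[1], dm[2], dm[3],
                                 as.matrix(sub[, c("level", "row", "col")]),
                                 contrast_thresh, evr_thresh,
                                 as.integer(border), as.integer(max_iter))
    code <- res[, "code"]
    rej["diverged"] <- rej["diverged"] + sum(code == 1)
    rej["low_contrast"] <- rej["low_contrast"] + sum(code == 2)
    rej["edge_like"] <- rej["edge_like"] + sum(code == 3)
    acc <- res[code == 0, , drop = FALSE]
    if (nrow(acc) == 0) next
    # refinement can funnel neighboring candidates to one sample: keep first
    dup <- duplicated(acc[, c("level", "row", "col"), drop = FALSE])
    acc <- acc[!dup, , drop = FALSE]
    lvl_cont <- acc[, "level"] + acc[, "ds"]
    kp[[length(kp) + 1L]] <- data.frame(
      x_oct = acc[, "col"] + acc[, "dx"],
      y_oct = acc[, "row"] + acc[, "dy"],
      octave = o, level = as.integer(acc[, "level"]),
      sigma = dog$sigma0 * 2^o * dog$k^lvl_cont,
      sigma_oct = dog$sigma0 * dog$k^lvl_cont,
      contrast = abs(acc[, "contrast"]), evr = acc[, "evr"],
      orientation = NA_real_)
  }
  kps <- if (length(kp)) do.call(rbind, kp) else
    data.frame(x_oct = numeric(), y_oct = numeric(), octave = integer(),
               level = integer(), sigma = numeric(), sigma_oct = numeric(),
               contrast = numeric(), evr = numeric(), orientation = numeric())
  kps$x_base <- kps$x_oct * 2^kps$octave
  kps$y_base <- kps$y_oct * 2^kps$octave
  rownames(kps) <- NULL
  list(keypoints = kps, rejections = rej)
}

#' Assign dominant orientations
#'
#' Builds a 36-bin gradient-orientation histogram around each keypoint on
#' its octave's Gaussian level, magnitude-weighted and windowed by a
#' Gaussian of width 1.5 x scale. The histogram is circularly smoothed
#' twice with a (1, 1, 1)/3 kernel; every local peak reaching
#' `peak_ratio` of the maximum spawns a keypoint copy, its angle refined by
#' parabolic interpolation over the peak and both neighbors. Keypoints whose
#' sampling window lies fully outside the raster (or whose neighborhood is
#' perfectly flat) produce no oriented copies.
#'
#' @param kps keypoint data.frame from [refine_keypoints()].
#' @param ss the matching [build_scale_space()].
#' @param peak_ratio secondary-peak acceptance ratio (default 0.8).
#' @return keypoint data.frame with `orientation` filled in (degrees in
#'   [0, 360)), one row per dominant orientation.
#' @export
assign_orientations <- function(kps, ss, peak_ratio = 0.8) {
  stopifnot(inherits(ss, "scale_space"))
  if (nrow(kps) == 0) return(kps)
  rows <- vector("list", nrow(kps))
  for (i in seq_len(nrow(kps))) {
    k <- kps[i, ]
    g <- ss$octaves[[k$octave + 1L]][, , k$level + 1L]
    hist <- orientation_hist_cpp(g, k$x_oct, k$y_oct, k$sigma_oct)
    for (pass in 1:2) {
      hist <- (hist + hist[c(36, 1:35)] + hist[c(2:36, 1)]) / 3
    }
    mx <- max(hist)
    if (mx <= 0) next
    left <- hist[c(36, 1:35)]; right <- hist[c(2:36, 1)]
    peaks <- which(hist > left & hist > right & hist >= peak_ratio * mx)
    if (!length(peaks)) next
    angles <- vapply(peaks, function(p) {
      l <- hist[if (p == 1) 36 else p - 1]
      r <- hist[if (p == 36) 1 else p + 1]
      off <- if (l - 2 * hist[p] + r != 0) 0.5 * (l - r) / (l - 2 * hist[p] + r) else 0
      ((p - 1 + 0.5 + off) * 10) %% 360
    }, numeric(1))
    out <- k[rep(1, length(angles)), , drop = FALSE]
    out$orientation <- angles
    rows[[i]] <- out
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- kps[0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compute 128-component descriptors
#'
#' A square neighborhood around each oriented keypoint, rotated by its
#' angle, is divided into 4x4 spatial cells with 8 orientation bins each;
#' gradient samples are Gaussian-weighted and soft-assigned trilinearly.
#' The concatenated vector is L2-normalized, clamped at 0.2, and
#' renormalized. Keypoints whose sampling center falls outside the usable
#' raster are dropped (reported via the `n_dropped` attribute); a perfectly
#' flat neighborhood yields the all-zero descriptor, kept as a degenerate.
#'
#' @param kps oriented keypoint data.frame.
#' @param ss the matching [build_scale_space()].
#' @return list with `keypoints` (possibly fewer rows) and `descriptors`
#'   (matrix, one row per kept keypoint, 128 columns).
#' @export
compute_descriptors <- function(kps, ss) {
  stopifnot(inherits(ss, "scale_space"))
  n <- nrow(kps)
  desc <- matrix(0, n, 128)
  keep <- logical(n)
  for (i in seq_len(n)) {
    k <- kps[i, ]
    g <- ss$octaves[[k$octave + 1L]][, , k$level + 1L]
    if (is.na(k$orientation) ||
        k$x_oct < 1 || k$x_oct > ncol(g) - 2 ||
        k$y_oct < 1 || k$y_oct > nrow(g) - 2) next
    d <- descriptor_cpp(g, k$x_oct, k$y_oct, k$sigma_oct, k$orientation)
    nrm <- sqrt(sum(d^2))
    if (nrm > 1e-12) {
      d <- pmin(d / nrm, 0.2)
      d <- d / sqrt(sum(d^2))
    }
    desc[i, ] <- d
    keep[i] <- TRUE
  }
  out <- list(keypoints = kps[keep, , drop = FALSE],
              descriptors = desc[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Precompute the per-image pyramid
#'
#' The scale space, DoG stack, and candidate extrema do not depend on the
#' contrast / eigenvalue-ratio thresholds, so during threshold sweeps they
#' are computed once per image and reused via
#' [keypoints_from_pyramid()].
#'
#' @param img numeric matrix in [0, 1].
#' @param config a [sift_config()].
#' @return a `sift_pyramid` (scale space + DoG + candidates + config).
#' @export
sift_pyramid <- function(img, config = sift_config()) {
  ss <- build_scale_space(img, s = config$s, sigma0 = config$sigma0,
                          n_octaves = config$n_octaves,
                          assumed_blur = config$assumed_blur)
  dog <- build_dog(ss)
  cand <- detect_extrema(dog, neighborhood = config$neighborhood,
                         border = config$border)
  structure(list(ss = ss, dog = dog, candidates = cand, config = config),
            class = "sift_pyramid")
}

#' Keypoints from a precomputed pyramid
#'
#' @param pyr a [sift_pyramid()].
#' @param contrast_thresh,evr_thresh detection thresholds.
#' @param orientations also assign orientations.
#' @return keypoint data.frame (with a `rejections` attribute).
#' @export
keypoints_from_pyramid <- function(pyr, contrast_thresh = 0.04,
                                   evr_thresh = 10, orientations = FALSE) {
  ref <- refine_keypoints(pyr$dog, pyr$candidates, contrast_thresh,
                          evr_thresh, border = pyr$config$border,
                          max_iter = pyr$config$max_iter)
  kps <- ref$keypoints
  if (orientations)
    kps <- assign_orientations(kps, pyr$ss, pyr$config$peak_ratio)
  attr(kps, "rejections") <- ref$rejections
  kps
}

#' Detect keypoints in an image
#'
#' Scale space, DoG, extremum scan, and sub-pixel refinement with the
#' contrast and eigenvalue-ratio thresholds. Orientation assignment is
#' optional (geometric repeatability analyses do not need it).
#'
#' @param img numeric matrix in [0, 1].
#' @param contrast_thresh,evr_thresh detection thresholds (defaults 0.04
#'   and 10).
#' @param config a [sift_config()].
#' @param orientations assign dominant orientations.
#' @return keypoint data.frame (with a `rejections` attribute).
#' @export
detect_keypoints <- function(img, contrast_thresh = 0.04, evr_thresh = 10,
                             config = sift_config(), orientations = FALSE) {
  keypoints_from_pyramid(sift_pyramid(img, config), contrast_thresh,
                         evr_thresh, orientations = orientations)
}

#' Detect and describe keypoints
#'
#' The full pipeline: detection, orientation assignment (multiple dominant
#' orientations spawn copies), and descriptor computation.
#'
#' @inheritParams detect_keypoints
#' @return list with `keypoints`, `descriptors` (row-aligned matrix), and
#'   `rejections` (per-stage counts).
#' @export
detect_and_describe <- function(img, contrast_thresh = 0.04, evr_thresh = 10,
                                config = sift_config()) {
  pyr <- sift_pyramid(img, config)
  kps <- keypoints_from_pyramid(pyr, contrast_thresh, evr_thresh,
                                orientations = TRUE)
  rej <- attr(kps, "rejections")
  dd <- compute_descriptors(kps, pyr$ss)
  list(keypoints = dd$keypoints, descriptors = dd$descriptors,
       rejections = c(rej, descriptor_window = attr(dd, "n_dropped")))
}

#' Write / read keypoints as CSV
#'
#' Columns: `image_id`, `x_base`, `y_base`, `octave`, `level`, `sigma`,
#' `contrast`, `evr`, `orientation`.
#'
#' @param kps keypoint data.frame.
#' @param path output file.
#' @param image_id identifier stored with each row.
#' @export
write_keypoints_csv <- function(kps, path, image_id = "image") {
  cols <- c("x_base", "y_base", "octave", "level", "sigma", "contrast",
            "evr", "orientation")
  out <- cbind(data.frame(image_id = image_id), kps[, cols, drop = FALSE])
  write.csv(out, path, row.names = FALSE)
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path) read.csv(path)
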