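#' Detector configuration
#'
#' Defaults follow Lowe's standard settings: base smoothing `sigma0 = 1.6`,
#' `s = 3` intervals per octave (so adjacent levels differ by
#' `k = 2^(1/3)`), an assumed input blur of 0.5 px, and as many octaves as
#' the raster supports (`floor(log2(min_dim)) - 3`). No initial 2x
#' upsampling is performed. The extremum neighborhood is the full 26-neighbor
#' 3x3x3 shell by default; `"l1"` selects the 6-connected axis neighborhood.
#'
#' @param sigma0 base scale of the first level, in pixels of the base image.
#' @param s intervals per octave (>= 1).
#' @param n_octaves number of octaves, or `NULL` for the size-derived
#'   default.
#' @param assumed_blur blur already present in the input, in pixels.
#' @param border margin, in pixels at octave resolution, inside which
#'   extrema are not considered.
#' @param neighborhood `"linf"` (26 neighbors) or `"l1"` (6 neighbors).
#' @param max_iter maximum sub-pixel refinement steps.
#' @param peak_ratio orientation-histogram secondary-peak acceptance ratio.
#' @return list of class `sift_config`.
#' @export
sift_config <- function(sigma0 = 1.6, s = 3L, n_octaves = NULL,
                        assumed_blur = 0.5, border = 5L,
                        neighborhood = c("linf", "l1"), max_iter = 5L,
                        peak_ratio = 0.8) {
  stopifnot(sigma0 > 0, s >= 1, border >= 1, max_iter >= 1)
  structure(list(sigma0 = sigma0, s = as.integer(s), n_octaves = n_octaves,
                 assumed_blur = assumed_blur, border = as.integer(border),
                 neighborhood = match.arg(neighborhood),
                 max_iter = as.integer(max_iter), peak_ratio = peak_ratio),
            class = "sift_config")
}

#' Build the Gaussian scale space
#'
#' The image is blurred up to `sigma0`, then each octave holds `s + 3`
#' progressively blurred levels with scales `sigma0 * 2^o * k^i`,
#' `k = 2^(1/s)`; the next octave starts from the level at twice the base
#' scale, downsampled by taking every other pixel (floor halving).
#'
#' @param img numeric matrix in [0, 1], at least 64 px per side.
#' @param s intervals per octave.
#' @param sigma0 base scale.
#' @param n_octaves octave count (`NULL`: `floor(log2(min_dim)) - 3`).
#' @param assumed_blur blur assumed already present in `img`.
#' @return a `scale_space`: per-octave `rows x cols x (s + 3)` arrays plus
#'   the sigma schedule.
#' @export
build_scale_space <- function(img, s = 3L, sigma0 = 1.6, n_octaves = NULL,
                              assumed_blur = 0.5) {
  assert_gray_image(img, min_dim = 64L)
  s <- as.integer(s)
  stopifnot(s >= 1, sigma0 > 0)
  k <- 2^(1 / s)
  if (is.null(n_octaves)) n_octaves <- max(1L, floor(log2(min(dim(img)))) - 3L)
  n_octaves <- as.integer(n_octaves)
  min_side <- min(dim(img)) %/% (2^(n_octaves - 1L))
  if (min_side < 16L)
    stop(sprintf("image too small for %d octaves (last octave %d px)",
                 n_octaves, min_side), call. = FALSE)
  sigma_oct <- sigma0 * k^(0:(s + 2))            # octave-relative scales
  base <- if (sigma0 > assumed_blur)
    gauss_blur_cpp(img, sqrt(sigma0^2 - assumed_blur^2)) else img
  octaves <- vector("list", n_octaves)
  for (o in seq_len(n_octaves)) {
    nr <- nrow(base); nc <- ncol(base)
    arr <- array(0, c(nr, nc, s + 3L))
    arr[, , 1] <- base
    for (i in 2:(s + 3L)) {
      inc <- sqrt(sigma_oct[i]^2 - sigma_oct[i - 1]^2)
      arr[, , i] <- gauss_blur_cpp(arr[, , i - 1], inc)
    }
    octaves[[o]] <- arr
    if (o < n_octaves) {
      lev <- arr[, , s + 1L]                     # scale 2 * sigma0
      base <- lev[seq_len(nr %/% 2L) * 2L - 1L, seq_len(nc %/% 2L) * 2L - 1L,
                  drop = FALSE]
    }
  }
  structure(list(octaves = octaves, s = s, sigma0 = sigma0, k = k,
                 n_octaves = n_octaves, sigma_oct = sigma_oct,
                 base_dim = dim(img)),
            class = "scale_space")
}

#' Difference-of-Gaussians stack
#'
#' Subtracts adjacent Gaussian levels within each octave:
#' `D[i] = G[i + 1] - G[i]`, yielding `s + 2` difference levels per octave.
#'
#' @param ss a [build_scale_space()] result.
#' @return a `dog_stack` mirroring the octave structure.
#' @export
build_dog <- function(ss) {
  stopifnot(inherits(ss, "scale_space"))
  octaves <- lapply(ss$octaves, function(arr) {
    nl <- dim(arr)[3]
    arr[, , 2:nl, drop = FALSE] - arr[, , 1:(nl - 1), drop = FALSE]
  })
  structure(list(octaves = octaves, s = ss$s, sigma0 = ss$sigma0, k = ss$k,
                 n_octaves = ss$n_octaves, base_dim = ss$base_dim),
            class = "dog_stack")
}
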