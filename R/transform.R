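#' Build a 2D similarity (limited affine, 4 DOF) transform
#'
#' Composition order: uniform scale about `centre`, then rotation about
#' `centre`, then translation. Coordinates are 0-based pixel centers with
#' x = column, y = row; a positive angle rotates +x toward +y (clockwise on
#' screen with row-down display).
#'
#' @param tx,ty translation in pixels.
#' @param angle rotation in degrees.
#' @param scale uniform scale factor (non-zero).
#' @param centre length-2 (x, y) fixed point of the rotation/scaling.
#' @return an `affine2d` object holding the 2x3 matrix and the generating
#'   parameters.
#' @export
similarity_transform <- function(tx = 0, ty = 0, angle = 0, scale = 1,
                                 centre = c(0, 0)) {
  if (scale == 0) stop("`scale` must be non-zero", call. = FALSE)
  th <- angle * pi / 180
  lin <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  off <- centre - lin %*% centre + c(tx, ty)
  m <- cbind(lin, off)
  dimnames(m) <- NULL
  structure(list(matrix = m,
                 params = list(tx = tx, ty = ty, angle = angle, scale = scale),
                 centre = centre),
            class = "affine2d")
}

#' Wrap a raw 2x3 matrix as an affine transform
#' @param m 2x3 numeric matrix mapping (x, y, 1) to (x', y').
#' @return an `affine2d` object (without generating parameters).
#' @export
affine2d <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 2, ncol(m) == 3)
  if (abs(det(m[, 1:2])) < .Machine$double.eps)
    stop("linear part is singular", call. = FALSE)
  structure(list(matrix = m, params = NULL, centre = NULL), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d transform\n")
  print(x$matrix)
  if (!is.null(x$params))
    cat(sprintf("params: tx=%.3f ty=%.3f angle=%.3f deg scale=%.4f (centre %.1f, %.1f)\n",
                x$params$tx, x$params$ty, x$params$angle, x$params$scale,
                x$centre[1], x$centre[2]))
  invisible(x)
}

#' Invert an affine transform
#' @param x an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
invert_transform <- function(x) {
  lin <- x$matrix[, 1:2]
  li <- solve(lin)
  affine2d(cbind(li, -li %*% x$matrix[, 3]))
}

#' Extract similarity parameters from a transform
#'
#' Decomposes the linear part as scale x rotation and re-expresses the
#' translation about `centre`, so estimates can be compared with transforms
#' generated about an image centre.
#'
#' @param x an `affine2d`.
#' @param centre (x, y) fixed point about which the translation is expressed.
#' @return list with `tx`, `ty`, `angle` (degrees in (-180, 180]), `scale`.
#' @export
transform_params <- function(x, centre = c(0, 0)) {
  lin <- x$matrix[, 1:2]
  sc <- sqrt(abs(det(lin)))
  ang <- atan2(lin[2, 1], lin[1, 1]) * 180 / pi
  t2 <- lin %*% centre + x$matrix[, 3] - centre
  list(tx = t2[1], ty = t2[2], angle = ang, scale = sc)
}

#' Describe a family of random similarity transforms
#'
#' Each range is a closed interval from which a parameter is drawn uniformly;
#' a degenerate interval (two equal values or a single value) pins the
#' parameter.
#'
#' @param id character label.
#' @param tx_range,ty_range translation ranges in pixels.
#' @param angle_range rotation range in degrees.
#' @param scale_range scale range (must exclude 0).
#' @return a `transform_spec` object.
#' @export
transform_spec <- function(id, tx_range = c(0, 0), ty_range = c(0, 0),
                           angle_range = c(0, 0), scale_range = c(1, 1)) {
  fix <- function(r) if (length(r) == 1) c(r, r) else sort(r)
  tx_range <- fix(tx_range); ty_range <- fix(ty_range)
  angle_range <- fix(angle_range); scale_range <- fix(scale_range)
  if (scale_range[1] <= 0 && scale_range[2] >= 0)
    stop("`scale_range` must exclude 0", call. = FALSE)
  structure(list(id = id, tx_range = tx_range, ty_range = ty_range,
                 angle_range = angle_range, scale_range = scale_range),
            class = "transform_spec")
}

#' The 12 benchmark transform families
#'
#' The randomized translation / rotation / scaling families (and their
#' combinations) used throughout the stability study: small and large
#' rotations, up- and down-scaling, +/-10 px translations, and mixtures.
#'
#' @return list of 12 [transform_spec()]s, ids `T0`..`T11`.
#' @export
default_transform_specs <- function() {
  r10 <- c(-10, 10)
  list(
    transform_spec("T0", r10, r10, 0, 1),
    transform_spec("T1", 0, 0, c(1, 5), 1),
    transform_spec("T2", 0, 0, c(30, 45), 1),
    transform_spec("T3", r10, r10, c(1, 5), 1),
    transform_spec("T4", 0, 0, 0, c(1.1, 1.5)),
    transform_spec("T5", 0, 0, 0, c(0.7, 0.9)),
    transform_spec("T6", r10, r10, 0, c(1.1, 1.5)),
    transform_spec("T7", r10, r10, 0, c(0.7, 0.9)),
    transform_spec("T8", 0, 0, c(1, 5), c(1.1, 1.5)),
    transform_spec("T9", 0, 0, c(30, 45), c(0.7, 0.9)),
    transform_spec("T10", r10, r10, c(1, 5), c(1.1, 1.5)),
    transform_spec("T11", r10, r10, c(1, 5), c(0.7, 0.9))
  )
}

#' Draw one random transform from a family
#'
#' Parameters are drawn as continuous uniforms on the spec's ranges
#' (`integer_params = TRUE` restricts draws to the integer lattice instead).
#'
#' @param spec a [transform_spec()].
#' @param seed integer seed; same seed, same transform.
#' @param centre (x, y) fixed point for rotation/scaling, typically the image
#'   centre.
#' @param integer_params draw integer-valued parameters.
#' @return an `affine2d` carrying its generating parameters and the spec id.
#' @export
sample_transform <- function(spec, seed = 1L, centre = c(0, 0),
                             integer_params = FALSE) {
  draw <- function(r) {
    if (r[1] == r[2]) return(r[1])
    if (integer_params) sample(seq(ceiling(r[1]), floor(r[2])), 1)
    else runif(1, r[1], r[2])
  }
  tr <- with_seed(seed, {
    similarity_transform(draw(spec$tx_range), draw(spec$ty_range),
                         draw(spec$angle_range), draw(spec$scale_range),
                         centre = centre)
  })
  tr$id <- spec$id
  tr
}

#' Draw the standard set of 12 transforms
#'
#' One sample from each family returned by [default_transform_specs()],
#' in order, all sharing the RNG stream started at `seed`.
#'
#' @inheritParams sample_transform
#' @return list of 12 `affine2d` objects.
#' @export
default_transform_set <- function(seed = 1L, centre = c(0, 0),
                                  integer_params = FALSE) {
  specs <- default_transform_specs()
  with_seed(seed, {
    lapply(specs, function(sp) {
      draw <- function(r) {
        if (r[1] == r[2]) return(r[1])
        if (integer_params) sample(seq(ceiling(r[1]), floor(r[2])), 1)
        else runif(1, r[1], r[2])
      }
      tr <- similarity_transform(draw(sp$tx_range), draw(sp$ty_range),
                                 draw(sp$angle_range), draw(sp$scale_range),
                                 centre = centre)
      tr$id <- sp$id
      tr
    })
  })
}

#' Warp an image by an affine transform
#'
#' Inverse mapping with bilinear interpolation: output pixel (x, y) is pulled
#' from the source at T^-1 (x, y). The output raster has the same size as the
#' input; samples falling outside the source are 0.
#'
#' @param img numeric image matrix.
#' @param tr an `affine2d`.
#' @param return_mask also return the valid-pullback logical mask.
#' @return the warped matrix, or (with `return_mask`) a list
#'   `(image, mask)`.
#' @export
warp_image <- function(img, tr, return_mask = FALSE) {
  assert_gray_image(img)
  res <- warp_bilinear_cpp(img, invert_transform(tr)$matrix)
  if (return_mask) res else res$image
}

#' Apply a transform to point coordinates
#'
#' @param points n x 2 matrix (or data.frame) of (x, y) base-image
#'   coordinates.
#' @param tr an `affine2d`.
#' @return n x 2 matrix of mapped coordinates.
#' @export
map_points <- function(points, tr) {
  p <- as.matrix(points)
  if (ncol(p) != 2) stop("`points` must be n x 2 (x, y)", call. = FALSE)
  out <- t(tr$matrix[, 1:2] %*% t(p) + tr$matrix[, 3])
  colnames(out) <- c("x", "y")
  out
}

#' Serialize transforms to JSON
#' @param transforms list of `affine2d`.
#' @param path output file.
#' @export
write_transforms_json <- function(transforms, path) {
  payload <- lapply(transforms, function(tr) {
    list(id = if (is.null(tr$id)) NA else tr$id,
         matrix = tr$matrix, params = tr$params, centre = tr$centre)
  })
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
}

#' Read transforms back from JSON
#' @param path file written by [write_transforms_json()].
#' @return list of `affine2d`.
#' @export
read_transforms_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    m <- matrix(unlist(payload$matrix[[i]]), 2, 3)
    tr <- affine2d(m)
    p <- payload$params[i, , drop = TRUE]
    if (!all(is.na(unlist(p)))) tr$params <- as.list(p)
    ctr <- payload$centre[[i]]
    if (!is.null(ctr) && length(ctr)) tr$centre <- unlist(ctr)
    if (!is.na(payload$id[i])) tr$id <- payload$id[i]
    tr
  })
}
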