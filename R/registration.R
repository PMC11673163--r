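#' Mutual-nearest-neighbor (cross-check) descriptor matching
#'
#' Returns only consistent pairs (i, j) such that descriptor j is the
#' Euclidean nearest neighbor of query i and vice versa; each index appears
#' at most once per side. Equal-distance ties resolve to the lowest index.
#'
#' @param desc_a,desc_b descriptor matrices (rows are descriptors).
#' @return data.frame with `ref_index`, `test_index`,
#'   `descriptor_distance`.
#' @export
cross_check_match <- function(desc_a, desc_b) {
  empty <- data.frame(ref_index = integer(), test_index = integer(),
                      descriptor_distance = numeric())
  if (is.null(desc_a) || is.null(desc_b) ||
      nrow(desc_a) == 0 || nrow(desc_b) == 0) return(empty)
  d2 <- outer(rowSums(desc_a^2), rowSums(desc_b^2), "+") -
    2 * tcrossprod(desc_a, desc_b)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1, which.min)        # for each a, nearest b
  nn_ba <- apply(d2, 2, which.min)        # for each b, nearest a
  i <- which(nn_ba[nn_ab] == seq_len(nrow(desc_a)))
  if (!length(i)) return(empty)
  j <- nn_ab[i]
  data.frame(ref_index = i, test_index = j,
             descriptor_distance = sqrt(d2[cbind(i, j)]))
}

#' Fraction of matches consistent with a known transform
#'
#' Benchmark-mode scoring: a matched pair is good when the ground-truth
#' transform maps the reference keypoint to within `tol_px` (base-image
#' coordinates) of its matched test keypoint. Returns 0 when there are no
#' matches; the per-pair flags are attached as attribute `is_good`.
#'
#' @param pairs match data.frame from [cross_check_match()].
#' @param ref_kps,test_kps keypoint data.frames the indices refer to.
#' @param tr_true ground-truth `affine2d`.
#' @param tol_px tolerance in pixels (default 5, the same tolerance as the
#'   stability correspondence check).
#' @return the good-match rate in [0, 1].
#' @export
good_match_rate <- function(pairs, ref_kps, test_kps, tr_true, tol_px = 5) {
  if (nrow(pairs) == 0) return(structure(0, is_good = logical(0)))
  mapped <- map_points(cbind(ref_kps$x_base, ref_kps$y_base)[pairs$ref_index, ,
                                                             drop = FALSE],
                       tr_true)
  tp <- cbind(test_kps$x_base, test_kps$y_base)[pairs$test_index, ,
                                                drop = FALSE]
  good <- sqrt(rowSums((mapped - tp)^2)) < tol_px
  structure(mean(good), is_good = good)
}

# Closed-form least-squares similarity fit (tx, ty, theta, uniform s).
fit_similarity_lsq <- function(p, q) {
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  denom <- sum(pp^2)
  if (denom < .Machine$double.eps)
    stop("registration failure: degenerate (coincident) point set",
         call. = FALSE)
  sxx <- sum(pp[, 1] * qq[, 1] + pp[, 2] * qq[, 2])
  sxy <- sum(pp[, 1] * qq[, 2] - pp[, 2] * qq[, 1])
  th <- atan2(sxy, sxx)
  s <- sqrt(sxx^2 + sxy^2) / denom
  if (s < .Machine$double.eps)
    stop("registration failure: zero-scale fit", call. = FALSE)
  lin <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  off <- qc - lin %*% pc
  tr <- affine2d(cbind(lin, off))
  tr$params <- list(tx = off[1], ty = off[2], angle = th * 180 / pi,
                    scale = s)
  tr$centre <- c(0, 0)
  tr
}

#' Estimate the 4-DOF (similarity) transform from matched points
#'
#' Least-squares similarity (translation, rotation, uniform scale) via the
#' closed form, wrapped by default in RANSAC (2-point minimal samples,
#' 3 px inlier threshold, up to 1000 iterations with adaptive early
#' termination at 99.9% confidence, fixed seed) with a final refit on the
#' inlier set — cross-checked matches still contain outliers, and an
#' unguarded least-squares fit is fragile to them. `method = "lsq"` uses
#' all pairs directly.
#'
#' @param ref_pts,test_pts n x 2 matrices of matched (x, y) coordinates
#'   (n >= 2, not all coincident).
#' @param method `"ransac"` or `"lsq"`.
#' @param inlier_tol RANSAC inlier residual threshold in pixels.
#' @param max_iter RANSAC iteration cap.
#' @param seed RANSAC seed.
#' @return an `affine2d` with similarity `params` and an `inliers`
#'   logical attribute.
#' @export
estimate_similarity <- function(ref_pts, test_pts,
                                method = c("ransac", "lsq"),
                                inlier_tol = 3, max_iter = 1000L,
                                seed = 1L) {
  method <- match.arg(method)
  p <- as.matrix(ref_pts); q <- as.matrix(test_pts)
  if (nrow(p) != nrow(q) || ncol(p) != 2 || ncol(q) != 2)
    stop("point sets must be matched n x 2 matrices", call. = FALSE)
  n <- nrow(p)
  if (n < 2) stop("registration failure: need at least 2 pairs", call. = FALSE)
  if (method == "lsq" || n == 2) {
    tr <- fit_similarity_lsq(p, q)
    res <- sqrt(rowSums((map_points(p, tr) - q)^2))
    attr(tr, "inliers") <- res <= inlier_tol
    return(tr)
  }
  best_in <- NULL; best_cnt <- -1L
  with_seed(seed, {
    needed <- max_iter
    it <- 0L
    while (it < needed && it < max_iter) {
      it <- it + 1L
      idx <- sample.int(n, 2L)
      if (all(p[idx[1], ] == p[idx[2], ])) next
      tr <- tryCatch(fit_similarity_lsq(p[idx, , drop = FALSE],
                                        q[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tr)) next
      res <- sqrt(rowSums((map_points(p, tr) - q)^2))
      inl <- res <= inlier_tol
      cnt <- sum(inl)
      if (cnt > best_cnt) {
        best_cnt <- cnt; best_in <- inl
        w <- max(cnt / n, 1e-6)
        needed <- min(max_iter,
                      ceiling(log(1e-3) / log(max(1 - w^2, 1e-12))))
      }
    }
  })
  if (is.null(best_in) || best_cnt < 2L)
    stop("registration failure: no consistent inlier set found",
         call. = FALSE)
  tr <- fit_similarity_lsq(p[best_in, , drop = FALSE],
                           q[best_in, , drop = FALSE])
  res <- sqrt(rowSums((map_points(p, tr) - q)^2))
  attr(tr, "inliers") <- res <= inlier_tol
  tr
}

#' RMSE of the registration difference image
#'
#' Warps the reference image by the estimated transform, subtracts it from
#' the test image, and takes the root mean square over the valid-overlap
#' mask (output pixels whose pull-back lands inside the source raster).
#' `full_frame = TRUE` scores the whole frame instead, counting
#' zero-filled border against the alignment.
#'
#' @param ref_img,test_img image matrices of equal size.
#' @param tr_est estimated `affine2d`.
#' @param full_frame score the full frame instead of the overlap mask.
#' @return RMSE on the [0, 1] intensity scale.
#' @export
registration_rmse <- function(ref_img, test_img, tr_est,
                              full_frame = FALSE) {
  stopifnot(all(dim(ref_img) == dim(test_img)))
  w <- warp_image(ref_img, tr_est, return_mask = TRUE)
  mask <- if (full_frame) rep(TRUE, length(test_img)) else as.vector(w$mask)
  if (!any(mask))
    stop("registration failure: empty overlap between images", call. = FALSE)
  sqrt(mean((as.vector(w$image)[mask] - as.vector(test_img)[mask])^2))
}

#' Register an image pair with the feature pipeline
#'
#' Detect and describe in both images, cross-check match, estimate the
#' 4-DOF similarity, and score by difference-image RMSE. Runs where either
#' image yields fewer than `min_keypoints` keypoints, or where matching /
#' estimation fails, return a failure record (status field) rather than an
#' error, so sweep aggregation can count and exclude them.
#'
#' @param ref_img,test_img image matrices.
#' @param contrast_thresh,evr_thresh detection thresholds.
#' @param config a [sift_config()].
#' @param tr_true optional ground-truth `affine2d`; enables good-match
#'   scoring.
#' @param min_keypoints minimum keypoints required in each image
#'   (default 10).
#' @param tol_px good-match tolerance in pixels.
#' @param method,seed estimator options (see [estimate_similarity()]).
#' @return list of class `registration_result`: `status` (`"ok"` or a
#'   failure reason), `estimated`, `n_matches`, `good_match_rate` (NA
#'   without ground truth), `rmse`, `n_kp_ref`, `n_kp_test`.
#' @export
register_pair <- function(ref_img, test_img, contrast_thresh = 0.04,
                          evr_thresh = 10, config = sift_config(),
                          tr_true = NULL, min_keypoints = 10L, tol_px = 5,
                          method = "ransac", seed = 1L) {
  a <- detect_and_describe(ref_img, contrast_thresh, evr_thresh, config)
  b <- detect_and_describe(test_img, contrast_thresh, evr_thresh, config)
  res <- list(status = "ok", estimated = NULL, n_matches = 0L,
              good_match_rate = NA_real_, rmse = NA_real_,
              n_kp_ref = nrow(a$keypoints), n_kp_test = nrow(b$keypoints))
  class(res) <- "registration_result"
  if (res$n_kp_ref < min_keypoints || res$n_kp_test < min_keypoints) {
    res$status <- "too_few_keypoints"
    return(res)
  }
  pairs <- cross_check_match(a$descriptors, b$descriptors)
  res$n_matches <- nrow(pairs)
  if (!is.null(tr_true))
    res$good_match_rate <- as.numeric(
      good_match_rate(pairs, a$keypoints, b$keypoints, tr_true, tol_px))
  if (nrow(pairs) < 2L) {
    res$status <- "too_few_matches"
    return(res)
  }
  p <- cbind(a$keypoints$x_base, a$keypoints$y_base)[pairs$ref_index, ,
                                                     drop = FALSE]
  q <- cbind(b$keypoints$x_base, b$keypoints$y_base)[pairs$test_index, ,
                                                     drop = FALSE]
  est <- tryCatch(estimate_similarity(p, q, method = method, seed = seed),
                  error = function(e) NULL)
  if (is.null(est)) {
    res$status <- "estimation_failed"
    return(res)
  }
  res$estimated <- est
  res$rmse <- tryCatch(registration_rmse(ref_img, test_img, est),
                       error = function(e) NA_real_)
  if (is.na(res$rmse)) res$status <- "empty_overlap"
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result, status:", x$status, "\n")
  cat(sprintf("  keypoints ref/test: %d / %d, matches: %d\n",
              x$n_kp_ref, x$n_kp_test, x$n_matches))
  if (!is.null(x$estimated) && !is.null(x$estimated$params)) {
    p <- x$estimated$params
    cat(sprintf("  estimated: tx=%.2f ty=%.2f angle=%.2f deg scale=%.4f\n",
                p$tx, p$ty, p$angle, p$scale))
  }
  if (!is.na(x$rmse)) cat(sprintf("  rmse: %.5f\n", x$rmse))
  if (!is.na(x$good_match_rate))
    cat(sprintf("  good match rate: %.3f\n", x$good_match_rate))
  invisible(x)
}
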