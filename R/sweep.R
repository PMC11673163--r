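#' Configure a threshold-sweep study
#'
#' The default grids span the threshold values examined in the benchmark:
#' contrast 0.02..0.14 and eigenvalue ratio 3..12, with the detector
#' defaults (0.04, 10) required to be present since keypoint counts are
#' normalized against them.
#'
#' @param contrast_grid sorted contrast thresholds (must contain
#'   `default_contrast`).
#' @param evr_grid sorted eigenvalue-ratio thresholds (must contain
#'   `default_evr`).
#' @param n_images number of phantom slices.
#' @param n_transforms number of transforms (the 12 standard families,
#'   recycled if more are requested).
#' @param image_size phantom side length in pixels.
#' @param noise_sd,texture_scale,n_structures phantom parameters.
#' @param tol_px correspondence / good-match tolerance.
#' @param min_keypoints minimum keypoints per image for a valid run.
#' @param seed master seed for phantoms, transforms, and estimation.
#' @param default_contrast,default_evr the normalization thresholds.
#' @param detector a [sift_config()].
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(contrast_grid = c(0.02, 0.04, 0.06, 0.08, 0.10,
                                           0.12, 0.14),
                         evr_grid = 3:12, n_images = 10L, n_transforms = 12L,
                         image_size = 256L, noise_sd = 0.02,
                         texture_scale = 24, n_structures = 6L, tol_px = 5,
                         min_keypoints = 10L, seed = 1L,
                         default_contrast = 0.04, default_evr = 10,
                         detector = sift_config()) {
  contrast_grid <- sort(contrast_grid); evr_grid <- sort(evr_grid)
  if (!any(abs(contrast_grid - default_contrast) < 1e-12))
    stop("`contrast_grid` must contain the default contrast threshold",
         call. = FALSE)
  if (!any(abs(evr_grid - default_evr) < 1e-12))
    stop("`evr_grid` must contain the default eigenvalue-ratio threshold",
         call. = FALSE)
  structure(list(contrast_grid = contrast_grid, evr_grid = evr_grid,
                 n_images = as.integer(n_images),
                 n_transforms = as.integer(n_transforms),
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 texture_scale = texture_scale,
                 n_structures = as.integer(n_structures), tol_px = tol_px,
                 min_keypoints = as.integer(min_keypoints),
                 seed = as.integer(seed),
                 default_contrast = default_contrast,
                 default_evr = default_evr, detector = detector),
            class = "sweep_config")
}

#' Build the study inputs
#'
#' Generates the phantom slices, draws one transform per family (about the
#' image centre), and warps every slice by every transform:
#' `n_images x n_transforms` transformed images, all reproducible from the
#' config seed.
#'
#' @param config a [sweep_config()].
#' @return list with `images`, `transforms`, and `warped` (a list of
#'   lists, `warped[[i]][[t]]`).
#' @export
build_study <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  base <- phantom_spec(config$image_size, config$image_size,
                       n_structures = config$n_structures,
                       noise_sd = config$noise_sd,
                       texture_scale = config$texture_scale,
                       seed = config$seed)
  images <- generate_dataset(config$n_images, base)
  ctr <- c((config$image_size - 1) / 2, (config$image_size - 1) / 2)
  transforms <- default_transform_set(config$seed + 500L, centre = ctr)
  if (config$n_transforms != 12L) {
    specs <- default_transform_specs()
    transforms <- lapply(seq_len(config$n_transforms), function(t) {
      sample_transform(specs[[(t - 1L) %% 12L + 1L]],
                       seed = config$seed + 500L + t, centre = ctr)
    })
  }
  warped <- lapply(images, function(img)
    lapply(transforms, function(tr) warp_image(img, tr)))
  list(images = images, transforms = transforms, warped = warped)
}

# Registration of one pair from already-computed keypoints/descriptors.
register_from_features <- function(ref, test, ref_img, test_img, tr_true,
                                   min_keypoints, tol_px, seed) {
  res <- list(status = "ok", estimated = NULL, n_matches = 0L,
              good_match_rate = NA_real_, rmse = NA_real_,
              n_kp_ref = nrow(ref$keypoints), n_kp_test = nrow(test$keypoints))
  if (res$n_kp_ref < min_keypoints || res$n_kp_test < min_keypoints) {
    res$status <- "too_few_keypoints"; return(res)
  }
  pairs <- cross_check_match(ref$descriptors, test$descriptors)
  res$n_matches <- nrow(pairs)
  if (!is.null(tr_true))
    res$good_match_rate <- as.numeric(
      good_match_rate(pairs, ref$keypoints, test$keypoints, tr_true, tol_px))
  if (nrow(pairs) < 2L) { res$status <- "too_few_matches"; return(res) }
  p <- cbind(ref$keypoints$x_base, ref$keypoints$y_base)[pairs$ref_index, ,
                                                         drop = FALSE]
  q <- cbind(test$keypoints$x_base,
             test$keypoints$y_base)[pairs$test_index, , drop = FALSE]
  est <- tryCatch(estimate_similarity(p, q, seed = seed),
                  error = function(e) NULL)
  if (is.null(est)) { res$status <- "estimation_failed"; return(res) }
  res$estimated <- est
  res$rmse <- tryCatch(registration_rmse(ref_img, test_img, est),
                       error = function(e) NA_real_)
  if (is.na(res$rmse)) res$status <- "empty_overlap"
  res
}

features_at <- function(pyr, contrast, evr) {
  kps <- keypoints_from_pyramid(pyr, contrast, evr, orientations = TRUE)
  compute_descriptors(kps, pyr$ss)
}

#' Run the threshold sweep
#'
#' One axis at a time: every contrast grid value is run with the
#' eigenvalue-ratio threshold at its default, and vice versa (mirroring how
#' the two thresholds are examined separately before the best pair is
#' combined). At each grid point every (reference, warped) pair is
#' registered; failed runs (minimum-keypoint rule, matching or estimation
#' failure) are counted and excluded from the medians. Keypoint counts are
#' averaged over all images and normalized by the count at the default
#' threshold pair. Scale spaces and extrema are computed once per image and
#' shared across the grid.
#'
#' @param study a [build_study()] result.
#' @param config the same [sweep_config()].
#' @return list with `results` (per grid point: axis, thresholds, median
#'   good-match rate, median rmse, mean keypoint count, keypoint fraction,
#'   run counts) and `runs` (every individual registration record).
#' @export
run_threshold_sweep <- function(study, config) {
  grid <- unique(rbind(
    data.frame(contrast = config$contrast_grid, evr = config$default_evr),
    data.frame(contrast = config$default_contrast, evr = config$evr_grid)))
  n_img <- length(study$images); n_tr <- length(study$transforms)
  runs <- vector("list", nrow(grid) * n_img * n_tr)
  kp_counts <- matrix(0, nrow(grid), 0)  # filled as columns per image role
  kp_sum <- numeric(nrow(grid)); kp_n <- numeric(nrow(grid))
  ri <- 0L
  for (i in seq_len(n_img)) {
    pyr_ref <- sift_pyramid(study$images[[i]], config$detector)
    ref_feats <- lapply(seq_len(nrow(grid)), function(g)
      features_at(pyr_ref, grid$contrast[g], grid$evr[g]))
    for (g in seq_len(nrow(grid))) {
      kp_sum[g] <- kp_sum[g] + nrow(ref_feats[[g]]$keypoints)
      kp_n[g] <- kp_n[g] + 1
    }
    for (t in seq_len(n_tr)) {
      pyr_test <- sift_pyramid(study$warped[[i]][[t]], config$detector)
      for (g in seq_len(nrow(grid))) {
        test_feats <- features_at(pyr_test, grid$contrast[g], grid$evr[g])
        kp_sum[g] <- kp_sum[g] + nrow(test_feats$keypoints)
        kp_n[g] <- kp_n[g] + 1
        r <- register_from_features(ref_feats[[g]], test_feats,
                                    study$images[[i]],
                                    study$warped[[i]][[t]],
                                    study$transforms[[t]],
                                    config$min_keypoints, config$tol_px,
                                    seed = config$seed + 7L * g + t)
        ri <- ri + 1L
        est <- r$estimated
        ep <- if (!is.null(est)) est$params else
          list(tx = NA_real_, ty = NA_real_, angle = NA_real_,
               scale = NA_real_)
        runs[[ri]] <- data.frame(
          image = i, transform_id = study$transforms[[t]]$id,
          contrast_thresh = grid$contrast[g], evr_thresh = grid$evr[g],
          n_kp_ref = r$n_kp_ref, n_kp_test = r$n_kp_test,
          n_matches = r$n_matches, good_match_rate = r$good_match_rate,
          rmse = r$rmse, est_tx = ep$tx, est_ty = ep$ty,
          est_angle = ep$angle, est_scale = ep$scale, status = r$status)
      }
    }
  }
  runs <- do.call(rbind, runs[seq_len(ri)])
  g_def <- which(abs(grid$contrast - config$default_contrast) < 1e-12 &
                 abs(grid$evr - config$default_evr) < 1e-12)
  mean_kp <- kp_sum / pmax(kp_n, 1)
  results <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sub <- runs[abs(runs$contrast_thresh - grid$contrast[g]) < 1e-12 &
                abs(runs$evr_thresh - grid$evr[g]) < 1e-12, ]
    ok <- sub[sub$status == "ok", ]
    axis <- if (abs(grid$evr[g] - config$default_evr) < 1e-12 &&
                abs(grid$contrast[g] - config$default_contrast) < 1e-12)
      "both" else if (abs(grid$evr[g] - config$default_evr) < 1e-12)
      "contrast" else "evr"
    data.frame(
      axis = axis, contrast_thresh = grid$contrast[g],
      evr_thresh = grid$evr[g],
      median_good_match_rate = if (nrow(ok)) median(ok$good_match_rate)
        else NA_real_,
      median_rmse = if (nrow(ok)) median(ok$rmse) else NA_real_,
      mean_keypoints = mean_kp[g],
      keypoint_fraction = mean_kp[g] / mean_kp[g_def],
      n_runs = nrow(sub), n_failed_runs = sum(sub$status != "ok"))
  }))
  list(results = results, runs = runs, config = config)
}

#' Select the per-axis optimum thresholds
#'
#' For each swept axis (the other threshold held at its default), returns
#' the grid value minimizing the median difference-image RMSE over valid
#' grid points; ties break toward the stricter threshold (larger contrast,
#' smaller eigenvalue ratio), which keeps fewer keypoints.
#'
#' @param results the `results` data.frame from [run_threshold_sweep()].
#' @return list with `contrast` and `evr`.
#' @export
select_optimum <- function(results) {
  pick <- function(sub, value, stricter_desc) {
    sub <- sub[!is.na(sub$median_rmse), ]
    if (!nrow(sub)) stop("no valid grid points on this axis", call. = FALSE)
    best <- sub[sub$median_rmse <= min(sub$median_rmse) + 1e-12, ]
    v <- best[[value]]
    if (stricter_desc) max(v) else min(v)
  }
  contrast_axis <- results[results$axis %in% c("contrast", "both"), ]
  evr_axis <- results[results$axis %in% c("evr", "both"), ]
  list(contrast = pick(contrast_axis, "contrast_thresh", TRUE),
       evr = pick(evr_axis, "evr_thresh", FALSE))
}

#' Registration at one combined threshold pair
#'
#' Re-runs every (reference, warped) pair at the given thresholds (the
#' "combined best pair" mode) and aggregates like one sweep grid point.
#'
#' @param study a [build_study()] result.
#' @param config a [sweep_config()].
#' @param contrast_thresh,evr_thresh the pair to evaluate.
#' @return one-row results data.frame plus the per-run records.
#' @export
run_combined_pair <- function(study, config, contrast_thresh, evr_thresh) {
  cfg <- config
  cfg$contrast_grid <- sort(unique(c(contrast_thresh,
                                     config$default_contrast)))
  cfg$evr_grid <- sort(unique(c(evr_thresh, config$default_evr)))
  # narrow grid: just the requested pair and the default for normalization
  grid_res <- run_threshold_sweep_pair(study, cfg, contrast_thresh,
                                       evr_thresh)
  grid_res
}

# internal: evaluate a single (contrast, evr) pair plus the default pair
run_threshold_sweep_pair <- function(study, config, contrast, evr) {
  pairs_df <- unique(data.frame(
    contrast = c(contrast, config$default_contrast),
    evr = c(evr, config$default_evr)))
  n_img <- length(study$images); n_tr <- length(study$transforms)
  runs <- list(); kp_sum <- numeric(nrow(pairs_df)); kp_n <- kp_sum
  for (i in seq_len(n_img)) {
    pyr_ref <- sift_pyramid(study$images[[i]], config$detector)
    ref_feats <- lapply(seq_len(nrow(pairs_df)), function(g)
      features_at(pyr_ref, pairs_df$contrast[g], pairs_df$evr[g]))
    for (g in seq_len(nrow(pairs_df)))
      { kp_sum[g] <- kp_sum[g] + nrow(ref_feats[[g]]$keypoints)
        kp_n[g] <- kp_n[g] + 1 }
    for (t in seq_len(n_tr)) {
      pyr_test <- sift_pyramid(study$warped[[i]][[t]], config$detector)
      for (g in seq_len(nrow(pairs_df))) {
        test_feats <- features_at(pyr_test, pairs_df$contrast[g],
                                  pairs_df$evr[g])
        kp_sum[g] <- kp_sum[g] + nrow(test_feats$keypoints)
        kp_n[g] <- kp_n[g] + 1
        r <- register_from_features(ref_feats[[g]], test_feats,
                                    study$images[[i]],
                                    study$warped[[i]][[t]],
                                    study$transforms[[t]],
                                    config$min_keypoints, config$tol_px,
                                    seed = config$seed + 13L * g + t)
        runs[[length(runs) + 1L]] <- data.frame(
          image = i, transform_id = study$transforms[[t]]$id,
          contrast_thresh = pairs_df$contrast[g],
          evr_thresh = pairs_df$evr[g], n_kp_ref = r$n_kp_ref,
          n_kp_test = r$n_kp_test, n_matches = r$n_matches,
          good_match_rate = r$good_match_rate, rmse = r$rmse,
          status = r$status)
      }
    }
  }
  runs <- do.call(rbind, runs)
  mean_kp <- kp_sum / pmax(kp_n, 1)
  g_def <- nrow(pairs_df)  # default pair is the last (or same) row
  results <- do.call(rbind, lapply(seq_len(nrow(pairs_df)), function(g) {
    sub <- runs[abs(runs$contrast_thresh - pairs_df$contrast[g]) < 1e-12 &
                abs(runs$evr_thresh - pairs_df$evr[g]) < 1e-12, ]
    ok <- sub[sub$status == "ok", ]
    data.frame(contrast_thresh = pairs_df$contrast[g],
               evr_thresh = pairs_df$evr[g],
               median_good_match_rate = if (nrow(ok))
                 median(ok$good_match_rate) else NA_real_,
               median_rmse = if (nrow(ok)) median(ok$rmse) else NA_real_,
               mean_keypoints = mean_kp[g],
               keypoint_fraction = mean_kp[g] / mean_kp[g_def],
               n_runs = nrow(sub), n_failed_runs = sum(sub$status != "ok"))
  }))
  list(results = results, runs = runs)
}
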