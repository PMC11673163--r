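test_that("extremum scan matches brute force under both neighborhoods", {
  set.seed(21)
  arr <- array(rnorm(20 * 22 * 5), c(20, 22, 5))
  dog <- make_dog(arr)
  for (nb in c("linf", "l1")) {
    got <- detect_extrema(dog, neighborhood = nb, border = 3)
    expected <- brute_extrema(arr, border = 3, l1 = (nb == "l1"))
    got_m <- as.matrix(got[, c("level", "row", "col")])
    dimnames(got_m) <- NULL; dimnames(expected) <- NULL
    expect_equal(got_m[order(got_m[, 1], got_m[, 2], got_m[, 3]), ,
                       drop = FALSE],
                 expected[order(expected[, 1], expected[, 2],
                                expected[, 3]), , drop = FALSE])
  }
  # every l1 disqualification is a subset relation: linf extrema are a
  # subset of l1 extrema (fewer constraints in l1)
  linf <- detect_extrema(dog, "linf", border = 3)
  l1 <- detect_extrema(dog, "l1", border = 3)
  expect_true(nrow(linf) <= nrow(l1))
})

test_that("single planted extremum is found by both neighborhoods; constant stack is empty", {
  arr <- array(0, c(30, 30, 5))
  arr[13, 17, 3] <- 1
  dog <- make_dog(arr)
  for (nb in c("linf", "l1")) {
    cand <- detect_extrema(dog, nb, border = 5)
    expect_equal(nrow(cand), 1)
    expect_equal(unlist(cand[1, ], use.names = FALSE), c(0L, 2L, 12L, 16L))
  }
  expect_equal(nrow(detect_extrema(make_dog(array(0.3, c(30, 30, 5))))), 0)
})

test_that("plateaus (equal-valued neighbors) yield no candidates", {
  arr <- array(0, c(30, 30, 5))
  arr[13, 16:17, 3] <- 1  # two equal maxima side by side
  expect_equal(nrow(detect_extrema(make_dog(arr))), 0)
})

test_that("sub-pixel refinement recovers an analytic quadratic extremum to 1e-6", {
  # D(x, y, s) = peak - a (x - x0)^2 - b (y - y0)^2 - c (s - s0)^2 with the
  # optimum offset (dx, dy, ds) = (0.3, -0.2, 0.1) from the sample at
  # (col 15, row 12, level 2); finite differences are exact on quadratics
  n <- 30
  x0 <- 15 + 0.3; y0 <- 12 - 0.2; s0 <- 2 + 0.1
  arr <- array(0, c(n, n, 5))
  for (l in 0:4) for (r in 0:(n - 1)) for (c in 0:(n - 1))
    arr[r + 1, c + 1, l + 1] <-
      0.2 - 0.01 * (c - x0)^2 - 0.012 * (r - y0)^2 - 0.015 * (l - s0)^2
  dog <- make_dog(arr)
  cand <- data.frame(octave = 0L, level = 2L, row = 12L, col = 15L)
  ref <- refine_keypoints(dog, cand, contrast_thresh = 0.04, evr_thresh = 10)
  expect_equal(nrow(ref$keypoints), 1)
  kp <- ref$keypoints
  expect_equal(kp$x_oct, x0, tolerance = 1e-6)
  expect_equal(kp$y_oct, y0, tolerance = 1e-6)
  expect_equal(kp$contrast, 0.2, tolerance = 1e-6)
  expect_equal(kp$evr, 0.012 / 0.01, tolerance = 1e-6)
  expect_equal(kp$sigma, 1.6 * 2^(s0 / 3), tolerance = 1e-4)
})

test_that("zero interpolated contrast is rejected as low contrast", {
  n <- 30
  arr <- array(0, c(n, n, 5))
  for (l in 0:4) for (r in 0:(n - 1)) for (c in 0:(n - 1))
    arr[r + 1, c + 1, l + 1] <-
      0 - 0.01 * (c - 15)^2 - 0.01 * (r - 12)^2 - 0.01 * (l - 2)^2
  cand <- data.frame(octave = 0L, level = 2L, row = 12L, col = 15L)
  ref <- refine_keypoints(make_dog(arr), cand, contrast_thresh = 1e-9,
                          evr_thresh = 10)
  expect_equal(nrow(ref$keypoints), 0)
  expect_equal(unname(ref$rejections["low_contrast"]), 1L)
})

test_that("an ideal straight ridge is rejected as edge-like at any threshold", {
  # one spatial curvature ~ 0: eigenvalue ratio diverges
  n <- 30
  arr <- array(0, c(n, n, 5))
  for (l in 0:4) for (r in 0:(n - 1)) for (c in 0:(n - 1))
    arr[r + 1, c + 1, l + 1] <-
      0.3 - 1e-9 * (c - 15)^2 - 0.02 * (r - 12)^2 - 0.01 * (l - 2)^2
  cand <- data.frame(octave = 0L, level = 2L, row = 12L, col = 15L)
  for (evr_t in c(10, 1e6)) {
    ref <- refine_keypoints(make_dog(arr), cand, contrast_thresh = 0.04,
                            evr_thresh = evr_t)
    expect_equal(nrow(ref$keypoints), 0)
    expect_equal(unname(ref$rejections["edge_like"]), 1L)
  }
})

test_that("keypoints self-audit against the thresholds in force", {
  pyr <- fixture_pyramid(3)
  kps <- keypoints_from_pyramid(pyr, 0.04, 10)
  expect_true(all(kps$contrast >= 0.04))
  expect_true(all(kps$evr <= 10 & kps$evr >= 1))
  expect_equal(kps$x_base, kps$x_oct * 2^kps$octave)
  expect_equal(kps$y_base, kps$y_oct * 2^kps$octave)
  kps2 <- keypoints_from_pyramid(pyr, 0.06, 8)
  expect_true(all(kps2$contrast >= 0.06))
  expect_true(all(kps2$evr <= 8))
})

test_that("keypoint counts are monotone in both thresholds with subset property", {
  pyr <- fixture_pyramid(3)
  key <- function(k) paste(k$octave, k$level, round(k$x_oct, 6),
                           round(k$y_oct, 6))
  prev <- NULL
  for (ct in c(0.02, 0.04, 0.06, 0.08, 0.10, 0.12, 0.14)) {
    kps <- keypoints_from_pyramid(pyr, ct, 10)
    if (!is.null(prev)) expect_true(all(key(kps) %in% prev))
    prev <- key(kps)
  }
  prev <- NULL
  for (evr_t in c(12, 10, 8, 6, 5, 4, 3)) {
    kps <- keypoints_from_pyramid(pyr, 0.04, evr_t)
    if (!is.null(prev)) expect_true(all(key(kps) %in% prev))
    prev <- key(kps)
  }
  n_loose <- nrow(keypoints_from_pyramid(pyr, 0.04, 10))
  n_strict <- nrow(keypoints_from_pyramid(pyr, 0.06, 8))
  expect_lt(n_strict, n_loose)
})

test_that("contrast threshold 1.0 yields no keypoints on a [0,1] image", {
  kps <- detect_keypoints(fixture_phantom(3), contrast_thresh = 1.0)
  expect_equal(nrow(kps), 0)
})

test_that("detection is invariant to intensity scaling followed by renormalization", {
  img <- fixture_phantom(7)
  rescaled <- (img * 0.5) / 0.5
  a <- detect_keypoints(img)
  b <- detect_keypoints(rescaled)
  expect_equal(a, b)
})

test_that("uniform gradient yields a single orientation near 0 degrees", {
  img <- matrix(rep(seq(0, 1, length.out = 80), each = 80), 80, 80)
  ss <- build_scale_space(img, n_octaves = 1)
  kp <- data.frame(x_oct = 40, y_oct = 40, octave = 0L, level = 1L,
                   sigma = 2, sigma_oct = 2, contrast = 0.1, evr = 1,
                   orientation = NA_real_)
  out <- assign_orientations(kp, ss)
  expect_equal(nrow(out), 1)
  ang <- out$orientation
  expect_true(min(ang, 360 - ang) < 10)
})

test_that("two orthogonal gradient populations yield two orientations ~90 deg apart", {
  # img = min(row, col): gradient points along +x below the diagonal and
  # along +y above it — two equal-energy orthogonal populations, continuous
  n <- 96
  img <- outer(seq_len(n), seq_len(n), pmin) / n
  ss <- build_scale_space(img, n_octaves = 1)
  kp <- data.frame(x_oct = n / 2, y_oct = n / 2, octave = 0L, level = 1L,
                   sigma = 2, sigma_oct = 2, contrast = 0.1, evr = 1,
                   orientation = NA_real_)
  out <- assign_orientations(kp, ss)
  expect_gte(nrow(out), 2)
  angs <- sort(out$orientation)[1:2]
  gap <- diff(angs) %% 360
  # near-orthogonal: blur mixes the two populations along the crease, which
  # pulls both peaks slightly toward 45 degrees
  expect_gt(min(gap, 360 - gap), 70)
  expect_lt(min(gap, 360 - gap), 110)
  # independent oracle: direct 36-bin histogram from pixel differences on
  # the same Gaussian level must peak where the implementation put its
  # orientations
  g <- ss$octaves[[1]][, , 2]
  hist <- numeric(36)
  for (r in 2:(n - 1)) for (c in 2:(n - 1)) {
    gx <- (g[r, c + 1] - g[r, c - 1]) / 2
    gy <- (g[r + 1, c] - g[r - 1, c]) / 2
    w <- exp(-((r - 1 - n / 2)^2 + (c - 1 - n / 2)^2) / (2 * 3^2))
    ang <- (atan2(gy, gx) * 180 / pi) %% 360
    b <- floor(ang / 10) %% 36 + 1
    hist[b] <- hist[b] + w * sqrt(gx^2 + gy^2)
  }
  centers <- (order(hist, decreasing = TRUE)[1:2] - 0.5) * 10
  for (a in angs) {
    dd <- abs((a - centers + 180) %% 360 - 180)
    expect_lt(min(dd), 15)
  }
})

test_that("descriptors are unit norm, flat patches degenerate to zero", {
  dd <- detect_and_describe(fixture_phantom(3))
  expect_equal(ncol(dd$descriptors), 128)
  norms <- sqrt(rowSums(dd$descriptors^2))
  expect_true(all(abs(norms - 1) < 1e-6 | norms == 0))
  flat <- build_scale_space(matrix(0.5, 80, 80), n_octaves = 1)
  kp <- data.frame(x_oct = 40, y_oct = 40, octave = 0L, level = 1L,
                   sigma = 2, sigma_oct = 2, contrast = 0.1, evr = 1,
                   orientation = 0)
  d <- compute_descriptors(kp, flat)
  expect_equal(sum(d$descriptors^2), 0)
})

test_that("descriptors of a 90-degree rotated phantom match at corresponding keypoints", {
  img <- fixture_phantom(5)
  rot <- t(img)[, nrow(img):1]
  a <- detect_and_describe(img)
  b <- detect_and_describe(rot)
  n <- nrow(img)
  mapped <- cbind((n - 1) - a$keypoints$y_base, a$keypoints$x_base)
  tp <- cbind(b$keypoints$x_base, b$keypoints$y_base)
  d <- sqrt(outer(mapped[, 1], tp[, 1], "-")^2 +
              outer(mapped[, 2], tp[, 2], "-")^2)
  best <- vapply(seq_len(nrow(mapped)), function(i) {
    j <- which(d[i, ] < 2)
    if (!length(j)) return(NA_real_)
    max(a$descriptors[i, ] %*% t(b$descriptors[j, , drop = FALSE]))
  }, numeric(1))
  expect_gt(mean(!is.na(best)), 0.85)              # re-detected under rotation
  expect_gt(mean(best >= 0.9, na.rm = TRUE), 0.85) # descriptors agree
  expect_gt(median(best, na.rm = TRUE), 0.9)
})

test_that("per-stage rejection counts are reported and propagate", {
  dd <- detect_and_describe(fixture_phantom(3))
  rej <- dd$rejections
  expect_true(all(c("diverged", "low_contrast", "edge_like",
                    "descriptor_window") %in% names(rej)))
  expect_true(all(rej >= 0))
})
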