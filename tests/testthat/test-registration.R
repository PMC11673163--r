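test_that("cross-check keeps only mutual nearest neighbors", {
  set.seed(41)
  a <- matrix(rnorm(10 * 8), 10, 8)
  pairs <- cross_check_match(a, a)
  expect_equal(pairs$ref_index, 1:10)
  expect_equal(pairs$test_index, 1:10)
  expect_true(all(pairs$descriptor_distance < 1e-6))
  # hand-built non-reciprocal configuration: a2's nearest is b1, but b1
  # prefers a1, so (2, 1) must be absent
  b <- rbind(c(0, 0), c(10, 0), c(20, 0))
  q <- rbind(c(0.1, 0), c(3, 0), c(20.2, 0))
  pr <- cross_check_match(b, q)
  expect_false(any(pr$ref_index == 2))
  expect_true(all(c(1, 3) %in% pr$ref_index))
})

test_that("cross-check output survives an exhaustive mutual-NN audit and is symmetric", {
  set.seed(42)
  a <- matrix(rnorm(30 * 16), 30, 16)
  b <- matrix(rnorm(25 * 16), 25, 16)
  pairs <- cross_check_match(a, b)
  d <- as.matrix(dist(rbind(a, b)))[1:30, 31:55]  # brute-force table
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$ref_index[r]; j <- pairs$test_index[r]
    expect_equal(which.min(d[i, ]), j, ignore_attr = TRUE)
    expect_equal(which.min(d[, j]), i, ignore_attr = TRUE)
  }
  expect_false(any(duplicated(pairs$ref_index)))
  expect_false(any(duplicated(pairs$test_index)))
  swapped <- cross_check_match(b, a)
  expect_equal(swapped$ref_index[order(swapped$test_index)],
               pairs$test_index[order(pairs$ref_index)])
  expect_equal(nrow(cross_check_match(matrix(0, 0, 8), a)), 0)
})

test_that("good-match rate scores planted half-good configurations", {
  ref <- data.frame(x_base = c(10, 20, 30, 40, 50, 60, 70, 80),
                    y_base = rep(10, 8), octave = 0L)
  tr <- similarity_transform(5, 0)
  test <- ref
  test$x_base <- test$x_base + 5            # = mapped position exactly
  test$x_base[5:8] <- test$x_base[5:8] + 30 # 4 planted bad matches
  pairs <- data.frame(ref_index = 1:8, test_index = 1:8,
                      descriptor_distance = 0)
  expect_equal(as.numeric(good_match_rate(pairs, ref, test, tr)), 0.5)
  expect_equal(as.numeric(good_match_rate(pairs[0, ], ref, test, tr)), 0)
  test_all <- ref; test_all$x_base <- test_all$x_base + 5
  expect_equal(as.numeric(good_match_rate(pairs, ref, test_all, tr)), 1)
})

test_that("similarity estimation matches the closed form on clean pairs", {
  set.seed(43)
  p <- matrix(runif(40, 0, 200), 20, 2)
  est0 <- estimate_similarity(p, p, method = "lsq")
  prm0 <- transform_params(est0)
  expect_equal(unlist(prm0), c(tx = 0, ty = 0, angle = 0, scale = 1),
               tolerance = 1e-9)
  tr <- similarity_transform(3, -2, 10, 1.1)
  q <- map_points(p, tr)
  for (m in c("lsq", "ransac")) {
    est <- estimate_similarity(p, q, method = m)
    expect_lt(max(abs(est$matrix - tr$matrix)), 1e-6)
  }
  # independent oracle: normal equations of the linear parametrization
  # (a, b, tx, ty) with x' = a x - b y + tx, y' = b x + a y + ty
  X <- rbind(cbind(p[, 1], -p[, 2], 1, 0), cbind(p[, 2], p[, 1], 0, 1))
  z <- c(q[, 1], q[, 2])
  beta <- solve(crossprod(X), crossprod(X, z))
  est <- estimate_similarity(p, q, method = "lsq")
  expect_equal(est$matrix[1, 1], beta[1], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(est$matrix[2, 1], beta[2], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(est$matrix[, 3], beta[3:4], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("RANSAC survives 20% gross outliers", {
  set.seed(44)
  n <- 50
  p <- matrix(runif(2 * n, 0, 200), n, 2)
  tr <- similarity_transform(6, -4, 12, 1.05, centre = c(100, 100))
  q <- map_points(p, tr)
  bad <- 1:10
  q[bad, ] <- matrix(runif(20, 0, 200), 10, 2)
  est <- estimate_similarity(p, q, method = "ransac", seed = 9)
  pe <- transform_params(est, centre = c(100, 100))
  tp <- tr$params
  expect_lt(abs(pe$tx - tp$tx), 0.5)
  expect_lt(abs(pe$ty - tp$ty), 0.5)
  expect_lt(abs(pe$angle - tp$angle), 0.5)
  expect_lt(abs(pe$scale / tp$scale - 1), 0.01)
  expect_gte(sum(attr(est, "inliers")), 40)
})

test_that("estimation is exactly equivariant under a common rigid pre-transform", {
  set.seed(45)
  p <- matrix(runif(30, 0, 100), 15, 2)
  q <- map_points(p, similarity_transform(2, 3, 8, 1.2)) +
    matrix(rnorm(30, sd = 0.2), 15, 2)
  est <- estimate_similarity(p, q, method = "lsq")
  rig <- similarity_transform(-5, 11, 30, 1, centre = c(40, 40))
  est2 <- estimate_similarity(map_points(p, rig), map_points(q, rig),
                              method = "lsq")
  # est2 = rig o est o rig^-1
  m_rig <- rbind(rig$matrix, c(0, 0, 1))
  m_est <- rbind(est$matrix, c(0, 0, 1))
  expected <- (m_rig %*% m_est %*% solve(m_rig))[1:2, ]
  expect_lt(max(abs(est2$matrix - expected)), 1e-9)
})

test_that("degenerate point sets signal registration failure", {
  p <- matrix(5, 4, 2)
  expect_error(estimate_similarity(p, p, method = "lsq"), "degenerate")
  expect_error(estimate_similarity(p[1, , drop = FALSE],
                                   p[1, , drop = FALSE]), "at least 2")
})

test_that("difference-image RMSE behaves analytically", {
  img <- fixture_phantom(3, 128)
  attributes(img) <- attributes(img)["dim"]
  expect_equal(registration_rmse(img, img, similarity_transform()), 0)
  expect_equal(registration_rmse(img, img + 0.1, similarity_transform()),
               0.1, tolerance = 1e-12)
  tr <- similarity_transform(4, -3, 8, 1.05, centre = c(63.5, 63.5))
  w <- warp_image(img, tr)
  expect_lt(registration_rmse(img, w, tr),
            registration_rmse(img, w, similarity_transform()))
})

test_that("self-registration is near-perfect and the min-keypoint rule flags sparse images", {
  img <- fixture_phantom(3)
  r <- register_pair(img, img, tr_true = similarity_transform())
  expect_identical(r$status, "ok")
  expect_lt(r$rmse, 0.01)
  expect_equal(r$good_match_rate, 1.0)
  # featureless noise field: almost no keypoints, run must be flagged
  set.seed(46)
  flat <- matrix(pmin(pmax(rnorm(128 * 128, 0.5, 0.01), 0), 1), 128, 128)
  r2 <- register_pair(flat, flat)
  expect_identical(r2$status, "too_few_keypoints")
  expect_true(is.na(r2$rmse))
})

test_that("true-transform RMSE beats identity RMSE on warped phantom pairs", {
  wins <- 0L
  for (i in 1:12) {
    img <- fixture_phantom(50 + i, 128)
    tr <- sample_transform(default_transform_specs()[[(i - 1) %% 12 + 1]],
                           seed = 80 + i, centre = c(63.5, 63.5))
    if (max(abs(tr$matrix - similarity_transform()$matrix)) < 1e-9) next
    w <- warp_image(img, tr)
    wins <- wins +
      (registration_rmse(img, w, tr) <
         registration_rmse(img, w, similarity_transform()))
  }
  expect_equal(wins, 12L)
})
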