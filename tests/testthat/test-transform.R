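test_that("degenerate ranges give the identity; family ranges are honored", {
  sp <- transform_spec("id", 0, 0, 0, 1)
  tr <- sample_transform(sp, seed = 1)
  expect_equal(tr$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-15)
  # rotation-only family: angle in [30, 45], everything else pinned
  sp2 <- default_transform_specs()[[3]]
  for (s in 1:20) {
    tr2 <- sample_transform(sp2, seed = s)
    p <- tr2$params
    expect_true(p$angle >= 30 && p$angle <= 45)
    expect_identical(c(p$tx, p$ty, p$scale), c(0, 0, 1))
  }
})

test_that("sampled parameters stay inside their ranges (combined family)", {
  sp <- default_transform_specs()[[12]]  # translation + small angle + shrink
  draws <- t(vapply(1:1000, function(s)
    unlist(sample_transform(sp, seed = s)$params), numeric(4)))
  expect_true(all(draws[, "tx"] >= -10 & draws[, "tx"] <= 10))
  expect_true(all(draws[, "ty"] >= -10 & draws[, "ty"] <= 10))
  expect_true(all(draws[, "angle"] >= 1 & draws[, "angle"] <= 5))
  expect_true(all(draws[, "scale"] >= 0.7 & draws[, "scale"] <= 0.9))
  # continuous sampling actually explores the interval
  expect_gt(length(unique(draws[, "tx"])), 990)
})

test_that("the standard set has 12 ordered families and is seed-stable", {
  set1 <- default_transform_set(7)
  set2 <- default_transform_set(7)
  expect_length(set1, 12)
  expect_identical(vapply(set1, `[[`, "", "id"), paste0("T", 0:11))
  expect_identical(lapply(set1, `[[`, "matrix"), lapply(set2, `[[`, "matrix"))
  # scaling-only family: no translation or rotation
  p4 <- set1[[5]]$params
  expect_identical(c(p4$tx, p4$ty, p4$angle), c(0, 0, 0))
  expect_true(p4$scale >= 1.1 && p4$scale <= 1.5)
})

test_that("similarity matrices decompose back to their parameters", {
  ctr <- c(60, 40)
  tr <- similarity_transform(4, -7, 23, 1.3, centre = ctr)
  p <- transform_params(tr, centre = ctr)
  expect_equal(unlist(p), c(tx = 4, ty = -7, angle = 23, scale = 1.3),
               tolerance = 1e-12)
  lin <- tr$matrix[, 1:2]
  expect_equal(crossprod(lin), diag(2) * 1.3^2, tolerance = 1e-12)
})

test_that("warping by the identity is lossless and by integer shifts exact", {
  img <- fixture_phantom(3, 128)
  attributes(img) <- attributes(img)["dim"]
  expect_lt(max(abs(warp_image(img, similarity_transform()) - img)), 1e-12)
  sh <- warp_image(img, similarity_transform(tx = 5, ty = -3))
  expected <- matrix(0, 128, 128)
  expected[1:125, 6:128] <- img[4:128, 1:123]
  expect_lt(max(abs(sh - expected)), 1e-12)
})

test_that("warp round trip through the inverse restores the interior", {
  # low-noise fixture: resampling error, not noise, is what is being bounded
  img <- fixture_phantom(3, 128, noise_sd = 0.005)
  tr <- similarity_transform(3, 2, 15, 1.08, centre = c(63.5, 63.5))
  back <- warp_image(warp_image(img, tr), invert_transform(tr))
  interior <- 30:98
  expect_lt(mean(abs(back[interior, interior] - img[interior, interior])),
            0.01)
})

test_that("point mapping is exact, preserves distance ratios and angles", {
  set.seed(5)
  pts <- matrix(runif(40, 0, 200), 20, 2)
  expect_equal(map_points(pts, similarity_transform()), pts,
               ignore_attr = TRUE)
  tr_shift <- similarity_transform(5, -3)
  expect_equal(map_points(matrix(c(0, 0), 1, 2), tr_shift),
               matrix(c(5, -3), 1, 2), ignore_attr = TRUE)
  tr <- similarity_transform(-4, 9, 37, 1.42, centre = c(50, 50))
  mp <- map_points(pts, tr)
  d0 <- dist(pts); d1 <- dist(mp)
  expect_equal(as.vector(d1 / d0), rep(1.42, length(d0)), tolerance = 1e-9)
  ang <- function(p) {
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  }
  expect_equal(ang(mp[1:3, ]), ang(pts[1:3, ]), tolerance = 1e-9)
  # inverse composition is the identity
  rt <- map_points(map_points(pts, tr), invert_transform(tr))
  expect_lt(max(abs(rt - pts)), 1e-9)
})

test_that("transform sets serialize to JSON and read back bit-exactly", {
  set1 <- default_transform_set(11, centre = c(127.5, 127.5))
  path <- tempfile(fileext = ".json")
  write_transforms_json(set1, path)
  back <- read_transforms_json(path)
  expect_length(back, 12)
  for (i in 1:12) {
    expect_identical(back[[i]]$matrix, set1[[i]]$matrix)
    expect_identical(back[[i]]$id, set1[[i]]$id)
  }
})
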