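#' Specify a synthetic CBCT-like phantom slice
#'
#' A phantom emulates a single cone-beam CT slice: a dark background (air),
#' a mid-intensity soft-tissue body with low-frequency texture, and a number
#' of high-contrast bone-like structures (bright annuli standing in for
#' cortical bone around marrow, and filled bright blobs for dense fragments).
#' All intensities live on the [0, 1] scale.
#'
#' @param width,height raster size in pixels (at least 64 each).
#' @param n_structures number of bone-like primitives to place.
#' @param noise_sd standard deviation of additive Gaussian noise, on the
#'   [0, 1] intensity scale. Zero disables noise.
#' @param texture_scale correlation length of the soft-tissue texture, in
#'   pixels. Zero disables texture, leaving a piecewise-constant composite.
#' @param seed integer seed; the same spec always renders bit-identically.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width, height, n_structures = 6L, noise_sd = 0.02,
                         texture_scale = 24, seed = 1L) {
  if (!is.numeric(width) || length(width) != 1 || width < 64)
    stop("`width` must be a single number >= 64", call. = FALSE)
  if (!is.numeric(height) || length(height) != 1 || height < 64)
    stop("`height` must be a single number >= 64", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(n_structures) || n_structures < 0)
    stop("`n_structures` must be >= 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_structures = as.integer(n_structures),
                 noise_sd = noise_sd, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth radial blob profile used for trabecular spots.
blob_profile <- function(x, y, cx, cy, sdx, sdy, phi) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  exp(-(u^2 / sdx^2 + v^2 / sdy^2) / 2)
}

# Ellipse level-set value at (x, y): <= 1 inside.
ellipse_q <- function(x, y, cx, cy, a, b, phi) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / a)^2 + (v / b)^2
}

# Paint the noiseless, textureless composite from sampled layout parameters.
# Painter's order: background, body, then structures front to back.
render_composite <- function(width, height, layout) {
  x <- matrix(rep(0:(width - 1), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1), times = width), nrow = height)
  img <- matrix(layout$background, height, width)
  b <- layout$body
  img[ellipse_q(x, y, b$cx, b$cy, b$a, b$b, b$phi) <= 1] <- layout$tissue
  st <- layout$structures
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    q <- ellipse_q(x, y, s$cx, s$cy, s$a, s$b, s$phi)
    if (s$type == "ring") {
      qi <- ellipse_q(x, y, s$cx, s$cy, max(s$a - s$thickness, 1),
                      max(s$b - s$thickness, 1), s$phi)
      img[q <= 1] <- s$rim
      img[qi <= 1] <- s$interior
    } else {
      img[q <= 1] <- s$rim
    }
  }
  dk <- layout$discs
  for (i in seq_len(NROW(dk)))
    img[ellipse_q(x, y, dk$cx[i], dk$cy[i], dk$r[i], dk$r[i], 0) <= 1] <-
      dk$value[i]
  sp <- layout$spots
  for (i in seq_len(NROW(sp)))
    img <- img + sp$amp[i] * blob_profile(x, y, sp$cx[i], sp$cy[i],
                                          sp$sdx[i], sp$sdy[i], sp$phi[i])
  ar <- layout$arcs
  for (i in seq_len(NROW(ar)))
    img <- img + ar$amp[i] * arc_profile(x, y, ar$cx[i], ar$cy[i], ar$R[i],
                                         ar$theta0[i], ar$span[i], ar$w[i])
  img
}

# Curved ridge: Gaussian cross-section about a circular arc, amplitude
# tapering smoothly toward the angular endpoints (no corner artifacts).
arc_profile <- function(x, y, cx, cy, R, theta0, span, w) {
  dx <- x - cx; dy <- y - cy
  rad <- sqrt(dx^2 + dy^2)
  dth <- atan2(dy, dx) - theta0
  dth <- (dth + pi) %% (2 * pi) - pi
  exp(-(rad - R)^2 / (2 * w^2)) * exp(-2 * (dth / (span / 2))^2)
}

#' Render a phantom slice
#'
#' Deterministic per seed: the layout (body, structure placement, intensities)
#' is drawn from the spec's seed, the piecewise-constant composite is painted
#' in painter's order, then soft-tissue texture and additive Gaussian noise
#' are applied and the result is clipped to [0, 1]. The sampled layout is
#' attached as `attr(img, "layout")` so the noiseless composite can be
#' reconstructed analytically.
#'
#' @param spec a [phantom_spec()].
#' @return a `height x width` numeric matrix in [0, 1] with the layout
#'   attached as an attribute.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  w <- spec$width; h <- spec$height
  with_seed(spec$seed, {
    m <- min(w, h)
    body <- list(cx = (w - 1) / 2 + runif(1, -0.02, 0.02) * w,
                 cy = (h - 1) / 2 + runif(1, -0.02, 0.02) * h,
                 a = runif(1, 0.38, 0.45) * w,
                 b = runif(1, 0.38, 0.45) * h,
                 phi = runif(1, 0, pi))
    n <- spec$n_structures
    structures <- data.frame(
      type = ifelse(runif(n) < 0.5, "ring", "blob"),
      cx = body$cx + runif(n, -0.55, 0.55) * body$a,
      cy = body$cy + runif(n, -0.55, 0.55) * body$b,
      a = runif(n, 0.05, 0.13) * m,
      b = NA_real_, phi = runif(n, 0, pi),
      rim = runif(n, 0.78, 0.97),
      interior = 0.55, thickness = NA_real_,
      stringsAsFactors = FALSE)
    structures$b <- structures$a * runif(n, 0.45, 1)
    structures$thickness <- pmax(2.5, 0.18 * pmin(structures$a, structures$b))
    # trabecular spots: smooth bright/dark blobs with characteristic scales
    # the scale space actually covers (sigma ~ 2..9 px at base resolution);
    # a fraction are strongly elongated (ridge-like), giving the detector a
    # genuine population of high eigenvalue-ratio, poorly localized points
    ns <- max(30L, round(80 * (w / 256) * (h / 256)))
    aniso <- runif(ns) < 0.45
    sdx <- runif(ns, 2, 9)
    spots <- data.frame(
      cx = body$cx + runif(ns, -0.85, 0.85) * body$a,
      cy = body$cy + runif(ns, -0.85, 0.85) * body$b,
      sdx = sdx * ifelse(aniso, runif(ns, 1.6, 4), 1),
      sdy = sdx, phi = runif(ns, 0, pi),
      amp = runif(ns, 0.2, 0.85) * ifelse(runif(ns) < 0.7, 1, -1))
    inside <- ellipse_q(spots$cx, spots$cy, body$cx, body$cy,
                        body$a, body$b, body$phi) <= 0.9
    spots <- spots[inside, , drop = FALSE]
    # dense bone fragments: small hard bright discs in the tissue
    nd <- max(12L, round(30 * (w / 256) * (h / 256)))
    discs <- data.frame(
      cx = body$cx + runif(nd, -0.8, 0.8) * body$a,
      cy = body$cy + runif(nd, -0.8, 0.8) * body$b,
      r = runif(nd, 2, 6),
      value = runif(nd, 0.78, 1))
    discs <- discs[ellipse_q(discs$cx, discs$cy, body$cx, body$cy,
                             body$a, body$b, body$phi) <= 0.85, ,
                   drop = FALSE]
    # curved bone-contour ridges: high-contrast crests whose position along
    # the arc is poorly constrained, the classic edge-response population
    na <- max(10L, round(18 * (w / 256) * (h / 256)))
    flat <- runif(na) < 0.4   # near-straight crests: highest eigenvalue ratio
    arc_R <- ifelse(flat, runif(na, 50, 120), runif(na, 12, 40))
    arcs <- data.frame(
      cx = body$cx + runif(na, -0.6, 0.6) * body$a,
      cy = body$cy + runif(na, -0.6, 0.6) * body$b,
      R = arc_R, theta0 = runif(na, 0, 2 * pi),
      span = ifelse(flat, runif(na, 18, 30) / arc_R,
                    runif(na, pi / 5, pi / 1.5)),
      w = runif(na, 1.5, 3),
      amp = runif(na, 0.25, 0.6) * ifelse(runif(na) < 0.75, 1, -1))
    layout <- list(background = 0.05, tissue = 0.35, body = body,
                   structures = structures, discs = discs, spots = spots,
                   arcs = arcs)
    img <- render_composite(w, h, layout)
    if (spec$texture_scale > 0) {
      tex <- gauss_blur_cpp(matrix(rnorm(h * w), h, w),
                            spec$texture_scale / 3)
      tex <- (tex - mean(tex)) / max(sd(tex), 1e-12)
      inside <- ellipse_q(matrix(rep(0:(w - 1), each = h), h),
                          matrix(rep(0:(h - 1), times = w), h),
                          body$cx, body$cy, body$a, body$b, body$phi) <= 1
      img[inside] <- img[inside] + 0.05 * tex[inside]
    }
    if (spec$noise_sd > 0) img <- img + rnorm(h * w, 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    attr(img, "layout") <- layout
    attr(img, "spec") <- spec
    img
  })
}

#' Generate a collection of distinct phantom slices
#'
#' Draws `n_images` phantoms from `base_spec` with distinct seeds. A
#' distinctness guard rejects any image whose normalized cross-correlation
#' with an already accepted one reaches 0.95 and re-draws it under a bumped
#' seed, so the collection mimics a set of slices "as different as possible".
#'
#' @param n_images number of slices (>= 1).
#' @param base_spec the [phantom_spec()] providing size, noise and texture;
#'   its seed anchors the per-image seeds.
#' @return list of image matrices.
#' @export
generate_dataset <- function(n_images, base_spec) {
  if (n_images < 1) stop("`n_images` must be >= 1", call. = FALSE)
  imgs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    attempt <- 0L
    repeat {
      sp <- base_spec
      sp$seed <- base_spec$seed + (i - 1L) * 1000L + attempt * 7919L
      img <- generate_phantom(sp)
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (cor(as.vector(img), as.vector(imgs[[j]])) >= 0.95) { ok <- FALSE; break }
      }
      if (ok) { imgs[[i]] <- img; break }
      attempt <- attempt + 1L
      if (attempt > 50L) stop("could not generate a distinct phantom", call. = FALSE)
    }
  }
  imgs
}
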