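# Shared fixtures, memoized so expensive phantoms/pyramids build once per run.
.fixtures <- new.env(parent = emptyenv())

fixture_phantom <- function(seed = 3L, size = 256L, ...) {
  key <- paste0("ph_", seed, "_", size, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_phantom(phantom_spec(size, size, seed = seed,
                                                      ...))
  .fixtures[[key]]
}

fixture_pyramid <- function(seed = 3L, size = 256L) {
  key <- paste0("pyr_", seed, "_", size)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- sift_pyramid(fixture_phantom(seed, size))
  .fixtures[[key]]
}

# Wrap a bare nr x nc x nl array as a one-octave DoG stack (s = nl - 2).
make_dog <- function(arr, sigma0 = 1.6) {
  s <- dim(arr)[3] - 2L
  structure(list(octaves = list(arr), s = s, sigma0 = sigma0,
                 k = 2^(1 / s), n_octaves = 1L, base_dim = dim(arr)[1:2]),
            class = "dog_stack")
}

# Independent brute-force strict-extremum scan over interior samples.
brute_extrema <- function(arr, border, l1) {
  dm <- dim(arr)
  hits <- NULL
  offs <- if (l1) rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                        c(0, 0, -1), c(0, 0, 1))
  else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, ]
  }
  for (l in 2:(dm[3] - 1))
    for (r in (border + 1):(dm[1] - border))
      for (c in (border + 1):(dm[2] - border)) {
        v <- arr[r, c, l]
        nb <- apply(offs, 1, function(o) arr[r + o[1], c + o[2], l + o[3]])
        if (all(v > nb) || all(v < nb))
          hits <- rbind(hits, c(l - 1L, r - 1L, c - 1L))  # 0-based
      }
  hits
}

# Independent per-pixel renderer of the noiseless phantom composite, used as
# the analytic oracle against the vectorized painter.
oracle_composite_at <- function(layout, xs, ys) {
  ell <- function(x, y, cx, cy, a, b, phi) {
    u <- (x - cx) * cos(phi) + (y - cy) * sin(phi)
    v <- -(x - cx) * sin(phi) + (y - cy) * cos(phi)
    (u / a)^2 + (v / b)^2
  }
  vapply(seq_along(xs), function(i) {
    x <- xs[i]; y <- ys[i]
    b <- layout$body
    val <- if (ell(x, y, b$cx, b$cy, b$a, b$b, b$phi) <= 1)
      layout$tissue else layout$background
    st <- layout$structures
    for (j in seq_len(nrow(st))) {
      s <- st[j, ]
      q <- ell(x, y, s$cx, s$cy, s$a, s$b, s$phi)
      if (s$type == "ring") {
        if (q <= 1) val <- s$rim
        if (ell(x, y, s$cx, s$cy, max(s$a - s$thickness, 1),
                max(s$b - s$thickness, 1), s$phi) <= 1) val <- s$interior
      } else if (q <= 1) val <- s$rim
    }
    dk <- layout$discs
    for (j in seq_len(NROW(dk)))
      if ((x - dk$cx[j])^2 + (y - dk$cy[j])^2 <= dk$r[j]^2) val <- dk$value[j]
    sp <- layout$spots
    for (j in seq_len(NROW(sp))) {
      u <- (x - sp$cx[j]) * cos(sp$phi[j]) + (y - sp$cy[j]) * sin(sp$phi[j])
      v <- -(x - sp$cx[j]) * sin(sp$phi[j]) + (y - sp$cy[j]) * cos(sp$phi[j])
      val <- val + sp$amp[j] * exp(-(u^2 / sp$sdx[j]^2 + v^2 / sp$sdy[j]^2) / 2)
    }
    ar <- layout$arcs
    for (j in seq_len(NROW(ar))) {
      dx <- x - ar$cx[j]; dy <- y - ar$cy[j]
      rad <- sqrt(dx^2 + dy^2)
      dth <- (atan2(dy, dx) - ar$theta0[j] + pi) %% (2 * pi) - pi
      val <- val + ar$amp[j] * exp(-(rad - ar$R[j])^2 / (2 * ar$w[j]^2)) *
        exp(-2 * (dth / (ar$span[j] / 2))^2)
    }
    min(max(val, 0), 1)
  }, numeric(1))
}
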