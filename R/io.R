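#' Read a grayscale image, normalized to [0, 1]
#'
#' Supports PNG and TIFF. Multi-channel rasters are converted to gray by
#' channel averaging; intensities are min-max normalized to [0, 1]
#' (a constant image maps to 0).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix in [0, 1].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  else img <- img * 0
  img
}

#' Write a grayscale image as 16-bit PNG
#'
#' @param img numeric matrix; values are clipped to [0, 1].
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  attributes(img) <- attributes(img)["dim"]
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}

#' Write a phantom fixture set with manifest
#'
#' Renders `n_images` phantoms, writes each as PNG, and writes a CSV
#' manifest (file, seed, size, parameters).
#'
#' @param n_images number of phantoms.
#' @param base_spec a [phantom_spec()].
#' @param dir output directory (created if missing).
#' @return path to the manifest CSV.
#' @export
write_phantom_fixtures <- function(n_images, base_spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgs <- generate_dataset(n_images, base_spec)
  rows <- lapply(seq_along(imgs), function(i) {
    sp <- attr(imgs[[i]], "spec")
    file <- file.path(dir, sprintf("phantom_%03d.png", i))
    write_gray_image(imgs[[i]], file)
    data.frame(file = basename(file), seed = sp$seed, width = sp$width,
               height = sp$height, n_structures = sp$n_structures,
               noise_sd = sp$noise_sd, texture_scale = sp$texture_scale)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
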