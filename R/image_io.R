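#' Calibrated micrograph images
#'
#' A `calibrated_image` bundles an 8-bit pixel array with its spatial
#' calibration. `pixels` is a numeric matrix (grayscale, rows = image rows
#' from the top) or an `h x w x 3` array (RGB), with intensities in
#' `[0, 255]`; `calibration` is micrometers per pixel.
#'
#' @param pixels matrix or 3-plane array of intensities in `[0, 255]`.
#' @param calibration micrometers per pixel (> 0).
#' @param name free-text image name.
#' @return a `calibrated_image`.
#' @export
calibrated_image <- function(pixels, calibration, name = "image") {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] < 3L) stop("RGB image needs 3 planes", call. = FALSE)
    pixels <- pixels[, , 1:3, drop = FALSE]
  } else if (!is.matrix(pixels)) {
    stop("`pixels` must be a matrix (gray) or h x w x 3 array (RGB)",
         call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("empty image", call. = FALSE)
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(calibration) || length(calibration) != 1L ||
      calibration <= 0) {
    stop("`calibration` must be a positive scalar (um/pixel)", call. = FALSE)
  }
  structure(list(pixels = pixels, calibration = calibration,
                 name = as.character(name)),
            class = "calibrated_image")
}

is_rgb <- function(img) length(dim(img$pixels)) == 3L

image_window <- function(img) {
  d <- dim(img$pixels)
  c(d[2], d[1]) * img$calibration  # width, height in um
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(if (is_rgb(x)) "RGB" else "Grayscale", " image `", x$name, "`: ",
      d[2], " x ", d[1], " px at ", x$calibration, " um/px (",
      signif(d[2] * x$calibration, 4), " x ", signif(d[1] * x$calibration, 4),
      " um)\n", sep = "")
  invisible(x)
}

#' Read a TIFF or PNG micrograph with a spatial calibration
#'
#' 8-bit grayscale or RGB images are supported; intensities are rescaled to
#' `[0, 255]`. An alpha plane, if present, is dropped.
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @param calibration micrometers per pixel.
#' @param name image name; defaults to the file name.
#' @return a [calibrated_image()].
#' @export
read_image <- function(path, calibration, name = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format `.", ext, "` (use TIFF or PNG)",
         call. = FALSE)
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] %in% c(2L, 4L)) {
    raw <- raw[, , seq_len(dim(raw)[3] - 1L), drop = FALSE]  # drop alpha
  }
  if (length(dim(raw)) == 3L && dim(raw)[3] == 1L) raw <- raw[, , 1]
  calibrated_image(raw * 255, calibration, name)
}

#' Write an image or label matrix to TIFF/PNG
#'
#' Intensities are rescaled from `[0, 255]` (images) or label ids (label
#' images, scaled to their maximum) to the file's `[0, 1]` range.
#'
#' @param x a `calibrated_image`, plain matrix/array in `[0, 255]`, or an
#'   integer label matrix.
#' @param path output path; format chosen by extension.
#' @export
write_image <- function(x, path) {
  px <- if (inherits(x, "calibrated_image")) x$pixels else x
  mx <- max(px, 1)
  scaled <- px / if (mx <= 255) 255 else mx   # labels may exceed 255
  scaled[scaled > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
    png = png::writePNG(scaled, path),
    stop("unsupported image format `.", ext, "`", call. = FALSE)
  )
  invisible(path)
}
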