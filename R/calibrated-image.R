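#' Calibrated 2D intensity image
#'
#' A `calibrated_image` is a numeric matrix of non-negative intensities with a
#' physical pixel size in micrometres per pixel. Rows index the image y axis,
#' columns the x axis; coordinates are 0-based `(row, col)` where exposed.
#' Synthetic generators attach their ground truth (masks, counts, parameters)
#' as the `ground_truth` attribute so downstream measurements can be validated
#' against an independent record of how the image was built.
#'
#' @param x Numeric matrix of intensities (non-negative, finite).
#' @param pixel_size Pixel side length in micrometres per pixel (> 0).
#' @param ground_truth Optional named list of generator ground truth.
#'
#' @return An object of class `calibrated_image` (a matrix with attributes
#'   `pixel_size` and optionally `ground_truth`).
#' @export
#'
#' @examples
#' img <- calibrated_image(matrix(runif(64), 8, 8), pixel_size = 0.5)
#' pixel_size(img)
calibrated_image <- function(x, pixel_size = 1, ground_truth = NULL) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L) {
    abort("`x` must be a non-empty numeric matrix.")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("image intensities must be finite and non-missing.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a single finite positive number (um/px).")
  }
  structure(
    x,
    pixel_size = as.numeric(pixel_size),
    ground_truth = ground_truth,
    class = c("calibrated_image", class(matrix()))
  )
}

#' @rdname calibrated_image
#' @param img A `calibrated_image`.
#' @export
pixel_size <- function(img) {
  ps <- attr(img, "pixel_size")
  if (is.null(ps)) 1 else ps
}

#' @rdname calibrated_image
#' @export
ground_truth <- function(img) attr(img, "ground_truth")

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "<calibrated_image> %d x %d px, %.4g um/px, intensity [%.4g, %.4g]%s\n",
    nrow(x), ncol(x), pixel_size(x), min(x), max(x),
    if (is.null(ground_truth(x))) "" else ", with ground truth"
  ))
  invisible(x)
}

#' @export
as.matrix.calibrated_image <- function(x, ...) as_image_matrix(x)

is_calibrated_image <- function(x) inherits(x, "calibrated_image")

as_image_matrix <- function(img) {
  if (is_calibrated_image(img)) {
    attributes(img) <- list(dim = dim(img))
  }
  img
}

#' Write and read calibrated images as TIFF with a JSON sidecar
#'
#' Images are written as single-channel unsigned 16-bit TIFF; intensities are
#' linearly rescaled to the 16-bit range on write and the scale recorded, with
#' the pixel size, in `<path>.json` so that `read_calibrated_tiff()` restores
#' the original floating-point values and calibration.
#'
#' @param img A [calibrated_image()].
#' @param path Output file path (`.tif`/`.tiff`).
#' @return `write_calibrated_tiff()` returns `path` invisibly;
#'   `read_calibrated_tiff()` returns a [calibrated_image()].
#' @export
write_calibrated_tiff <- function(img, path) {
  stopifnot(is_calibrated_image(img))
  m <- as_image_matrix(img)
  lo <- min(m)
  hi <- max(m)
  scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  # tiff maps [0,1] onto the full unsigned 16-bit range
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    pixel_size_um = pixel_size(img),
    intensity_min = lo,
    intensity_max = hi,
    bits_per_sample = 16L
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibrated_tiff
#' @export
read_calibrated_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m <- m * (sidecar$intensity_max - sidecar$intensity_min) +
    sidecar$intensity_min
  calibrated_image(m, pixel_size = sidecar$pixel_size_um)
}
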