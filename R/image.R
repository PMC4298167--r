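#' Calibrated 8-bit image
#'
#' The pipeline's working currency: a 2D 8-bit intensity raster together
#' with its acquisition modality, an optional spatial calibration and a
#' source identifier. Pixel values are integers in `[0, 255]`, stored as a
#' `[row, col]` matrix with the origin at the top-left.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]` (integers).
#' @param modality `"fluorescence"` or `"brightfield"`.
#' @param calibration Optional micrometers-per-pixel scalar (> 0, finite).
#' @param source_id Identifier string (usually the file name).
#'
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(80L, 64, 64))
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, modality = "fluorescence",
                             calibration = NULL, source_id = "image") {
  stopifnot(is.matrix(pixels))
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    stop(sprintf("image '%s' is %dx%d; images smaller than 64x64 are rejected",
                 source_id, nrow(pixels), ncol(pixels)))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  if (any(pixels != floor(pixels))) {
    stop("pixel intensities must be integers (8-bit)")
  }
  modality <- match.arg(modality, c("fluorescence", "brightfield"))
  if (!is.null(calibration)) {
    stopifnot("calibration must be a positive finite scalar" =
                length(calibration) == 1 && is.finite(calibration) && calibration > 0)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels,
                 height = nrow(pixels), width = ncol(pixels),
                 modality = modality,
                 calibration = calibration,
                 source_id = as.character(source_id)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> '%s' %dx%d, %s%s\n", x$source_id,
              x$height, x$width, x$modality,
              if (is.null(x$calibration)) ""
              else sprintf(", %.4g um/px", x$calibration)))
  invisible(x)
}

#' Convert an RGB raster to an 8-bit grayscale image
#'
#' Applies the standard luminance weighting
#' `0.299 R + 0.587 G + 0.114 B`, rounding half up.
#'
#' @param rgb_pixels A `height x width x 3` array with channel values in
#'   `[0, 255]`.
#' @param ... Passed to [calibrated_image()] (modality, calibration,
#'   source_id).
#' @return A `calibrated_image`.
#' @examples
#' a <- array(c(100, 150, 200), dim = c(1, 1, 3))[rep(1, 64), rep(1, 64), ]
#' to_grayscale(a)$pixels[1, 1]  # 141
#' @export
to_grayscale <- function(rgb_pixels, ...) {
  stopifnot(length(dim(rgb_pixels)) == 3, dim(rgb_pixels)[3] == 3)
  if (anyNA(rgb_pixels) || min(rgb_pixels) < 0 || max(rgb_pixels) > 255) {
    stop("RGB channel values must lie in [0, 255]")
  }
  g <- 0.299 * rgb_pixels[, , 1] + 0.587 * rgb_pixels[, , 2] + 0.114 * rgb_pixels[, , 3]
  calibrated_image(clip8(round_half_up(g)), ...)
}

#' Load a micrograph from disk
#'
#' Reads a TIFF, PNG or JPEG raster and normalizes it to the pipeline's
#' 8-bit grayscale working format. RGB inputs are converted with
#' [to_grayscale()]; inputs of bit depth greater than 8 (e.g. 16-bit TIFF)
#' are linearly min-max rescaled to `[0, 255]`.
#'
#' @param path Path to the image file.
#' @param params A [pipeline_params()]; modality and calibration are copied
#'   onto the returned image.
#' @return A `calibrated_image`.
#' @export
load_image <- function(path, params = pipeline_params()) {
  if (!file.exists(path)) stop(sprintf("image file '%s' does not exist", path))
  e <- tryCatch(EBImage::readImage(path),
                error = function(err)
                  stop(sprintf("cannot read image '%s': %s", path,
                               conditionMessage(err))))
  d <- dim(e)
  a <- EBImage::imageData(e)  # values in [0, 1], dims (x, y[, c])
  grab <- function(channel_slice) t(channel_slice) * 255
  if (length(d) == 2) {
    g255 <- grab(a)
    g <- .rescale_depth(g255)
  } else if (length(d) == 3 && d[3] >= 3) {
    rgb <- array(0, dim = c(d[2], d[1], 3))
    for (k in 1:3) rgb[, , k] <- .rescale_depth(grab(a[, , k]))
    g <- to_grayscale(rgb)$pixels
  } else if (length(d) == 3 && d[3] == 1) {
    g <- .rescale_depth(grab(a[, , 1]))
  } else {
    stop(sprintf("unsupported image layout in '%s' (dims: %s)", path,
                 paste(d, collapse = "x")))
  }
  if (nrow(g) < 64 || ncol(g) < 64) {
    stop(sprintf("image '%s' is %dx%d; images smaller than 64x64 are rejected",
                 path, nrow(g), ncol(g)))
  }
  calibrated_image(g, modality = params$modality,
                   calibration = params$calibration,
                   source_id = basename(path))
}

# Values arrive scaled to [0, 255] from the reader's [0, 1] normalization.
# 8-bit sources land exactly on integers; deeper sources do not and are
# min-max rescaled to the full 8-bit range.
.rescale_depth <- function(v255) {
  if (max(abs(v255 - round(v255))) < 1e-6) return(round(v255))
  lo <- min(v255); hi <- max(v255)
  if (hi <= lo) return(matrix(0L, nrow(v255), ncol(v255)))
  round_half_up((v255 - lo) / (hi - lo) * 255)
}
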