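#' Gaussian denoising filter
#'
#' Convolves the image with a normalized Gaussian kernel (support truncated
#' at about 3.5 sigma), replicating edge pixels at the boundary, and
#' re-quantizes to 8 bits (round half up). `sigma = 0` returns the input
#' unchanged.
#'
#' @param img A `calibrated_image`.
#' @param sigma Kernel standard deviation in pixels (>= 0).
#' @return A `calibrated_image`.
#' @export
gaussian_smooth <- function(img, sigma = 2) {
  stopifnot(inherits(img, "calibrated_image"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  size <- 2L * as.integer(ceiling(3.5 * sigma)) + 1L
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  e <- EBImage::filter2(.as_ebi(img$pixels, scale = 255), k, boundary = "replicate")
  out <- clip8(round_half_up(.from_ebi(e, scale = 255)))
  calibrated_image(out, modality = img$modality, calibration = img$calibration,
                   source_id = img$source_id)
}

#' Automatic contrast enhancement
#'
#' Linear histogram stretch: the `saturation` quantile of the pixel values
#' maps to 0 and the `1 - saturation` quantile to 255, clipping outside.
#' Constant images are returned unchanged.
#'
#' @param img A `calibrated_image`.
#' @param saturation Fraction of pixels saturated at each tail, in
#'   `[0, 0.5)`.
#' @return A `calibrated_image`.
#' @export
enhance_contrast <- function(img, saturation = 0.0035) {
  stopifnot(inherits(img, "calibrated_image"))
  if (saturation < 0 || saturation >= 0.5) stop("saturation must be in [0, 0.5)")
  v <- as.vector(img$pixels)
  n <- length(v)
  s <- sort(v)
  lo <- s[min(n, floor(saturation * n) + 1)]
  hi <- s[max(1, ceiling((1 - saturation) * n))]
  if (hi <= lo) return(img)
  out <- clip8(round_half_up((img$pixels - lo) / (hi - lo) * 255))
  calibrated_image(out, modality = img$modality, calibration = img$calibration,
                   source_id = img$source_id)
}

# Exhaustive between-class-variance (Otsu) threshold on an 8-bit intensity
# vector. Returns the threshold t in 0..254 maximizing the between-class
# variance of the split {v <= t} / {v > t}. When a range of thresholds
# ties (an empty intensity gap between the classes), the midpoint of the
# tied range is used, placing the cut centrally in the gap.
otsu_threshold <- function(values) {
  h <- as.numeric(tabulate(as.integer(values) + 1L, nbins = 256L))
  n <- sum(h)
  if (n == 0) return(127L)
  lev <- 0:255
  w0 <- cumsum(h)               # count of values <= t
  m0 <- cumsum(h * lev)         # intensity sum of values <= t
  total <- m0[256]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(127L) # constant image
  mu0 <- m0 / pmax(w0, 1)
  mu1 <- (total - m0) / pmax(w1, 1)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  bcv <- bcv[1:255]             # thresholds t = 0..254
  tied <- which(bcv == max(bcv)) - 1L
  as.integer(floor(mean(tied) + 0.5))
}

#' Threshold an image into a binary mask
#'
#' Foreground are the pixels strictly above the threshold. For
#' `brightfield` modality the image is inverted (`255 - v`) before
#' thresholding, so that structures of interest are bright in both
#' modalities. Without an override the threshold is chosen automatically by
#' between-class variance maximization (Otsu) over the 8-bit histogram.
#'
#' @param img A `calibrated_image`.
#' @param threshold_override Optional manual threshold in `[0, 255]`.
#' @return A logical `[row, col]` mask with attributes `threshold` (the
#'   level used) and `degenerate` (`TRUE` when the result is all-foreground
#'   or all-background, a warning carried downstream).
#' @export
binarize <- function(img, threshold_override = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  v <- img$pixels
  if (img$modality == "brightfield") v <- 255L - v
  if (is.null(threshold_override)) {
    thr <- otsu_threshold(v)
  } else {
    if (threshold_override < 0 || threshold_override > 255)
      stop("threshold_override must be in [0, 255]")
    thr <- as.integer(threshold_override)
  }
  mask <- v > thr
  degenerate <- all(mask) || !any(mask)
  attr(mask, "threshold") <- thr
  attr(mask, "degenerate") <- degenerate
  mask
}

#' Smooth a binary selection by morphological closing
#'
#' Dilates then erodes the mask with a disk structuring element of the
#' given radius (the classical "enlarge then decrease" smoothing).
#' `radius = 0` is the identity.
#'
#' @param mask Logical `[row, col]` mask.
#' @param radius Disk radius in pixels (>= 0).
#' @return A logical mask of the same dimensions.
#' @export
smooth_selection <- function(mask, radius = 3) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (radius < 0) stop("radius must be >= 0")
  radius <- as.integer(radius)
  if (radius == 0 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- .ebi_mask(EBImage::closing(.mask_ebi(mask), brush))
  attributes(out) <- attributes(mask)[c("dim")]
  dim(out) <- dim(mask)
  out
}

# The fixed preprocessing chain: Gaussian -> contrast -> threshold.
# Returns list(image = enhanced grayscale, mask = binary, threshold, degenerate).
.preprocess_chain <- function(img, params) {
  sm <- gaussian_smooth(img, params$gaussian_sigma)
  en <- enhance_contrast(sm, params$contrast_saturation)
  mask <- binarize(en, params$threshold_override)
  list(image = en, mask = mask,
       threshold = attr(mask, "threshold"),
       degenerate = attr(mask, "degenerate"))
}
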