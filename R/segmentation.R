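# Region selections: labelled filled regions with contour and area.

.region_selection <- function(label, mask, calibration = NULL,
                              warnings = character(0)) {
  area_px <- sum(mask)
  comps <- if (area_px > 0) max(.label_components(mask)) else 0L
  structure(list(
    label = label,
    mask = mask,
    contour = .mask_contours(mask),
    area_px = as.integer(area_px),
    area_units = if (is.null(calibration)) NULL else area_px * calibration^2,
    n_components = as.integer(max(comps, 1L)),
    warnings = warnings
  ), class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(sprintf("<region_selection> %s: %d px, %d component(s)%s\n",
              x$label, x$area_px, x$n_components,
              if (length(x$warnings)) paste0(" [", length(x$warnings), " warning(s)]") else ""))
  invisible(x)
}

# Largest connected component; ties broken by smaller centroid row then
# smaller centroid column (deterministic).
.largest_component <- function(mask) {
  lab <- .label_components(mask)
  n <- max(lab)
  if (n == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    cent <- t(vapply(best, function(l) .mask_centroid(lab == l), numeric(2)))
    best <- best[order(cent[, 1], cent[, 2])][1]
  }
  lab == best[1]
}

# Which image borders (top/bottom/left/right) a mask touches.
.borders_touched <- function(mask) {
  c(top = any(mask[1, ]), bottom = any(mask[nrow(mask), ]),
    left = any(mask[, 1]), right = any(mask[, ncol(mask)]))
}

#' Select the whole root section
#'
#' Runs the fixed preprocessing chain (Gaussian filter, contrast
#' enhancement, automatic or overridden threshold), keeps the largest
#' connected foreground component, fills its interior holes and smooths
#' the selection by morphological closing. The result is the filled root
#' disk bounded by the outermost bright cell wall.
#'
#' @param img A `calibrated_image`.
#' @param params A [pipeline_params()].
#' @return A `region_selection` labelled `"root"`.
#' @export
select_root <- function(img, params = pipeline_params()) {
  pp <- .preprocess_chain(img, params)
  warnings <- character(0)
  if (!any(pp$mask)) {
    stop(sprintf("root selection failed for '%s': no foreground at threshold %d",
                 img$source_id, pp$threshold))
  }
  if (pp$degenerate) warnings <- c(warnings, "threshold produced a degenerate (all-foreground) mask")
  comp <- .largest_component(pp$mask)
  touched <- .borders_touched(comp)
  if (sum(touched) >= 2) {
    stop(sprintf("root selection failed for '%s': section truncated (touches %s borders)",
                 img$source_id, paste(names(touched)[touched], collapse = "+")))
  }
  comp <- .fill_holes(comp)
  comp <- smooth_selection(comp, params$smoothing_radius)
  comp <- .fill_holes(comp)
  .region_selection("root", comp, params$calibration, warnings)
}

# Second central moments of a mask -> list(centroid, axes (unit rows),
# sdev (sqrt eigenvalues, major first)).
.mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mu <- colMeans(idx)
  d <- sweep(idx, 2, mu)
  cov <- crossprod(d) / nrow(d)
  eg <- eigen(cov, symmetric = TRUE)
  list(centroid = mu, axes = t(eg$vectors), sdev = sqrt(pmax(eg$values, 1e-12)))
}

#' Draw the oval stele selection
#'
#' The stele is modelled as a filled ellipse centered at the root
#' centroid, with orientation and axis ratio taken from the root mask's
#' second central moments, sized so that root area / stele area equals
#' `proportion` (the macro's default proportion is 4). For a circular root
#' this reduces to a concentric disk. An ellipse not fully contained in
#' the root is shrunk to fit, with a warning.
#'
#' @param root The root `region_selection`.
#' @param proportion Root-area / stele-area ratio (> 1).
#' @param calibration Optional micrometers per pixel.
#' @return A `region_selection` labelled `"stele"`.
#' @export
select_stele <- function(root, proportion = 4, calibration = NULL) {
  stopifnot(inherits(root, "region_selection"), root$n_components == 1)
  if (proportion <= 1) stop("stele proportion must be > 1")
  mo <- .mask_moments(root$mask)
  target <- root$area_px / proportion
  ratio <- mo$sdev[1] / mo$sdev[2]          # major/minor axis ratio
  b <- sqrt(target / (pi * ratio))
  a <- b * ratio
  warnings <- character(0)
  mask <- .ellipse_mask(dim(root$mask), mo$centroid, mo$axes, a, b)
  shrink <- 0L
  while (any(mask & !root$mask) && shrink < 60) {
    a <- a * 0.98; b <- b * 0.98; shrink <- shrink + 1L
    mask <- .ellipse_mask(dim(root$mask), mo$centroid, mo$axes, a, b)
  }
  if (shrink > 0) warnings <- "stele ellipse shrunk to fit inside the root"
  .region_selection("stele", mask, calibration, warnings)
}

# Rasterize a filled ellipse: pixel centers with normalized radius <= 1.
# axes: 2x2 matrix whose rows are the unit major/minor directions.
.ellipse_mask <- function(dims, centroid, axes, a, b) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2]) - centroid[1]
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - centroid[2]
  u <- rr * axes[1, 1] + cc * axes[1, 2]
  v <- rr * axes[2, 1] + cc * axes[2, 2]
  (u / a)^2 + (v / b)^2 <= 1
}

#' Select and count the central metaxylem vessels
#'
#' Inside the stele (eroded slightly so the pericycle boundary wall does
#' not interfere), the image is re-thresholded on stele pixels only, the
#' result is closed and hole-filled per component, and components are kept
#' when they are large enough (`min_cmx_area`) and round enough
#' (circularity `4*pi*A/P^2 >= min_cmx_circularity`). `manual_ncm`
#' replaces the automatic count while the selection is retained.
#'
#' @param img A `calibrated_image`.
#' @param stele The stele `region_selection`.
#' @param params A [pipeline_params()].
#' @return List with `selection` (a `region_selection` labelled
#'   `"central_metaxylem"`) and `ncm` (vessel count).
#' @export
select_central_metaxylem <- function(img, stele, params = pipeline_params()) {
  stopifnot(inherits(img, "calibrated_image"), inherits(stele, "region_selection"))
  warnings <- character(0)
  # vessel walls are only a few px thick; threshold the unsmoothed image —
  # the tissue-scale blur erases thin wall ridges, and the closing plus
  # area/circularity filters already absorb pixel noise
  pp_img <- enhance_contrast(img, params$contrast_saturation)
  v <- pp_img$pixels
  if (img$modality == "brightfield") v <- 255L - v
  inner <- .ebi_mask(EBImage::erode(.mask_ebi(stele$mask),
                                    EBImage::makeBrush(9L, "disc")))
  if (!any(inner)) {
    return(list(selection = .region_selection("central_metaxylem", stele$mask & FALSE,
                                              params$calibration,
                                              "stele too small for metaxylem search"),
                ncm = 0L))
  }
  thr <- if (is.null(params$threshold_override)) otsu_threshold(v[inner])
         else as.integer(params$threshold_override)
  cand <- (v > thr) & inner
  cand <- smooth_selection(cand, params$smoothing_radius)
  lab <- .label_components(cand)
  keep <- cand & FALSE
  ncm <- 0L
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      comp <- .fill_holes(lab == l)
      # vessels are interior structures; discard anything hugging the search rim
      if (any(comp & !inner)) next
      A <- sum(comp)
      if (A < params$min_cmx_area) next
      ctr <- .mask_contours(comp)
      P <- .polygon_perimeter(ctr[[1]])
      if (P <= 0) next
      circ <- 4 * pi * A / P^2
      if (circ < params$min_cmx_circularity) next
      keep <- keep | comp
      ncm <- ncm + 1L
    }
  }
  if (ncm == 0L) warnings <- c(warnings, "no central metaxylem vessel detected")
  if (!is.null(params$manual_ncm)) ncm <- params$manual_ncm
  sel <- .region_selection("central_metaxylem", keep, params$calibration, warnings)
  sel$n_components <- max(ncm, if (any(keep)) 1L else 0L)
  list(selection = sel, ncm = as.integer(ncm))
}

# Per-angle outer extent (radius, px) of a mask in polar coordinates
# around `center`: the largest radius whose bilinear sample of the 0/1
# mask is >= 0.5.
.polar_extent <- function(mask, center, n_angles, r_max) {
  m01 <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  img <- structure(list(pixels = m01, height = nrow(mask), width = ncol(mask),
                        modality = "fluorescence", calibration = NULL,
                        source_id = "mask"), class = "calibrated_image")
  pol <- polar_transform(img, center, n_angles, r_max)
  apply(pol$pixels >= 0.5, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) 0 else max(w) - 1
  })
}

#' Select the cortex (tissue internal to the sclerenchyma)
#'
#' Works in polar coordinates about the stele centroid: for each angle the
#' radially outermost strong intensity band of sufficient thickness within
#' the outer portion of the local root radius is taken as the sclerenchyma;
#' the cortex boundary is that band's inner edge, median-filtered over
#' angle, and the returned region is the filled area inside this boundary
#' (always containing the stele). When the band cannot be found for more
#' than a quarter of the angles the selection falls back to the root mask
#' eroded by a default external-layer thickness, with a warning.
#'
#' @param img A `calibrated_image`.
#' @param root The root `region_selection`.
#' @param stele The stele `region_selection`.
#' @param params A [pipeline_params()].
#' @param search_fraction Outer fraction of the local root radius searched
#'   for the sclerenchyma band.
#' @param min_band_px Minimum radial thickness (px) of a candidate band.
#' @param median_width Angular median-filter width (samples, odd).
#' @param fallback_thickness Erosion depth (px) of the fallback selection.
#' @return A `region_selection` labelled `"cortex"`.
#' @export
select_cortex <- function(img, root, stele, params = pipeline_params(),
                          search_fraction = 0.35, min_band_px = 4L,
                          median_width = 9L, fallback_thickness = 20L) {
  stopifnot(inherits(img, "calibrated_image"),
            inherits(root, "region_selection"),
            inherits(stele, "region_selection"))
  warnings <- character(0)
  pp_img <- enhance_contrast(gaussian_smooth(img, params$gaussian_sigma),
                             params$contrast_saturation)
  v <- pp_img$pixels
  if (img$modality == "brightfield") v <- 255L - v
  center <- .mask_centroid(stele$mask)
  na <- params$n_angles
  r_max <- as.integer(ceiling(max(dim(v)) / 2))
  vimg <- structure(list(pixels = matrix(as.numeric(v), nrow(v), ncol(v)),
                         height = nrow(v), width = ncol(v),
                         modality = "fluorescence", calibration = NULL,
                         source_id = img$source_id), class = "calibrated_image")
  pol <- polar_transform(vimg, center, na, r_max)
  root_r <- .polar_extent(root$mask, center, na, r_max)
  stele_r <- .polar_extent(stele$mask, center, na, r_max)

  # threshold separating wall from tissue, from the searched annulus only
  rowsets <- lapply(seq_len(na), function(a) {
    lo <- floor((1 - search_fraction) * root_r[a]); hi <- root_r[a]
    if (hi <= lo + 1) return(integer(0))
    (lo:hi) + 1L
  })
  win_vals <- unlist(lapply(seq_len(na), function(a) pol$pixels[rowsets[[a]], a]))
  if (length(win_vals) < 10) {
    boundary <- NULL
  } else {
    thr <- otsu_threshold(clip8(round_half_up(win_vals)))
    # a genuine wall/tissue split sits well above the window's bulk
    # intensity; otherwise the annulus holds no bright band at all
    if (thr < 1.25 * stats::median(win_vals)) thr <- Inf
    boundary <- vapply(seq_len(na), function(a) {
      rows <- rowsets[[a]]
      if (length(rows) == 0) return(NA_real_)
      bright <- pol$pixels[rows, a] > thr
      r <- rle(bright)
      if (!any(r$values & r$lengths >= min_band_px)) return(NA_real_)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      ok <- which(r$values & r$lengths >= min_band_px)
      j <- ok[length(ok)]                 # outermost qualifying band
      rows[starts[j]] - 1                 # inner edge, as a radius
    }, numeric(1))
  }
  n_missing <- if (is.null(boundary)) na else sum(is.na(boundary))
  if (n_missing > 0.25 * na) {
    warnings <- c(warnings, sprintf(
      "sclerenchyma band undetected for %d/%d angles; falling back to eroded root", n_missing, na))
    mask <- .ebi_mask(EBImage::erode(.mask_ebi(root$mask),
                                     EBImage::makeBrush(2L * fallback_thickness + 1L, "disc")))
    mask <- mask | stele$mask
    mask <- .fill_holes(.largest_component(mask))
    return(.region_selection("cortex", mask, params$calibration, warnings))
  }
  if (n_missing > 0) boundary <- .fill_circular_na(boundary)
  boundary <- .circular_median(boundary, median_width)
  boundary <- pmax(boundary, stele_r + 1)   # cortex must contain the stele

  # rasterize: pixel inside iff its radius < boundary at its angle
  H <- nrow(v); W <- ncol(v)
  rr <- matrix(seq_len(H), H, W) - center[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  rad <- sqrt(rr^2 + cc^2)
  ang <- atan2(-rr, cc) %% (2 * pi)
  aidx <- (round_half_up(ang / pol$angular_step) %% na) + 1
  mask <- rad <= boundary[aidx]
  mask <- mask | stele$mask
  mask <- mask & root$mask
  mask <- .fill_holes(.largest_component(mask))
  .region_selection("cortex", mask, params$calibration, warnings)
}

# Linear interpolation across NA runs of a circular sequence.
.fill_circular_na <- function(x) {
  n <- length(x)
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  ext_i <- c(idx, idx[1] + n)
  ext_v <- c(x[idx], x[idx[1]])
  out <- x
  for (i in which(is.na(x))) {
    ii <- if (i < idx[1]) i + n else i
    out[i] <- stats::approx(ext_i, ext_v, xout = ii)$y
  }
  out
}

# Circular running median, window width w (odd).
.circular_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  xx <- c(x[(n - h + 1):n], x, x[1:h])
  vapply(seq_len(n), function(i) stats::median(xx[i:(i + 2 * h)]), numeric(1))
}

#' Derived area arithmetic
#'
#' Computes the external layer area `ELA = ROOTA - cortex_measured`
#' (epidermis + exodermis + sclerenchyma) and the cortex proper
#' `CTXA = cortex_measured - STELEA`. With a calibration `c` (micrometers
#' per pixel) each area is scaled by `c^2`.
#'
#' @param root,stele,cmx,cortex `region_selection`s.
#' @param calibration Optional micrometers per pixel.
#' @return An object of class `area_set`: list with `roota`, `ela`,
#'   `ctxa`, `stelea`, `cma`, `cortex_measured`, `unit`.
#' @export
compute_areas <- function(root, stele, cmx, cortex, calibration = NULL) {
  roota <- root$area_px
  stelea <- stele$area_px
  cma <- cmx$area_px
  cortex_measured <- cortex$area_px
  if (cortex_measured > roota) stop("violated ordering: cortex_measured > ROOTA")
  if (stelea > cortex_measured) stop("violated ordering: STELEA > cortex_measured")
  if (cma > stelea) stop("violated ordering: CMA > STELEA")
  scale <- if (is.null(calibration)) 1 else calibration^2
  structure(list(
    roota = roota * scale,
    ela = (roota - cortex_measured) * scale,
    ctxa = (cortex_measured - stelea) * scale,
    stelea = stelea * scale,
    cma = cma * scale,
    cortex_measured = cortex_measured * scale,
    unit = if (is.null(calibration)) "px" else "um2"
  ), class = "area_set")
}
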