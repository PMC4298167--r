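#' Write the measurement table
#'
#' Tab-separated table, one row per analyzed image. Columns:
#' `image_id`, `unit`, then the standard abbreviations `ROOTA`, `ELA`,
#' `CTXA`, `STELEA`, `CMA`, `NCM`, `NM`, `NCL`, `NCF1..NCFk` (k = the
#' largest number of counted files among the records). Areas are written
#' as integers in pixel units and with 2 decimals in square micrometers;
#' `NCL` with 2 decimals; a missing manual metaxylem count is `NA`.
#'
#' @param records List of `measurement_record`s (a single record is
#'   accepted), sharing one unit mode.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (inherits(records, "measurement_record")) records <- list(records)
  k <- if (length(records) == 0) 0L else max(vapply(records, function(r) length(r$ncf), integer(1)))
  if (length(records) > 1) {
    units <- unique(vapply(records, function(r) r$unit, character(1)))
    if (length(units) > 1) stop("records mix unit modes: ", paste(units, collapse = ", "))
  }
  header <- c("image_id", "unit", "ROOTA", "ELA", "CTXA", "STELEA", "CMA",
              "NCM", "NM", "NCL", if (k > 0) paste0("NCF", seq_len(k)))
  lines <- vapply(records, function(r) {
    fmt_area <- function(a) if (r$unit == "px") sprintf("%d", as.integer(round_half_up(a)))
                            else sprintf("%.2f", a)
    ncf <- rep(NA_integer_, k)
    if (length(r$ncf)) ncf[seq_along(r$ncf)] <- r$ncf
    paste(c(r$image_id, r$unit,
            fmt_area(r$roota), fmt_area(r$ela), fmt_area(r$ctxa),
            fmt_area(r$stelea), fmt_area(r$cma),
            sprintf("%d", r$ncm),
            ifelse(is.na(r$nm), "NA", sprintf("%d", r$nm)),
            sprintf("%.2f", r$ncl),
            ifelse(is.na(ncf), "NA", sprintf("%d", ncf))),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' Export selections and counting lines as a ROI JSON document
#'
#' A portable, re-loadable record of the analysis: per selection the
#' label, closed contour vertex list (1-based row/col pixel coordinates),
#' pixel area and calibrated area; per counting line its orientation,
#' geometry, maxima positions and raw/extrapolated counts; plus the
#' measurement row itself.
#'
#' @param record A `measurement_record` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_rois <- function(record, path) {
  stopifnot(inherits(record, "measurement_record"))
  det <- record$detail
  sels <- lapply(det$selections, function(s) list(
    label = s$label,
    area_px = s$area_px,
    area_units = s$area_units,
    n_components = s$n_components,
    contour = lapply(s$contour, function(p) list(row = p[, 1], col = p[, 2]))
  ))
  prof_json <- function(p) list(
    orientation = p$orientation,
    fixed_coord = p$fixed_coord,
    span = p$span,
    maxima = p$maxima,
    raw_count = p$raw_count,
    coverage = p$coverage,
    extrapolated_count = p$extrapolated_count,
    noise_tolerance = p$noise_tolerance
  )
  doc <- list(
    image_id = record$image_id,
    unit = record$unit,
    measurements = list(roota = record$roota, ela = record$ela,
                        ctxa = record$ctxa, stelea = record$stelea,
                        cma = record$cma, ncm = record$ncm,
                        nm = record$nm, ncl = record$ncl, ncf = record$ncf),
    polar_center = det$polar_center,
    file_radii = det$file_radii,
    selections = sels,
    counting_lines = c(lapply(det$layer_profiles, prof_json),
                       lapply(det$file_profiles, prof_json)),
    warnings = record$warnings
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a ROI JSON document
#'
#' @param path Path written by [export_rois()].
#' @return The parsed document (list).
#' @export
load_rois <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' Render a review overlay
#'
#' Writes the grayscale image with the region contours superimposed in
#' yellow (root, cortex, stele, central metaxylem edges), the layer-line
#' maxima as magenta dots and the cell-file maxima as green dots, for
#' after-the-fact review of an unattended batch run.
#'
#' @param img The analyzed `calibrated_image`.
#' @param record The `measurement_record` from [run_pipeline()].
#' @param path Output raster path (PNG recommended).
#' @return `path`, invisibly.
#' @export
export_overlay <- function(img, record, path) {
  stopifnot(inherits(img, "calibrated_image"),
            inherits(record, "measurement_record"))
  g <- img$pixels / 255
  R <- g; G <- g; B <- g
  paint <- function(rc, col_rgb, thick = FALSE) {
    if (is.null(rc) || nrow(rc) == 0) return()
    pts <- rc
    if (thick) {
      pts <- rbind(rc, cbind(rc[, 1] + 1, rc[, 2]), cbind(rc[, 1], rc[, 2] + 1),
                   cbind(rc[, 1] - 1, rc[, 2]), cbind(rc[, 1], rc[, 2] - 1))
    }
    ok <- pts[, 1] >= 1 & pts[, 1] <= nrow(R) & pts[, 2] >= 1 & pts[, 2] <= ncol(R)
    pts <- pts[ok, , drop = FALSE]
    idx <- cbind(pts[, 1], pts[, 2])
    R[idx] <<- col_rgb[1]; G[idx] <<- col_rgb[2]; B[idx] <<- col_rgb[3]
  }
  for (s in record$detail$selections) {
    for (ctr in s$contour) paint(ctr, c(1, 1, 0))       # yellow contours
  }
  center <- record$detail$polar_center
  # counting markers: convert (radius, angle index) back to image coordinates
  to_rc <- function(r, aidx, n_angles) {
    th <- (aidx - 1) * 2 * pi / n_angles
    cbind(round_half_up(center[1] - r * sin(th)),
          round_half_up(center[2] + r * cos(th)))
  }
  lp <- record$detail$layer_profiles
  fp <- record$detail$file_profiles
  n_angles <- if (length(fp)) length(fp[[1]]$profile) else 720L
  for (p in lp) paint(to_rc(p$maxima, p$fixed_coord, n_angles), c(1, 0, 1), thick = TRUE)
  for (p in fp) paint(to_rc(p$fixed_coord, p$maxima, n_angles), c(0, 1, 0), thick = TRUE)
  arr <- array(0, dim = c(ncol(R), nrow(R), 3))
  arr[, , 1] <- t(R); arr[, , 2] <- t(G); arr[, , 3] <- t(B)
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}
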