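#' Run the full analysis pipeline on one image
#'
#' Executes the sequential stages of the root cross-section analysis:
#' root selection, oval stele selection, central metaxylem selection and
#' count, cortex selection, area arithmetic, polar transformation about
#' the stele centroid, cell-layer counting on radial lines, automatic
#' cell-file placement and per-file cell counting. All stage warnings are
#' collected on the returned record. Deterministic for fixed parameters.
#'
#' @param img A `calibrated_image`.
#' @param params A [pipeline_params()].
#' @return An object of class `measurement_record`: `image_id`, `unit`,
#'   `roota`, `ela`, `ctxa`, `stelea`, `cma` (areas), `ncm`, `nm`
#'   (`NA` when no manual count was supplied), `ncl`, `ncf` (per-file
#'   counts), `warnings`, plus a `detail` element holding the selections
#'   and counting profiles for overlay/ROI export.
#' @export
run_pipeline <- function(img, params = pipeline_params()) {
  stopifnot(inherits(img, "calibrated_image"))
  warnings <- character(0)
  calib <- if (params$unit_mode == "calibrated") {
    if (!is.null(img$calibration)) img$calibration else params$calibration
  } else NULL
  if (params$unit_mode == "calibrated" && is.null(calib)) {
    stop(sprintf("'%s': calibrated units requested but no calibration available",
                 img$source_id))
  }

  root <- select_root(img, params)
  stele <- select_stele(root, params$stele_proportion, calib)
  cmx <- select_central_metaxylem(img, stele, params)
  cortex <- select_cortex(img, root, stele, params)
  areas <- compute_areas(root, stele, cmx$selection, cortex, calib)
  warnings <- c(warnings, root$warnings, stele$warnings,
                cmx$selection$warnings, cortex$warnings)

  # polar counting on the smoothed, contrast-enhanced image
  counting <- enhance_contrast(gaussian_smooth(img, params$gaussian_sigma),
                               params$contrast_saturation)
  v <- counting$pixels
  if (img$modality == "brightfield") v <- 255L - v
  cimg <- calibrated_image(v, source_id = img$source_id)
  center <- .mask_centroid(stele$mask)
  na <- params$n_angles
  r_max <- as.integer(ceiling(max(dim(v)) / 2))
  pol <- polar_transform(cimg, center, na, r_max)
  stele_r <- .polar_extent(stele$mask, center, na, r_max)
  cortex_r <- .polar_extent(cortex$mask, center, na, r_max)
  # the span runs from just inside the stele boundary wall into the
  # sclerenchyma band, which registers as the final maximum
  inner <- pmax(1, stele_r - 3)
  outer <- pmin(r_max, cortex_r + 6)

  layers <- count_layers(pol, inner, outer, params)
  warnings <- c(warnings, layers$warnings)

  placement <- place_file_radii(layers$profiles, params$n_cell_files,
                                override = params$file_radii)
  warnings <- c(warnings, placement$warnings)
  file_profiles <- lapply(placement$radii, function(r)
    count_cells_in_file(pol, r, span_fraction = 1, params = params))
  ncf <- vapply(file_profiles, function(p) p$extrapolated_count, integer(1))

  structure(list(
    image_id = img$source_id,
    unit = areas$unit,
    roota = areas$roota, ela = areas$ela, ctxa = areas$ctxa,
    stelea = areas$stelea, cma = areas$cma,
    ncm = cmx$ncm,
    nm = if (is.null(params$manual_nm)) NA_integer_ else params$manual_nm,
    ncl = layers$ncl,
    ncf = ncf,
    warnings = warnings,
    detail = list(
      selections = list(root = root, stele = stele,
                        central_metaxylem = cmx$selection, cortex = cortex),
      layer_profiles = layers$profiles,
      file_profiles = file_profiles,
      file_radii = placement$radii,
      polar_center = center
    )
  ), class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("<measurement_record> %s [%s]\n", x$image_id, x$unit))
  cat(sprintf("  ROOTA %.6g  ELA %.6g  CTXA %.6g  STELEA %.6g  CMA %.6g\n",
              x$roota, x$ela, x$ctxa, x$stelea, x$cma))
  cat(sprintf("  NCM %d  NM %s  NCL %.2f  NCF [%s]\n", x$ncm,
              ifelse(is.na(x$nm), "NA", x$nm), x$ncl,
              paste(x$ncf, collapse = ", ")))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Read a batch configuration file
#'
#' YAML or JSON with top-level parameter defaults and an optional
#' `images:` map of per-image (file name keyed) overrides; any field of
#' [pipeline_params()] may appear at either level.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return List with `defaults` and `images`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  images <- cfg$images
  cfg$images <- NULL
  list(defaults = cfg, images = if (is.null(images)) list() else images)
}

#' Analyze a batch of images
#'
#' Runs [run_pipeline()] on every image of a directory (or explicit file
#' list), applying global and per-image configuration overrides, and
#' writes the measurement table, per-image ROI JSON, optional review
#' overlays and a run log into `out_dir`. A failing image is recorded and
#' skipped; the batch continues.
#'
#' @param input Directory containing images, or a character vector of
#'   image paths.
#' @param params Base [pipeline_params()].
#' @param out_dir Output directory (created if needed).
#' @param config Optional result of [read_config()] (or a path to one).
#' @param overlay Write per-image overlay PNGs.
#' @return List with `records`, `failures` (named reasons) and
#'   `exit_status` (0 = all succeeded, 2 = partial failures).
#' @export
analyze_batch <- function(input, params = pipeline_params(), out_dir = ".",
                          config = NULL, overlay = TRUE) {
  paths <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "\\.(tiff?|png|jpe?g)$", ignore.case = TRUE,
               full.names = TRUE)
  } else input
  if (length(paths) == 0) stop("no input images found")
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(level, msg) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, msg)
    writeLines(line, log_con)
    if (params$verbose) message(line)
  }

  records <- list()
  failures <- character(0)
  for (path in paths) {
    id <- basename(path)
    p <- params
    if (!is.null(config)) {
      p <- .merge_params(p, config$defaults)
      p <- .merge_params(p, config$images[[id]])
    }
    logline("INFO", sprintf("%s: starting analysis", id))
    rec <- tryCatch({
      img <- load_image(path, p)
      run_pipeline(img, p)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      failures[id] <- rec
      logline("ERROR", sprintf("%s: %s", id, rec))
      next
    }
    for (w in rec$warnings) logline("WARN", sprintf("%s: %s", id, w))
    records[[id]] <- rec
    base <- tools::file_path_sans_ext(id)
    export_rois(rec, file.path(out_dir, paste0(base, "_rois.json")))
    if (overlay) {
      img <- load_image(path, p)
      export_overlay(img, rec, file.path(out_dir, paste0(base, "_overlay.png")))
    }
    logline("INFO", sprintf("%s: done (ROOTA=%g, NCL=%.2f)", id, rec$roota, rec$ncl))
  }
  if (length(records)) {
    write_table(records, file.path(out_dir, "measurements.tsv"))
  }
  status <- if (length(failures) == 0) 0L else 2L
  list(records = records, failures = failures, exit_status = status)
}
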