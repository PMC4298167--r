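#' Pipeline parameters
#'
#' Bundles every tunable of the analysis pipeline. Defaults follow the
#' conventions of the original supervised macro where it states them
#' (stele proportion 4, three layer-count lines, six cell files, pixel
#' units, fluorescence modality) and otherwise hold documented choices
#' (Gaussian sigma, contrast saturation, closing radius, noise tolerance).
#'
#' @param verbose Emit per-stage log messages.
#' @param modality `"fluorescence"` (bright cell walls on dark background,
#'   the default) or `"brightfield"` (inverted polarity; the image is
#'   inverted before thresholding and counting).
#' @param unit_mode `"pixel"` (areas in px) or `"calibrated"` (areas in
#'   square micrometers, requires a calibration).
#' @param stele_proportion Target ratio root area / stele area used to size
#'   the oval stele selection. Must exceed 1.
#' @param n_layer_lines Number of radial lines averaged for the cell-layer
#'   count.
#' @param n_cell_files Number of cell files (concentric rings) whose cells
#'   are counted.
#' @param noise_tolerance Minimum prominence (8-bit intensity levels) for a
#'   profile local maximum to count as a cell wall.
#' @param gaussian_sigma Standard deviation (px) of the Gaussian denoising
#'   filter; 0 disables it.
#' @param contrast_saturation Fraction of pixels saturated at each histogram
#'   tail by the automatic contrast stretch; in `[0, 0.5)`.
#' @param threshold_override Optional manual threshold in `[0, 255]`
#'   replacing the automatic (Otsu) choice.
#' @param smoothing_radius Disk radius (px) of the morphological closing
#'   that smooths binary selections; 0 disables it.
#' @param layer_offset Offset added to the per-line maxima count to obtain
#'   the layer count. A radial span crossing k layers crosses k + 1 bright
#'   periclinal walls, hence the default `-1`.
#' @param min_cmx_area Minimum component area (px) for a central metaxylem
#'   vessel candidate.
#' @param min_cmx_circularity Minimum circularity `4*pi*A/P^2` for a vessel
#'   candidate.
#' @param n_angles Angular samples of the polar transform (default 720,
#'   i.e. 0.5 degree steps).
#' @param manual_nm Optional user-supplied count of (peripheral) metaxylem
#'   vessels; reported as missing when absent, never zero.
#' @param manual_ncm Optional user-supplied count of central metaxylem
#'   vessels overriding the automatic count.
#' @param file_radii Optional explicit cell-file radii (px from the stele
#'   center) overriding automatic placement.
#' @param calibration Optional spatial calibration, micrometers per pixel.
#' @param rng_seed Integer seed controlling the (deterministic) placement of
#'   counting lines.
#'
#' @return An object of class `pipeline_params` (a validated list).
#' @examples
#' p <- pipeline_params(noise_tolerance = 30)
#' p$stele_proportion
#' @export
pipeline_params <- function(verbose = TRUE,
                            modality = c("fluorescence", "brightfield"),
                            unit_mode = c("pixel", "calibrated"),
                            stele_proportion = 4,
                            n_layer_lines = 3L,
                            n_cell_files = 6L,
                            noise_tolerance = 20,
                            gaussian_sigma = 2,
                            contrast_saturation = 0.0035,
                            threshold_override = NULL,
                            smoothing_radius = 3L,
                            layer_offset = -1L,
                            min_cmx_area = 80L,
                            min_cmx_circularity = 0.5,
                            n_angles = 720L,
                            manual_nm = NULL,
                            manual_ncm = NULL,
                            file_radii = NULL,
                            calibration = NULL,
                            rng_seed = 1L) {
  modality <- match.arg(modality)
  unit_mode <- match.arg(unit_mode)
  stopifnot(
    "stele_proportion must be > 1" = is.numeric(stele_proportion) && stele_proportion > 1,
    "n_layer_lines must be >= 1" = n_layer_lines >= 1,
    "n_cell_files must be >= 1" = n_cell_files >= 1,
    "noise_tolerance must be >= 0" = noise_tolerance >= 0,
    "gaussian_sigma must be >= 0" = gaussian_sigma >= 0,
    "contrast_saturation must be in [0, 0.5)" =
      contrast_saturation >= 0 && contrast_saturation < 0.5,
    "smoothing_radius must be >= 0" = smoothing_radius >= 0,
    "n_angles must be >= 8" = n_angles >= 8
  )
  if (!is.null(threshold_override)) {
    stopifnot("threshold_override must be in [0, 255]" =
                threshold_override >= 0 && threshold_override <= 255)
  }
  if (!is.null(calibration)) {
    stopifnot("calibration must be a positive finite scalar" =
                is.finite(calibration) && calibration > 0)
  }
  if (unit_mode == "calibrated" && is.null(calibration)) {
    stop("unit_mode 'calibrated' requires a calibration (micrometers per pixel)")
  }
  structure(list(
    verbose = isTRUE(verbose),
    modality = modality,
    unit_mode = unit_mode,
    stele_proportion = as.numeric(stele_proportion),
    n_layer_lines = as.integer(n_layer_lines),
    n_cell_files = as.integer(n_cell_files),
    noise_tolerance = as.numeric(noise_tolerance),
    gaussian_sigma = as.numeric(gaussian_sigma),
    contrast_saturation = as.numeric(contrast_saturation),
    threshold_override = if (is.null(threshold_override)) NULL else as.integer(threshold_override),
    smoothing_radius = as.integer(smoothing_radius),
    layer_offset = as.integer(layer_offset),
    min_cmx_area = as.integer(min_cmx_area),
    min_cmx_circularity = as.numeric(min_cmx_circularity),
    n_angles = as.integer(n_angles),
    manual_nm = if (is.null(manual_nm)) NULL else as.integer(manual_nm),
    manual_ncm = if (is.null(manual_ncm)) NULL else as.integer(manual_ncm),
    file_radii = if (is.null(file_radii)) NULL else as.numeric(file_radii),
    calibration = if (is.null(calibration)) NULL else as.numeric(calibration),
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# Merge named overrides (e.g. from a sidecar config) into a pipeline_params.
.merge_params <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0) return(params)
  known <- names(formals(pipeline_params))
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
  args <- unclass(params)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(pipeline_params, args)
}
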