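#' Specification of a synthetic root phantom
#'
#' Describes a synthetic transverse root section built from concentric
#' tissue rings bounded by bright (autofluorescent) cell walls: epidermis
#' and exodermis rings outside a dense bright sclerenchyma band, several
#' cortex layers subdivided into cells by anticlinal walls, and a stele
#' bounded by the pericycle wall containing peripheral metaxylem and
#' central metaxylem vessels. Defaults model a 6-day-old cereal radicle
#' section at a magnification class of roughly 0.5 um/px.
#'
#' @param image_size `(height, width)` in pixels.
#' @param center `(row, col)` of the root axis; default image center.
#' @param root_radius Outer root radius (px).
#' @param scler_outer_radius,scler_inner_radius Sclerenchyma band limits
#'   (px); defaults scale with the root radius.
#' @param stele_radius Stele (pericycle) radius (px); default half the
#'   root radius, matching the conventional root/stele area proportion 4.
#' @param n_cortex_layers Number of cortex cell layers between stele and
#'   sclerenchyma.
#' @param cells_per_file Integer vector, cells in each cortex layer,
#'   outermost layer first; default decreases inward from 40.
#' @param wall_thickness Cell-wall thickness (px).
#' @param wall_intensity,tissue_intensity,background_intensity 8-bit
#'   levels (fluorescence convention: walls brightest).
#' @param noise_sigma Additive Gaussian noise s.d. (intensity levels).
#' @param n_cmx Number of central metaxylem vessels (1 in most varieties,
#'   up to 4 in some).
#' @param cmx_radius Central metaxylem vessel radius (px).
#' @param n_mx Number of peripheral metaxylem vessels.
#' @param mx_radius Peripheral metaxylem vessel radius (px).
#' @param modality `"fluorescence"` or `"brightfield"` (inverted).
#' @param angular_jitter Anticlinal-wall position jitter as a fraction of
#'   the cell's angular width.
#' @param rng_seed Integer seed; rendering is bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(512L, 512L),
                         center = (image_size + 1) / 2,
                         root_radius = 120,
                         scler_inner_radius = round(root_radius * 5 / 6),
                         scler_outer_radius = scler_inner_radius + max(5, round(root_radius * 0.05)),
                         stele_radius = root_radius / 2,
                         n_cortex_layers = 5L,
                         cells_per_file = pmax(12L, round(40 * 0.88^(seq_len(n_cortex_layers) - 1))),
                         wall_thickness = 2,
                         wall_intensity = 220L,
                         tissue_intensity = 60L,
                         background_intensity = 10L,
                         noise_sigma = 0,
                         n_cmx = 1L,
                         cmx_radius = 10,
                         n_mx = 6L,
                         mx_radius = 3,
                         modality = c("fluorescence", "brightfield"),
                         angular_jitter = 0.1,
                         rng_seed = 1L) {
  modality <- match.arg(modality)
  spec <- list(image_size = as.integer(image_size), center = as.numeric(center),
               root_radius = root_radius,
               scler_outer_radius = scler_outer_radius,
               scler_inner_radius = scler_inner_radius,
               stele_radius = stele_radius,
               n_cortex_layers = as.integer(n_cortex_layers),
               cells_per_file = as.integer(cells_per_file),
               wall_thickness = wall_thickness,
               wall_intensity = as.integer(wall_intensity),
               tissue_intensity = as.integer(tissue_intensity),
               background_intensity = as.integer(background_intensity),
               noise_sigma = noise_sigma,
               n_cmx = as.integer(n_cmx), cmx_radius = cmx_radius,
               n_mx = as.integer(n_mx), mx_radius = mx_radius,
               modality = modality,
               angular_jitter = angular_jitter,
               rng_seed = as.integer(rng_seed))
  .validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

.validate_phantom_spec <- function(s) {
  if (!(s$stele_radius < s$scler_inner_radius &&
        s$scler_inner_radius < s$scler_outer_radius &&
        s$scler_outer_radius < s$root_radius)) {
    stop("phantom radii must satisfy stele < scler_inner < scler_outer < root")
  }
  margin <- min(s$center[1] - 1, s$image_size[1] - s$center[1],
                s$center[2] - 1, s$image_size[2] - s$center[2])
  if (s$root_radius > margin) {
    stop("root_radius does not fit inside the image at the given center")
  }
  if (length(s$cells_per_file) != s$n_cortex_layers) {
    stop("cells_per_file must have one entry per cortex layer")
  }
  if (any(s$cells_per_file < 3)) stop("each cortex layer needs at least 3 cells")
  if (!(s$wall_intensity > s$tissue_intensity &&
        s$tissue_intensity >= s$background_intensity)) {
    stop("intensities must satisfy wall > tissue >= background")
  }
  if (s$n_cmx > 1) {
    d <- .cmx_center_distance(s)
    if (d + s$cmx_radius > 0.62 * s$stele_radius) {
      stop("central metaxylem vessels do not fit inside the stele")
    }
  } else if (s$cmx_radius > 0.5 * s$stele_radius) {
    stop("central metaxylem vessel too large for the stele")
  }
  invisible(TRUE)
}

.cmx_center_distance <- function(s) {
  if (s$n_cmx <= 1) return(0)
  max(2.4 * s$cmx_radius, (s$cmx_radius + 2) / sin(pi / s$n_cmx))
}

#' Render a synthetic root section with exact ground truth
#'
#' Rasterizes the concentric anatomy described by a [phantom_spec()]:
#' tissue rings bounded by bright periclinal walls, cortex layers
#' subdivided by jittered anticlinal walls, a dense sclerenchyma band,
#' metaxylem vessels with bright walls, plus seeded Gaussian noise.
#' Brightfield output is the inverted fluorescence rendering (inversion
#' applied before noise). Ground-truth areas and counts come from the same
#' rasterized label map used for rendering, so they are exact for the
#' rendered instance rather than analytic approximations.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (a `calibrated_image`) and `truth` (list:
#'   `true_root_area`, `true_cortex_area`, `true_stele_area`, `true_cma`,
#'   `true_ncm`, `true_nm`, `true_ncl`, `true_cells_per_file`,
#'   `wall_radii`, `center`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cr <- spec$center[1]; cc <- spec$center[2]
  rr <- matrix(seq_len(H), H, W) - cr
  ccm <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  rad <- sqrt(rr^2 + ccm^2)
  ang <- atan2(-rr, ccm) %% (2 * pi)
  wt <- spec$wall_thickness
  half <- wt / 2

  img <- matrix(as.numeric(spec$background_intensity), H, W)
  img[rad <= spec$root_radius] <- spec$tissue_intensity
  wall <- matrix(FALSE, H, W)

  # periclinal walls of the external layers (drawn inside each boundary)
  wall <- wall | (rad >= spec$root_radius - wt & rad <= spec$root_radius)
  mid_out <- (spec$scler_outer_radius + spec$root_radius) / 2
  wall <- wall | (abs(rad - mid_out) <= half)
  # sclerenchyma: dense bright band
  wall <- wall | (rad >= spec$scler_inner_radius & rad <= spec$scler_outer_radius)
  # cortex periclinal walls (stele boundary = pericycle wall included)
  wall_radii <- seq(spec$stele_radius, spec$scler_inner_radius,
                    length.out = spec$n_cortex_layers + 1)
  for (rho in wall_radii) wall <- wall | (abs(rad - rho) <= half)

  truth_cells <- spec$cells_per_file
  res <- .with_seed(spec$rng_seed, {
    w <- wall
    # anticlinal walls subdividing each cortex layer (outermost first)
    for (i in seq_len(spec$n_cortex_layers)) {
      j <- spec$n_cortex_layers - i + 1          # innermost-first index
      r_in <- wall_radii[j]; r_out <- wall_radii[j + 1]
      ncell <- truth_cells[i]
      phase <- stats::runif(1, 0, 2 * pi)
      step <- 2 * pi / ncell
      jit <- stats::runif(ncell, -spec$angular_jitter, spec$angular_jitter) * step
      wang <- sort(((seq_len(ncell) - 1) * step + phase + jit) %% (2 * pi))
      sel <- which(rad > r_in + half & rad < r_out - half)
      if (length(sel)) {
        a <- ang[sel]
        k <- findInterval(a, wang)
        left <- ifelse(k == 0, wang[ncell] - 2 * pi, wang[pmax(k, 1)])
        right <- ifelse(k == ncell, wang[1] + 2 * pi, wang[pmin(k + 1, ncell)])
        dist <- pmin(a - left, right - a)
        w[sel[dist * rad[sel] <= half]] <- TRUE
      }
    }
    # metaxylem vessels: bright wall rings
    cmx_centers <- .cmx_centers(spec)
    cma_mask <- matrix(FALSE, H, W)
    for (p in cmx_centers) {
      d <- sqrt((rr - (p[1] - cr))^2 + (ccm - (p[2] - cc))^2)
      w <- w | (d >= spec$cmx_radius - wt & d <= spec$cmx_radius)
      cma_mask <- cma_mask | (d <= spec$cmx_radius)
    }
    if (spec$n_mx > 0) {
      mx_ring <- 0.75 * spec$stele_radius
      mx_ang <- stats::runif(1, 0, 2 * pi) + (seq_len(spec$n_mx) - 1) * 2 * pi / spec$n_mx
      for (a in mx_ang) {
        py <- cr - mx_ring * sin(a); px <- cc + mx_ring * cos(a)
        d <- sqrt((rr - (py - cr))^2 + (ccm - (px - cc))^2)
        w <- w | (d >= spec$mx_radius - wt & d <= spec$mx_radius)
      }
    }
    base <- img
    base[w] <- spec$wall_intensity
    if (spec$modality == "brightfield") base <- 255 - base
    if (spec$noise_sigma > 0) {
      base <- base + stats::rnorm(length(base), 0, spec$noise_sigma)
    }
    list(img = base, cma_mask = cma_mask)
  })

  pixels <- clip8(round_half_up(res$img))
  storage.mode(pixels) <- "integer"
  truth <- list(
    true_root_area = sum(rad <= spec$root_radius),
    true_cortex_area = sum(rad <= spec$scler_inner_radius),
    true_stele_area = sum(rad <= spec$stele_radius),
    true_cma = sum(res$cma_mask),
    true_ncm = spec$n_cmx,
    true_nm = spec$n_mx,
    true_ncl = spec$n_cortex_layers,
    true_cells_per_file = truth_cells,
    wall_radii = wall_radii,
    center = spec$center
  )
  image <- calibrated_image(pixels, modality = spec$modality,
                            source_id = sprintf("phantom_seed%d", spec$rng_seed))
  list(image = image, truth = truth, spec = spec)
}

# Central metaxylem vessel centers: one at the stele center, several on a
# small circle around it.
.cmx_centers <- function(spec) {
  cr <- spec$center[1]; cc <- spec$center[2]
  if (spec$n_cmx == 0) return(list())
  if (spec$n_cmx == 1) return(list(c(cr, cc)))
  d <- .cmx_center_distance(spec)
  lapply(seq_len(spec$n_cmx), function(k) {
    a <- (k - 1) * 2 * pi / spec$n_cmx + pi / spec$n_cmx
    c(cr - d * sin(a), cc + d * cos(a))
  })
}

#' Draw a reproducible suite of random phantoms
#'
#' Samples `n` phantom specifications from documented realistic ranges
#' (root radius 80-160 px, 3-6 cortex layers, 12-64 cells per file, 1-4
#' central metaxylem vessels, noise sigma 0-15) under a single seed and
#' renders each.
#'
#' @param seed Integer seed.
#' @param n Number of phantoms (>= 1).
#' @param image_size Image size used for every phantom.
#' @param noise_range Range of the per-phantom noise sigma.
#' @return List of `n` results from [generate_phantom()] (each with
#'   `spec`, `image`, `truth`).
#' @export
phantom_suite <- function(seed, n, image_size = c(384L, 384L),
                          noise_range = c(0, 15)) {
  stopifnot(n >= 1)
  specs <- .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      r <- stats::runif(1, 80, min(160, (min(image_size) - 24) / 2))
      # cortical cell depth is roughly constant, so thicker roots carry
      # more layers; cap keeps layers at least ~8 px (about one cell) deep
      nl_range <- 3:max(3, min(6, floor(r / 24)))
      nl <- nl_range[sample.int(length(nl_range), 1)]
      scler_inner <- round(r * 5 / 6)
      stele <- r / 2
      wall_radii <- seq(stele, scler_inner, length.out = nl + 1)
      mids <- (wall_radii[-1] + wall_radii[-(nl + 1)]) / 2
      outer_cells <- sample(24:64, 1)
      cells <- vapply(rev(mids), function(rm) {
        cap <- floor(2 * pi * rm / 6)
        max(12L, min(as.integer(cap), as.integer(round(outer_cells * rm / mids[nl]))))
      }, integer(1))
      # several central vessels only fit in thick roots (as in real varieties)
      n_cmx <- sample(1:4, 1)
      cmx_cap <- 0.18 * stele
      if (n_cmx > 1 && cmx_cap < 8) n_cmx <- 1L
      cmx_radius <- if (n_cmx > 1) stats::runif(1, 8, min(12, cmx_cap))
                    else stats::runif(1, 8, 12)
      phantom_spec(image_size = image_size,
                   root_radius = r,
                   n_cortex_layers = nl,
                   cells_per_file = cells,
                   n_cmx = n_cmx,
                   cmx_radius = cmx_radius,
                   noise_sigma = stats::runif(1, noise_range[1], noise_range[2]),
                   rng_seed = sample.int(1e6, 1))
    })
  })
  lapply(specs, generate_phantom)
}
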