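#' Polar transform of an image
#'
#' Resamples the image into (radius, angle) coordinates about a center:
#' row `r + 1` holds radius `r` (1 px radial step, the center on row 1),
#' column `a` holds angle `(a - 1) * 2 * pi / n_angles`. Angle 0 points
#' along +col and increases counter-clockwise (row offsets decrease).
#' Sampling is bilinear; samples falling outside the source are 0. In the
#' result, concentric rings become horizontal bands and radial walls
#' become vertical stripes, with the stele at the top and the epidermis at
#' the bottom.
#'
#' @param img A `calibrated_image`.
#' @param center Numeric `(row, col)` center, inside the image.
#' @param n_angles Number of angular samples (>= 8).
#' @param r_max Maximum radius in pixels (>= 1).
#' @return An object of class `polar_image`: list with `pixels`
#'   (`(r_max + 1) x n_angles` numeric matrix), `center`, `n_angles`,
#'   `r_max`, `angular_step`.
#' @export
polar_transform <- function(img, center, n_angles = 720L, r_max) {
  stopifnot(inherits(img, "calibrated_image"), length(center) == 2)
  if (center[1] < 1 || center[1] > img$height ||
      center[2] < 1 || center[2] > img$width) {
    stop("polar transform center lies outside the image")
  }
  if (r_max < 1) stop("r_max must be >= 1")
  if (n_angles < 8) stop("n_angles must be >= 8")
  n_angles <- as.integer(n_angles)
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  r <- 0:r_max
  rows <- center[1] - outer(r, sin(theta))   # CCW: +angle moves up the image
  cols <- center[2] + outer(r, cos(theta))
  px <- .bilinear_sample(img$pixels, rows, cols)
  structure(list(pixels = px, center = as.numeric(center),
                 n_angles = n_angles, r_max = as.integer(r_max),
                 angular_step = 2 * pi / n_angles),
            class = "polar_image")
}

# Bilinear interpolation of matrix P at fractional (Y, X) positions
# (same-shaped matrices); positions outside the grid sample as 0.
.bilinear_sample <- function(P, Y, X) {
  H <- nrow(P); W <- ncol(P)
  y0 <- floor(Y); x0 <- floor(X)
  wy <- Y - y0; wx <- X - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    out <- numeric(length(yy))
    out[ok] <- P[cbind(yy[ok], xx[ok])]
    out
  }
  dn <- dim(Y)
  v <- (1 - wy) * (1 - wx) * val(y0,     x0) +
       (1 - wy) * wx       * val(y0,     x0 + 1) +
       wy       * (1 - wx) * val(y0 + 1, x0) +
       wy       * wx       * val(y0 + 1, x0 + 1)
  dim(v) <- dn
  v
}

#' Locate local maxima of an intensity profile by prominence
#'
#' A position (or plateau) counts as a maximum when its neighbors on both
#' sides are strictly lower (at the ends of a non-periodic profile the
#' missing side is waived) and its prominence — the height above the
#' higher of the two bounding minima reachable without crossing a larger
#' value — is at least `noise_tolerance`. Plateaus report their center
#' position (round half up). Periodic profiles are treated circularly and
#' a maximum spanning the seam is counted once.
#'
#' @param profile Numeric intensity sequence, length >= 3.
#' @param noise_tolerance Minimum prominence (intensity units, >= 0).
#' @param periodic Treat the profile as circular.
#' @return Integer vector of maxima positions (1-based, strictly
#'   increasing).
#' @examples
#' find_profile_maxima(c(0, 5, 0, 7, 0), 3)  # 2 4
#' find_profile_maxima(c(0, 5, 0, 7, 0), 6)  # 4
#' @export
find_profile_maxima <- function(profile, noise_tolerance, periodic = FALSE) {
  n <- length(profile)
  stopifnot(n >= 3, noise_tolerance >= 0)
  x <- as.numeric(profile)
  runs <- rle(x)
  k <- length(runs$lengths)
  if (k == 1) return(integer(0))              # constant profile
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pos <- integer(0)
  if (!periodic) {
    for (j in seq_len(k)) {
      v <- runs$values[j]
      left_ok <- j == 1 || runs$values[j - 1] < v
      right_ok <- j == k || runs$values[j + 1] < v
      if (!(left_ok && right_ok)) next
      prom <- .prominence_linear(x, starts[j], ends[j], v)
      if (prom >= noise_tolerance) {
        pos <- c(pos, round_half_up((starts[j] + ends[j]) / 2))
      }
    }
  } else {
    # merge the seam run if first and last values match
    wrap <- runs$values[1] == runs$values[k]
    jset <- if (wrap) 2:k else seq_len(k)
    if (wrap && k == 2) jset <- 2   # two runs, one wraps: only it and the other
    for (j in jset) {
      v <- runs$values[j]
      jl <- if (j == 1) k else j - 1
      jr <- if (j == k) 1 else j + 1
      s <- starts[j]; e <- ends[j]; len <- runs$lengths[j]
      if (wrap && j == k) { # wrapped run: spans [starts[k]..n] + [1..ends[1]]
        jl <- k - 1; jr <- 2
        len <- runs$lengths[k] + runs$lengths[1]
        e <- ends[1] + n   # virtual end past the seam
      }
      if (wrap && j == 1) next
      if (!(runs$values[jl] < v && runs$values[jr] < v)) next
      prom <- .prominence_circular(x, s, v)
      if (prom >= noise_tolerance) {
        p <- round_half_up((s + s + len - 1) / 2)
        pos <- c(pos, ((p - 1) %% n) + 1)
      }
    }
  }
  sort(unique(as.integer(pos)))
}

# Prominence of the plateau [i..j] (value v) in a non-periodic profile:
# on each side walk until a value > v (or the boundary), take the minimum
# encountered; prominence = v - max(left min, right min); a missing side
# does not bound the prominence.
.prominence_linear <- function(x, i, j, v) {
  lmin <- -Inf
  if (i > 1) {
    seg <- x[(i - 1):1]
    stopidx <- which(seg > v)[1]
    lmin <- if (is.na(stopidx)) min(seg) else min(seg[1:stopidx])
  }
  rmin <- -Inf
  n <- length(x)
  if (j < n) {
    seg <- x[(j + 1):n]
    stopidx <- which(seg > v)[1]
    rmin <- if (is.na(stopidx)) min(seg) else min(seg[1:stopidx])
  }
  v - max(lmin, rmin)
}

# Circular prominence: walk both directions around the circle from the run
# starting at s until a strictly larger value; if none exists (global
# maximum), the prominence is v minus the global minimum.
.prominence_circular <- function(x, s, v) {
  n <- length(x)
  walk <- function(step) {
    m <- Inf
    idx <- s
    for (t in seq_len(n)) {
      idx <- ((idx - 1 + step) %% n) + 1
      if (x[idx] > v) return(m)
      m <- min(m, x[idx])
    }
    m  # no larger value anywhere
  }
  v - max(min(walk(-1L)), min(walk(+1L)))
}

#' Extrapolate a cell count from partial coverage
#'
#' When only a fraction of a cell file is countable, the full-circle count
#' is extrapolated as `raw / coverage`, rounded half up. Full coverage is
#' the identity.
#'
#' @param raw Non-negative integer count from the covered portion.
#' @param coverage Fraction of the file covered, in `(0, 1]`.
#' @return Non-negative integer extrapolated count.
#' @examples
#' extrapolate_count(12, 0.25)  # 48
#' @export
extrapolate_count <- function(raw, coverage) {
  stopifnot(raw >= 0, coverage > 0, coverage <= 1)
  as.integer(round_half_up(raw / coverage))
}

# Constructor for one counting line's result.
.count_profile <- function(orientation, fixed_coord, span, profile, maxima,
                           raw_count, coverage, noise_tolerance) {
  structure(list(orientation = orientation, fixed_coord = fixed_coord,
                 span = span, profile = profile, maxima = maxima,
                 raw_count = as.integer(raw_count), coverage = coverage,
                 extrapolated_count = extrapolate_count(raw_count, coverage),
                 noise_tolerance = noise_tolerance),
            class = "count_profile")
}

# A counting line must cross walls transversally: a line running along or
# near an anticlinal (bright) wall has an elevated baseline, which fills
# in the valleys between periclinal-wall maxima. Among nearby candidate
# angles the cleanest line is the one with the lowest mean intensity —
# the automatic analog of the supervising user tracing a line through
# clean tissue.
.line_cleanliness <- function(profile) mean(profile)

# Truncate a radial layer-count profile at the sclerenchyma band's
# brightest sample (the outermost attainment of the profile maximum), so
# the band always registers as a terminal maximum instead of being cut
# mid-descent with an artificially shallow prominence. Only applied when
# that brightest point sits in the outer half of the span.
.trim_at_outer_peak <- function(p) {
  j <- max(which(p == max(p)))
  if (j > length(p) / 2) p[1:j] else p
}

#' Count cortical cell layers on radial lines
#'
#' Places `n_layer_lines` radial lines at evenly spaced angles (offset
#' derived from `rng_seed`; lines that run along a wall are shifted to the
#' next clean angle), extracts each line's intensity profile between the
#' stele boundary and the sclerenchyma inner edge, counts its maxima
#' (periclinal walls) at the configured noise tolerance, and averages the
#' per-line layer counts. A span crossing k layers crosses k + 1 walls, so
#' the per-line count is `maxima + layer_offset` (default -1), floored at
#' zero.
#'
#' @param polar A `polar_image`.
#' @param inner_r,outer_r Span of each radial line in pixels from the
#'   center; either scalars or per-angle vectors of length `n_angles`.
#' @param params A [pipeline_params()].
#' @return List with `ncl` (mean layer count, possibly fractional),
#'   `profiles` (list of `count_profile`), `warnings`.
#' @export
count_layers <- function(polar, inner_r, outer_r, params = pipeline_params()) {
  stopifnot(inherits(polar, "polar_image"))
  na <- polar$n_angles
  inner_r <- rep_len(inner_r, na)
  outer_r <- rep_len(outer_r, na)
  warnings <- character(0)
  nlines <- params$n_layer_lines
  base <- (params$rng_seed %% na)
  anchors <- (base + round((seq_len(nlines) - 1) * na / nlines)) %% na + 1
  profiles <- vector("list", nlines)
  counts <- rep(NA_real_, nlines)
  for (i in seq_len(nlines)) {
    # pick the cleanest line among candidate angles near the anchor
    best <- NULL
    for (try in 0:24) {
      aa <- ((anchors[i] - 1 + 3 * try) %% na) + 1
      if (inner_r[aa] >= outer_r[aa]) next
      rows <- (max(0, floor(inner_r[aa])):min(polar$r_max, ceiling(outer_r[aa]))) + 1
      p <- .trim_at_outer_peak(polar$pixels[rows, aa])
      score <- .line_cleanliness(p)
      if (is.null(best) || score < best$score) best <- list(a = aa, prof = p, score = score)
    }
    if (is.null(best)) {
      warnings <- c(warnings, sprintf("layer line %d has an empty span", i))
      next
    }
    a <- best$a
    prof <- best$prof
    mx <- find_profile_maxima(prof, params$noise_tolerance, periodic = FALSE)
    if (length(mx) == 0) {
      warnings <- c(warnings, sprintf("layer line %d (angle index %d) had no maxima; excluded", i, a))
      next
    }
    r_lo <- max(0, floor(inner_r[a]))
    profiles[[i]] <- .count_profile("radial", a, c(r_lo, r_lo + length(prof) - 1),
                                    prof, r_lo + mx - 1, length(mx), 1,
                                    params$noise_tolerance)
    counts[i] <- max(0, length(mx) + params$layer_offset)
  }
  ok <- !is.na(counts)
  if (!any(ok)) stop("all layer-count lines were excluded (no maxima found)")
  list(ncl = mean(counts[ok]), profiles = profiles[ok], warnings = warnings)
}

#' Count cells in one cell file
#'
#' Extracts the angular intensity profile at the given radius. A full
#' circle (`span_fraction = 1`) is counted periodically — each detected
#' maximum is one anticlinal wall, i.e. one cell. A partial span is
#' counted non-periodically and the full-circle count is extrapolated from
#' the covered fraction.
#'
#' @param polar A `polar_image`.
#' @param file_radius Radius of the cell file in pixels, in `[1, r_max]`.
#' @param span_fraction Fraction of the circle to cover, in `(0, 1]`.
#' @param params A [pipeline_params()].
#' @return A `count_profile` (`extrapolated_count` is the cell count).
#' @export
count_cells_in_file <- function(polar, file_radius, span_fraction = 1,
                                params = pipeline_params()) {
  stopifnot(inherits(polar, "polar_image"))
  if (file_radius < 1 || file_radius > polar$r_max) {
    stop(sprintf("file radius %.1f outside [1, %d]", file_radius, polar$r_max))
  }
  if (span_fraction <= 0 || span_fraction > 1) stop("span_fraction must be in (0, 1]")
  row <- as.integer(round_half_up(file_radius)) + 1L
  full <- polar$pixels[row, ]
  na <- polar$n_angles
  if (span_fraction == 1) {
    mx <- find_profile_maxima(full, params$noise_tolerance, periodic = TRUE)
    return(.count_profile("angular", file_radius, c(1, na), full, mx,
                          length(mx), 1, params$noise_tolerance))
  }
  m <- max(3L, as.integer(round_half_up(span_fraction * na)))
  start <- (params$rng_seed %% na) + 1L
  cols <- ((start - 1 + 0:(m - 1)) %% na) + 1
  prof <- full[cols]
  coverage <- m / na
  mx <- find_profile_maxima(prof, params$noise_tolerance, periodic = FALSE)
  .count_profile("angular", file_radius, c(start, start + m - 1), prof,
                 mx, length(mx), coverage, params$noise_tolerance)
}

#' Derive cell-file radii from layer-count profiles
#'
#' Candidate file radii are the midpoints between consecutive periclinal
#' walls, averaged over the radial lines that found the modal number of
#' walls, ordered from outermost inward. Explicit radii in the
#' configuration override the automatic placement.
#'
#' @param layer_profiles List of radial `count_profile`s (from
#'   [count_layers()]).
#' @param n_files Number of file radii wanted.
#' @param override Optional numeric radii returned as-is.
#' @return List with `radii` (numeric, outermost first, at most `n_files`)
#'   and `warnings`.
#' @export
place_file_radii <- function(layer_profiles, n_files, override = NULL) {
  if (!is.null(override)) return(list(radii = as.numeric(override), warnings = character(0)))
  stopifnot(length(layer_profiles) >= 1)
  counts <- vapply(layer_profiles, function(p) length(p$maxima), integer(1))
  modal <- as.integer(names(which.max(table(counts))))
  use <- layer_profiles[counts == modal]
  if (modal < 2) {
    return(list(radii = numeric(0),
                warnings = "fewer than two walls detected; no file radii placed"))
  }
  wall_r <- Reduce(`+`, lapply(use, function(p) as.numeric(p$maxima))) / length(use)
  mids <- (wall_r[-1] + wall_r[-length(wall_r)]) / 2
  mids <- sort(mids, decreasing = TRUE)   # outermost first
  warnings <- character(0)
  if (length(mids) < n_files) {
    warnings <- sprintf("only %d candidate file radii available (%d requested)",
                        length(mids), n_files)
  }
  list(radii = mids[seq_len(min(n_files, length(mids)))], warnings = warnings)
}
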