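# Internal helpers shared across the pipeline.

# Round half up to nearest integer (the package-wide rounding convention;
# base round() rounds half to even, which is unsuitable for count arithmetic).
round_half_up <- function(x) floor(x + 0.5)

# Clip to the 8-bit range.
clip8 <- function(x) pmin(pmax(x, 0), 255)

# Convert a [row, col] matrix (our convention) to an EBImage Image (x, y) and back.
.as_ebi <- function(m, scale = 1) EBImage::Image(t(m) / scale)

.from_ebi <- function(e, scale = 1) t(EBImage::imageData(e)) * scale

# Logical mask -> EBImage binary image
.mask_ebi <- function(mask) EBImage::Image(t(mask * 1))

.ebi_mask <- function(e) t(EBImage::imageData(e)) > 0.5

# Foreground centroid (row, col) of a logical mask.
.mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Labelled connected components of a logical mask (8-connectivity).
.label_components <- function(mask) {
  t(EBImage::imageData(EBImage::bwlabel(.mask_ebi(mask))))
}

# Fill interior holes of a logical mask.
.fill_holes <- function(mask) {
  .ebi_mask(EBImage::fillHull(.mask_ebi(mask)))
}

# Outer contour(s) of a logical mask as a list of n x 2 [row, col] matrices
# (1-based pixel coordinates).
.mask_contours <- function(mask) {
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(.mask_ebi(mask))
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(xy) {
    # ocontour returns 0-based (x, y); convert to 1-based (row, col)
    cbind(row = xy[, 2] + 1, col = xy[, 1] + 1)
  })
}

# Perimeter of a closed polygon given as n x 2 matrix.
.polygon_perimeter <- function(p) {
  if (nrow(p) < 2) return(0)
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2))
}

# Run a block with a private RNG stream, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
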