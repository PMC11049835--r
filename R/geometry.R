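# Internal geometry helpers. All coordinates are 0-based (row, col) pixel
# centers; masks are logical matrices indexed [row + 1, col + 1].

# Pixel-center coordinates of TRUE pixels, as a 2-column (row, col) matrix.
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(row = idx[, 1L] - 1, col = idx[, 2L] - 1)
}

# Logical ellipse mask on an nr x nc grid. theta is the angle of the major
# axis measured from the column (x) axis, in radians.
ellipse_mask <- function(nr, nc, center, semi_major, semi_minor, theta) {
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  dy <- rr - center[1L]
  dx <- cc - center[2L]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / semi_major)^2 + (v / semi_minor)^2 <= 1
}

# Normalized elliptical radius of points (row, col): 1 on the boundary.
ellipse_norm <- function(pts, center, semi_major, semi_minor, theta) {
  dy <- pts[, 1L] - center[1L]
  dx <- pts[, 2L] - center[2L]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sqrt((u / semi_major)^2 + (v / semi_minor)^2)
}

# Maximum Feret (caliper) diameter of a mask, in pixels, together with the
# defining pixel pair. Pixel-center extremes plus 1 px for the half-pixel
# extent at each end, so a digitized segment of n collinear pixels has
# Feret n, matching the continuous caliper width.
feret_diameter <- function(mask) {
  pts <- mask_coords(mask)
  if (nrow(pts) == 0L) stop("empty mask", call. = FALSE)
  if (nrow(pts) == 1L)
    return(list(length_px = 1, p1 = pts[1L, ], p2 = pts[1L, ]))
  hull <- grDevices::chull(pts[, 2L], pts[, 1L])
  hp <- pts[hull, , drop = FALSE]
  d <- as.matrix(stats::dist(hp))
  ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
  # stable endpoint order: smaller (row, col) first
  p <- hp[ij, , drop = FALSE]
  o <- order(p[, 1L], p[, 2L])
  list(length_px = max(d) + 1, p1 = p[o[1L], ], p2 = p[o[2L], ])
}

# Largest connected component of a logical mask (8-connectivity), holes
# filled. Returns a logical matrix.
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labd <- EBImage::imageData(lab)
  if (max(labd) == 0) return(mask & FALSE)
  counts <- tabulate(labd[labd > 0])
  keep <- which.max(counts)
  comp <- labd == keep
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1)))
  filled > 0.5
}

euclid <- function(p, q) sqrt(sum((p - q)^2))
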