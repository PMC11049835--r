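# Nucleus segmentation and morphometry from the counterstain channel.

#' Segment the sperm nucleus and measure its geometry
#'
#' Global Otsu threshold on the counterstain channel, largest connected
#' component, hole fill. Nucleus length is the maximum Feret (caliper)
#' diameter of the mask — the operational reading of "base to tip" — and is
#' therefore independent of which endpoint is labelled base. The base is the
#' Feret endpoint nearer the midpiece stub when one is visible (brighter
#' counterstain near the base), otherwise the endpoint on the wider half of
#' the mask.
#'
#' @param image A [calibrated_image()] whose first/`"counterstain"` channel
#'   holds the nuclear stain.
#' @param min_area_um2 Components smaller than this are treated as
#'   segmentation failures.
#' @return Object of class `nucleus_geometry`: `mask`, `area_um2`,
#'   `length_um`, `base_point`, `tip_point` (0-based `(row, col)`),
#'   `centroid`, `pixel_size_um`.
#' @export
segment_nucleus <- function(image, min_area_um2 = 3) {
  stopifnot(inherits(image, "calibrated_image"))
  ch <- if ("counterstain" %in% image$channel_names)
    get_channel(image, "counterstain") else image$pixels[, , 1L]
  rng <- range(ch)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("counterstain channel is constant; cannot segment", call. = FALSE)
  scaled <- (ch - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  mask <- largest_component(scaled > thr)
  n_px <- sum(mask)
  if (n_px == 0) stop("segmentation produced an empty mask", call. = FALSE)
  ps <- image$pixel_size_um
  area_um2 <- n_px * ps^2
  fer <- feret_diameter(mask)
  pts <- mask_coords(mask)
  centroid <- colMeans(pts)
  # base assignment: stub intensity in a 7x7 window just inside each
  # endpoint (shifted toward the centroid so the window samples nucleus, not
  # background), falling back to the mask-pixel count nearer each endpoint
  # ("wider half")
  win_mean <- function(p) {
    v <- centroid - p
    p <- round(p + 3 * v / max(sqrt(sum(v^2)), 1e-9))
    r <- (p[1L] - 3):(p[1L] + 3) + 1; c <- (p[2L] - 3):(p[2L] + 3) + 1
    r <- r[r >= 1 & r <= nrow(ch)]; c <- c[c >= 1 & c <= ncol(ch)]
    mean(ch[r, c])
  }
  m1 <- win_mean(fer$p1); m2 <- win_mean(fer$p2)
  if (abs(m1 - m2) > 0.05 * max(m1, m2)) {
    base_first <- m1 > m2
  } else {
    d1 <- (pts[, 1L] - fer$p1[1L])^2 + (pts[, 2L] - fer$p1[2L])^2
    d2 <- (pts[, 1L] - fer$p2[1L])^2 + (pts[, 2L] - fer$p2[2L])^2
    base_first <- sum(d1 < d2) >= sum(d1 > d2)
  }
  structure(list(mask = mask,
                 area_um2 = area_um2,
                 length_um = px_to_um(fer$length_px, ps),
                 base_point = as.numeric(if (base_first) fer$p1 else fer$p2),
                 tip_point = as.numeric(if (base_first) fer$p2 else fer$p1),
                 centroid = centroid,
                 pixel_size_um = ps,
                 too_small = area_um2 < min_area_um2),
            class = "nucleus_geometry")
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf("<nucleus_geometry> area %.2f um^2, length %.2f um, base (%g, %g), tip (%g, %g)\n",
              x$area_um2, x$length_um, x$base_point[1L], x$base_point[2L],
              x$tip_point[1L], x$tip_point[2L]))
  invisible(x)
}

#' Quality-control limits for nucleus geometry
#'
#' Defaults bracket the normal human sperm head: area 3-30 µm², length
#' 2-8 µm.
#'
#' @param area_um2,length_um Numeric `(min, max)` limits.
#' @return List of limits.
#' @export
qc_limits <- function(area_um2 = c(3, 30), length_um = c(2, 8)) {
  list(area_um2 = area_um2, length_um = length_um)
}

#' Check nucleus geometry against QC limits
#'
#' @param geometry A `nucleus_geometry`.
#' @param limits A [qc_limits()].
#' @return List with `pass` (logical) and `reason` (`""`,
#'   `"area_out_of_range"` or `"length_out_of_range"`).
#' @export
qc_geometry <- function(geometry, limits = qc_limits()) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  if (geometry$area_um2 < limits$area_um2[1L] ||
      geometry$area_um2 > limits$area_um2[2L])
    return(list(pass = FALSE, reason = "area_out_of_range"))
  if (geometry$length_um < limits$length_um[1L] ||
      geometry$length_um > limits$length_um[2L])
    return(list(pass = FALSE, reason = "length_out_of_range"))
  list(pass = TRUE, reason = "")
}
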