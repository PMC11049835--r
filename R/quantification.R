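# Telomere spot detection and chromosome-territory quantification.

log_kernel <- function(sigma) {
  k <- 2L * ceiling(3 * sigma) + 1L
  h <- (k - 1L) / 2L
  x <- matrix(-h:h, k, k, byrow = TRUE)
  y <- matrix(-h:h, k, k)
  r2 <- x^2 + y^2
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  # negated, scale-normalized LoG (sigma^2 * laplacian of a unit Gaussian):
  # response peaks at the matching scale and a blob of amplitude A yields
  # ~A/2 at its center; zero-sum, so constant offsets contribute nothing
  kern <- -(r2 - 2 * sigma^2) / sigma^2 * g
  kern - mean(kern)
}

local_maxima <- function(resp) {
  nr <- nrow(resp); nc <- ncol(resp)
  m <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- resp[rs - dr, cs - dc]
    m <- m & (resp >= shifted)
  }
  m
}

#' Spot-detection parameters
#'
#' @param sigmas Laplacian-of-Gaussian scales in px, spanning the expected
#'   telomere spot size.
#' @param threshold Minimum scale-normalized LoG response (intensity
#'   counts) for a candidate.
#' @param min_separation_px Candidates closer than this are merged, keeping
#'   the stronger.
#' @return List of parameters.
#' @export
spot_params <- function(sigmas = c(1.5, 2, 3, 4), threshold = 300,
                        min_separation_px = 3) {
  list(sigmas = sigmas, threshold = threshold,
       min_separation_px = min_separation_px)
}

#' Detect telomere spots in the nucleus
#'
#' Multi-scale Laplacian-of-Gaussian blob detection on the telomere channel,
#' restricted to the nucleus mask. Candidate positions are local maxima of
#' the finest-scale response (coarse scales merge close pairs into a single
#' midpoint maximum), kept when their maximum-over-scales response exceeds
#' `params$threshold`; sub-pixel centers are intensity-weighted centroids of
#' the background-subtracted 5x5 neighborhood. All candidates above
#' threshold are returned, strongest first — the two-spot rule is enforced
#' by the caller. A lone candidate is treated as an unresolved pair of
#' overlapping telomere signals (expected for a hairpin-conformed
#' chromosome, where both telomeres colocalize) and is split into two
#' sub-spots along the blob's principal intensity axis, recovering
#' separations from about two optical widths down to zero.
#'
#' @param image A [calibrated_image()] with a `"telomere"` channel.
#' @param geometry A `nucleus_geometry` from [segment_nucleus()].
#' @param params A [spot_params()].
#' @return Data frame of class `fish_spots`: `row`, `col` (0-based
#'   sub-pixel), `response`, `sigma`, `in_mask`.
#' @export
detect_telomere_spots <- function(image, geometry, params = spot_params()) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(geometry, "nucleus_geometry"))
  ch <- if ("telomere" %in% image$channel_names)
    get_channel(image, "telomere") else image$pixels[, , 2L]
  resp <- matrix(-Inf, nrow(ch), ncol(ch))
  scale_of <- matrix(params$sigmas[1L], nrow(ch), ncol(ch))
  fine <- NULL
  for (s in sort(params$sigmas)) {
    r <- EBImage::imageData(EBImage::filter2(EBImage::Image(ch),
                                             log_kernel(s),
                                             boundary = "replicate"))
    if (is.null(fine)) fine <- r
    upd <- r > resp
    resp[upd] <- r[upd]
    scale_of[upd] <- s
  }
  # candidate positions come from the finest scale, which keeps two maxima
  # for close spot pairs that coarser scales blur into one; strength and
  # best scale are read off the multi-scale maximum response
  cand <- local_maxima(fine) & geometry$mask & (resp > params$threshold)
  idx <- which(cand, arr.ind = TRUE)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      response = numeric(0), sigma = numeric(0),
                      in_mask = logical(0))
  if (nrow(idx) == 0L) return(structure(empty, class = c("fish_spots", "data.frame")))
  ord <- order(resp[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  # merge near-duplicates (plateaus, neighboring scales)
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1L):nrow(idx)
      d <- sqrt((idx[later, 1L] - idx[i, 1L])^2 + (idx[later, 2L] - idx[i, 2L])^2)
      keep[later[d < params$min_separation_px]] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 1L) {
    # a single candidate is an unresolved pair: overlapping or coincident
    # telomere signals. Split it by second moments — for two equal spots a
    # distance d apart, the intensity variance along the pair axis exceeds
    # the perpendicular one by d^2/4, so d = 2 sqrt(lambda1 - lambda2).
    pair <- split_merged_spot(ch, idx[1L, ])
    out <- data.frame(row = pair[, 1L], col = pair[, 2L],
                      response = rep(resp[idx], 2L),
                      sigma = rep(scale_of[idx], 2L), in_mask = TRUE)
    return(structure(out, class = c("fish_spots", "data.frame")))
  }
  centers <- t(apply(idx, 1L, function(p) subpixel_centroid(ch, p)))
  out <- data.frame(row = centers[, 1L], col = centers[, 2L],
                    response = resp[idx], sigma = scale_of[idx],
                    in_mask = TRUE)
  structure(out[order(out$response, decreasing = TRUE), ],
            class = c("fish_spots", "data.frame"))
}

# Split one unresolved blob into two sub-spots along its principal axis.
# p is a 1-based (row, col) matrix index; returns a 2 x 2 matrix of 0-based
# sub-pixel (row, col) centers (coincident when the blob is isotropic).
split_merged_spot <- function(ch, p, halfwin = 5L) {
  rs <- max(1L, p[1L] - halfwin):min(nrow(ch), p[1L] + halfwin)
  cs <- max(1L, p[2L] - halfwin):min(ncol(ch), p[2L] + halfwin)
  w <- ch[rs, cs, drop = FALSE]
  w <- pmax(w - stats::median(w), 0)  # robust background removal
  tw <- sum(w)
  if (tw == 0) {
    ctr <- c(p[1L] - 1, p[2L] - 1)
    return(rbind(ctr, ctr))
  }
  rr <- matrix(rs - 1, length(rs), length(cs))
  cc <- matrix(cs - 1, length(rs), length(cs), byrow = TRUE)
  mr <- sum(w * rr) / tw
  mc <- sum(w * cc) / tw
  vrr <- sum(w * (rr - mr)^2) / tw
  vcc <- sum(w * (cc - mc)^2) / tw
  vrc <- sum(w * (rr - mr) * (cc - mc)) / tw
  e <- eigen(matrix(c(vrr, vrc, vrc, vcc), 2L), symmetric = TRUE)
  half_d <- sqrt(max(e$values[1L] - e$values[2L], 0))
  ctr <- c(mr, mc)
  rbind(ctr + half_d * e$vectors[, 1L], ctr - half_d * e$vectors[, 1L])
}

# Intensity-weighted centroid in a 5x5 window around a (row, col) matrix
# index (1-based in, 0-based sub-pixel out). The window minimum is
# subtracted so the centroid is invariant to constant offsets.
subpixel_centroid <- function(ch, p) {
  rs <- max(1L, p[1L] - 2L):min(nrow(ch), p[1L] + 2L)
  cs <- max(1L, p[2L] - 2L):min(ncol(ch), p[2L] + 2L)
  w <- ch[rs, cs, drop = FALSE] - min(ch[rs, cs])
  tw <- sum(w)
  if (tw == 0) return(c(p[1L] - 1, p[2L] - 1))
  c(sum(w * (rs - 1)) / tw,
    sum(t(w) * (cs - 1)) / tw)
}

#' Apply the two-spot acceptance rule
#'
#' From ranked candidates, a third candidate within `ambiguity_ratio` of the
#' second-strongest response makes the cell ambiguous (all such strong
#' candidates are kept, and the caller QC-fails on count != 2); clearly
#' weaker trailing candidates are dropped as noise.
#'
#' @param spots A `fish_spots` data frame, strongest first.
#' @param ambiguity_ratio Relative response defining "comparably strong".
#' @return Accepted subset of `spots`.
#' @export
accept_spots <- function(spots, ambiguity_ratio = 0.8) {
  if (nrow(spots) <= 2L) return(spots)
  cut <- ambiguity_ratio * spots$response[2L]
  spots[spots$response >= cut, , drop = FALSE]
}

#' Measure the chromosome-territory area inside the nucleus
#'
#' Otsu threshold computed over the paint intensities of nucleus-mask pixels
#' only (background outside the nucleus is irrelevant to the territory
#' definition); the territory is all thresholded pixels inside the mask,
#' every connected component kept. If the in-mask intensities show no real
#' contrast (class means closer than 4 pooled standard deviations), the
#' channel is either saturated — paint covering the whole nucleus, territory
#' = mask — or empty — no paint above the out-of-mask background, territory
#' area 0 with `no_signal = TRUE`.
#'
#' @param image A [calibrated_image()] with a `"paint"` channel.
#' @param geometry A `nucleus_geometry`.
#' @return List of class `territory_measurement`: `territory_mask`,
#'   `area_um2`, `threshold_used`, `no_signal`.
#' @export
measure_territory <- function(image, geometry) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(geometry, "nucleus_geometry"))
  ch <- if ("paint" %in% image$channel_names)
    get_channel(image, "paint") else image$pixels[, , 3L]
  mask <- geometry$mask
  vals <- ch[mask]
  out_vals <- ch[!mask]
  ps <- geometry$pixel_size_um
  result <- function(ter, thr, no_signal = FALSE) {
    stopifnot(!any(ter & !mask))  # territory must stay inside the nucleus
    structure(list(territory_mask = ter, area_um2 = sum(ter) * ps^2,
                   threshold_used = thr, no_signal = no_signal),
              class = "territory_measurement")
  }
  if (diff(range(vals)) == 0) {
    if (length(out_vals) && diff(range(out_vals)) == 0 &&
        vals[1L] > out_vals[1L])
      return(result(mask, -Inf))  # uniform paint above background: saturated
    warning("constant paint channel inside nucleus; territory area 0",
            call. = FALSE)
    return(result(mask & FALSE, NA_real_, no_signal = TRUE))
  }
  rng <- range(vals)
  scaled <- (vals - rng[1L]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1L)),
                         range = c(0, 1), levels = 256)
  thr <- rng[1L] + thr01 * diff(rng)
  lo <- vals[vals <= thr]; hi <- vals[vals > thr]
  pooled_sd <- sqrt((stats::var(lo) * (length(lo) - 1) +
                     stats::var(hi) * (length(hi) - 1)) /
                    max(1, length(vals) - 2))
  if (!is.finite(pooled_sd)) pooled_sd <- 0
  if (mean(hi) - mean(lo) < 4 * max(pooled_sd, 1)) {
    # no real bimodality: decide saturated vs empty against the out-of-mask
    # background level
    bg_mean <- if (length(out_vals)) mean(out_vals) else 0
    bg_sd <- if (length(out_vals) > 1) stats::sd(out_vals) else 0
    if (mean(vals) > bg_mean + 4 * max(bg_sd, 1)) return(result(mask, -Inf))
    warning("no paint signal above background; territory area 0",
            call. = FALSE)
    return(result(mask & FALSE, NA_real_, no_signal = TRUE))
  }
  ter <- mask & (ch > thr)
  result(ter, thr)
}
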