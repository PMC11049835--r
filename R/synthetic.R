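# Synthetic two-class FISH dataset generator with per-cell ground truth.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Study design: subjects, classes and cells per subject
#'
#' @param subjects Data frame with columns `subject_id` (unique) and
#'   `class` (`"low"` or `"high"` morphology-score class).
#' @param cells_per_subject Cells imaged per subject (default 50).
#' @param seed Integer seed controlling every random draw of the dataset.
#' @return Object of class `study_design`.
#' @export
study_design <- function(subjects, cells_per_subject = 50L, seed = 1L) {
  subjects <- as.data.frame(subjects)
  if (nrow(subjects) < 1L) stop("design must contain at least one subject",
                                call. = FALSE)
  if (!all(c("subject_id", "class") %in% names(subjects)))
    stop("`subjects` needs columns subject_id and class", call. = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject ids", call. = FALSE)
  if (!all(subjects$class %in% c("low", "high")))
    stop("class must be 'low' or 'high'", call. = FALSE)
  if (!is.numeric(cells_per_subject) || cells_per_subject < 1)
    stop("`cells_per_subject` must be >= 1", call. = FALSE)
  structure(list(subjects = subjects,
                 cells_per_subject = as.integer(cells_per_subject),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Default five-subject study design
#'
#' Two subjects in the high-score class and three in the low-score class,
#' 50 cells each (250 cells total: 100 high, 150 low).
#'
#' @param seed Integer seed.
#' @param cells_per_subject Cells per subject.
#' @return A [study_design()].
#' @export
default_design <- function(seed = 1L, cells_per_subject = 50L) {
  study_design(data.frame(subject_id = paste0("s", 1:5),
                          class = c("high", "high", "low", "low", "low")),
               cells_per_subject = cells_per_subject, seed = seed)
}

#' Nucleus geometry settings for the generator
#'
#' Semi-axes are drawn uniformly within `jitter` (relative) of the nominal
#' 2.25 x 1.5 µm human sperm-head half-axes; orientation is uniform.
#'
#' @param semi_major_um,semi_minor_um Nominal semi-axes in µm.
#' @param jitter Relative half-width of the uniform size jitter (<= 0.1
#'   keeps heads within normal morphometric range).
#' @param image_size Field of view in pixels (square).
#' @param center_jitter_px Uniform jitter of the nucleus center in px.
#' @return List of settings.
#' @export
nucleus_config <- function(semi_major_um = 2.25, semi_minor_um = 1.5,
                           jitter = 0.1, image_size = 128L,
                           center_jitter_px = 4) {
  list(semi_major_um = semi_major_um, semi_minor_um = semi_minor_um,
       jitter = jitter, image_size = as.integer(image_size),
       center_jitter_px = center_jitter_px)
}

place_spots <- function(itd, length_px, center, a, b, theta,
                        margin_px = 2.5, retries = 60L) {
  d <- itd * length_px
  for (i in seq_len(retries)) {
    # anchor: unit-disc sample mapped into the ellipse shrunk to 45% radius
    rho <- 0.45 * sqrt(stats::runif(1))
    ang <- stats::runif(1, 0, 2 * pi)
    u <- rho * cos(ang); v <- rho * sin(ang)
    anchor <- c(center[1] + a * u * sin(theta) + b * v * cos(theta),
                center[2] + a * u * cos(theta) - b * v * sin(theta))
    phi <- stats::runif(1, 0, pi)
    half <- (d / 2) * c(sin(phi), cos(phi))
    pts <- rbind(anchor + half, anchor - half)
    nn <- ellipse_norm(pts, center, a, b, theta)
    # (1 - norm) * b lower-bounds the distance to the boundary
    if (all((1 - nn) * b >= margin_px)) return(pts)
  }
  # fallback: chord along the major axis through the center
  half <- (d / 2) * c(sin(theta), cos(theta))
  pts <- rbind(center + half, center - half)
  nn <- ellipse_norm(pts, center, a, b, theta)
  if (all((1 - nn) * b >= 1)) return(pts)
  stop("spot placement failed: separation too large for nucleus",
       call. = FALSE)
}

place_territory <- function(mask, cta, center, a, b, theta) {
  pts <- mask_coords(mask)
  n_px <- nrow(pts)
  n_ter <- max(1L, min(n_px, round(cta * n_px)))
  rho <- 0.5 * sqrt(stats::runif(1))
  ang <- stats::runif(1, 0, 2 * pi)
  u <- rho * cos(ang); v <- rho * sin(ang)
  seed_pt <- c(center[1] + a * u * sin(theta) + b * v * cos(theta),
               center[2] + a * u * cos(theta) - b * v * sin(theta))
  d2 <- (pts[, 1L] - seed_pt[1L])^2 + (pts[, 2L] - seed_pt[2L])^2
  keep <- order(d2)[seq_len(n_ter)]
  ter <- mask & FALSE
  ter[cbind(pts[keep, 1L] + 1, pts[keep, 2L] + 1)] <- TRUE
  ter
}

#' Sample the ground truth of one synthetic sperm cell
#'
#' Draws `(itd, cta)` from the class preset, a jittered nucleus ellipse, two
#' telomere spot positions on a chord whose length is `itd` times the
#' nucleus length (the Feret diameter of the nucleus mask), and a connected
#' chromosome-territory region covering a fraction `cta` of the nucleus
#' pixels (exact to rounding). Consumes the current RNG stream.
#'
#' @param preset A [fish_preset()].
#' @param nucleus A [nucleus_config()].
#' @param pixel_size_um Microns per pixel.
#' @param correlation Copula correlation between ITD and CTA.
#' @return Object of class `cell_truth`: scalar geometry plus `nucleus_mask`
#'   and `territory_mask` matrices.
#' @export
sample_cell_truth <- function(preset, nucleus = nucleus_config(),
                              pixel_size_um = 1 / 12, correlation = 0) {
  stopifnot(inherits(preset, "fish_preset"))
  draw <- sample_preset(preset, 1L, correlation = correlation)
  sz <- nucleus$image_size
  a <- nucleus$semi_major_um * (1 + stats::runif(1, -nucleus$jitter, nucleus$jitter)) /
    pixel_size_um
  b <- nucleus$semi_minor_um * (1 + stats::runif(1, -nucleus$jitter, nucleus$jitter)) /
    pixel_size_um
  theta <- stats::runif(1, 0, pi)
  cj <- nucleus$center_jitter_px
  center <- (sz - 1) / 2 + stats::runif(2, -cj, cj)
  if (any(center - a - 6 < 0) || any(center + a + 6 > sz - 1))
    stop("field of view too small for nucleus", call. = FALSE)
  mask <- ellipse_mask(sz, sz, center, a, b, theta)
  fer <- feret_diameter(mask)
  spots <- place_spots(draw$itd, fer$length_px, center, a, b, theta)
  territory <- place_territory(mask, draw$cta, center, a, b, theta)
  # base/tip: random end carries the midpiece stub
  ends <- if (stats::runif(1) < 0.5) list(fer$p1, fer$p2) else list(fer$p2, fer$p1)
  structure(list(
    true_itd = draw$itd, true_cta = draw$cta,
    center = center, semi_major_px = a, semi_minor_px = b, theta = theta,
    length_px = fer$length_px,
    base = as.numeric(ends[[1L]]), tip = as.numeric(ends[[2L]]),
    spot1 = spots[1L, ], spot2 = spots[2L, ],
    nucleus_mask = mask, territory_mask = territory,
    nucleus_px = sum(mask), territory_px = sum(territory),
    pixel_size_um = pixel_size_um, image_size = sz),
    class = "cell_truth")
}

#' Rendering settings for synthetic FISH images
#'
#' Intensities are 16-bit counts. Noise is Poisson shot noise (photon gain
#' `gain` counts/photon) plus Gaussian read noise; `noise_scale = 0` gives a
#' noiseless deterministic render.
#'
#' @param background Per-channel background counts (counterstain, telomere,
#'   paint).
#' @param nucleus_intensity,territory_intensity Foreground fill counts.
#' @param stub_gain Intensity multiplier of the midpiece stub marking the
#'   base end of the nucleus in the counterstain channel.
#' @param spot_amplitude Peak amplitude of each telomere spot.
#' @param spot_sigma_px Gaussian sigma of rendered spots, px.
#' @param blur_sigma_px Optical blur applied to area channels, px.
#' @param gain,read_noise Noise model parameters (counts).
#' @param noise_scale Multiplier on both noise components.
#' @param n_spots_override If non-NULL, render this many telomere spots
#'   instead of 2 (quality-control fixtures).
#' @return List of settings.
#' @export
render_config <- function(background = c(500, 300, 300),
                          nucleus_intensity = 3000,
                          territory_intensity = 3000,
                          stub_gain = 1.5,
                          spot_amplitude = 12000,
                          spot_sigma_px = 2,
                          blur_sigma_px = 1,
                          gain = 4, read_noise = 20,
                          noise_scale = 1,
                          n_spots_override = NULL) {
  list(background = background, nucleus_intensity = nucleus_intensity,
       territory_intensity = territory_intensity, stub_gain = stub_gain,
       spot_amplitude = spot_amplitude, spot_sigma_px = spot_sigma_px,
       blur_sigma_px = blur_sigma_px, gain = gain, read_noise = read_noise,
       noise_scale = noise_scale, n_spots_override = n_spots_override)
}

add_noise <- function(m, config) {
  if (config$noise_scale <= 0) return(m)
  lam <- pmax(m, 0) / config$gain
  shot <- (stats::rpois(length(lam), lam) * config$gain - m)
  read <- stats::rnorm(length(m), 0, config$read_noise)
  m + config$noise_scale * (matrix(shot, nrow(m)) + matrix(read, nrow(m)))
}

gaussian_spot_field <- function(nr, nc, centers, amplitude, sigma) {
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centers))) {
    out <- out + amplitude *
      exp(-((rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2) / (2 * sigma^2))
  }
  out
}

blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Render one synthetic cell into a calibrated 3-channel image
#'
#' Channel 0: nucleus fill with a brighter midpiece stub at the base end;
#' channel 1: Gaussian telomere spots at the true sub-pixel positions;
#' channel 2: chromosome-territory fill. Area channels are blurred; all
#' channels receive Poisson-Gaussian noise (see [render_config()]).
#' Deterministic given the RNG state.
#'
#' @param truth A `cell_truth` from [sample_cell_truth()].
#' @param config A [render_config()].
#' @return A [calibrated_image()].
#' @export
render_cell_image <- function(truth, config = render_config()) {
  stopifnot(inherits(truth, "cell_truth"))
  sz <- truth$image_size
  if (any(truth$center - truth$semi_major_px < 0) ||
      any(truth$center + truth$semi_major_px > sz - 1))
    stop("field of view too small for nucleus", call. = FALSE)
  bg <- config$background
  mask <- truth$nucleus_mask

  ch0 <- matrix(bg[1L], sz, sz)
  ch0[mask] <- config$nucleus_intensity
  rr <- matrix(0:(sz - 1), sz, sz)
  cc <- matrix(0:(sz - 1), sz, sz, byrow = TRUE)
  stub <- mask & ((rr - truth$base[1L])^2 + (cc - truth$base[2L])^2 <= 2.5^2)
  ch0[stub] <- config$nucleus_intensity * config$stub_gain
  ch0 <- blur(ch0, config$blur_sigma_px)

  centers <- rbind(truth$spot1, truth$spot2)
  n_spots <- if (is.null(config$n_spots_override)) 2L
             else as.integer(config$n_spots_override)
  if (n_spots < 2L) centers <- centers[seq_len(n_spots), , drop = FALSE]
  if (nrow(centers) < n_spots) {
    # extra spots for QC fixtures: interior points on the nucleus axes,
    # taking the first clearly separated from the spots already placed
    major <- c(sin(truth$theta), cos(truth$theta))
    minor <- c(cos(truth$theta), -sin(truth$theta))
    cands <- rbind(truth$center + 0.45 * truth$semi_minor_px * minor,
                   truth$center - 0.45 * truth$semi_minor_px * minor,
                   truth$center + 0.45 * truth$semi_major_px * major,
                   truth$center - 0.45 * truth$semi_major_px * major)
    for (k in seq_len(nrow(cands))) {
      if (nrow(centers) >= n_spots) break
      d <- sqrt(rowSums((centers - matrix(cands[k, ], nrow(centers), 2,
                                          byrow = TRUE))^2))
      if (all(d >= 6)) centers <- rbind(centers, cands[k, ])
    }
  }
  ch1 <- matrix(bg[2L], sz, sz) +
    gaussian_spot_field(sz, sz, centers, config$spot_amplitude,
                        config$spot_sigma_px)

  ch2 <- matrix(bg[3L], sz, sz)
  ch2[truth$territory_mask] <- config$territory_intensity
  ch2 <- blur(ch2, config$blur_sigma_px)

  px <- array(0, dim = c(sz, sz, 3L))
  px[, , 1L] <- add_noise(ch0, config)
  px[, , 2L] <- add_noise(ch1, config)
  px[, , 3L] <- add_noise(ch2, config)
  px <- round(pmin(pmax(px, 0), 65535))
  calibrated_image(px, pixel_size_um = truth$pixel_size_um)
}

truth_row <- function(truth, cell_id, subject_id, class) {
  data.frame(cell_id = cell_id, subject_id = subject_id, class = class,
             true_itd = truth$true_itd, true_cta = truth$true_cta,
             center_row = truth$center[1L], center_col = truth$center[2L],
             semi_major_px = truth$semi_major_px,
             semi_minor_px = truth$semi_minor_px,
             theta_rad = truth$theta, length_px = truth$length_px,
             base_row = truth$base[1L], base_col = truth$base[2L],
             tip_row = truth$tip[1L], tip_col = truth$tip[2L],
             spot1_row = truth$spot1[1L], spot1_col = truth$spot1[2L],
             spot2_row = truth$spot2[1L], spot2_col = truth$spot2[2L],
             nucleus_px = truth$nucleus_px, territory_px = truth$territory_px,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-class FISH dataset
#'
#' Samples ground truth for every cell of the design (one RNG stream seeded
#' by `design$seed`, so the truth table is byte-identical across runs), then
#' optionally renders each cell (per-cell derived seeds, so skipping
#' rendering does not change the truth). With `outdir` set, writes one
#' multi-page TIFF + JSON sidecar per cell and `truth.csv`.
#'
#' @param design A [study_design()].
#' @param presets Named list with a [fish_preset()] for each class, keyed
#'   `low_score` / `high_score`.
#' @param render Render images? `FALSE` gives a fast truth-only dataset.
#' @param config A [render_config()].
#' @param nucleus A [nucleus_config()].
#' @param correlation Copula correlation between ITD and CTA.
#' @param outdir Optional output directory.
#' @return List of class `fish_dataset`: `truth` (data frame), `records`
#'   (list of `cell_truth`), `images` (list of [calibrated_image()] or
#'   NULL), `design`, `presets`.
#' @export
generate_dataset <- function(design, presets = default_presets(),
                             render = TRUE, config = render_config(),
                             nucleus = nucleus_config(), correlation = 0,
                             outdir = NULL) {
  stopifnot(inherits(design, "study_design"))
  classes <- unique(design$subjects$class)
  need <- paste0(classes, "_score")
  if (!all(need %in% names(presets)))
    stop(sprintf("missing preset(s): %s",
                 paste(setdiff(need, names(presets)), collapse = ", ")),
         call. = FALSE)
  cells <- expand.grid(cell = seq_len(design$cells_per_subject),
                       subject = seq_len(nrow(design$subjects)))
  ids <- sprintf("%s_c%03d", design$subjects$subject_id[cells$subject],
                 cells$cell)
  cls <- design$subjects$class[cells$subject]

  records <- with_seed(design$seed, {
    lapply(seq_len(nrow(cells)), function(i)
      sample_cell_truth(presets[[paste0(cls[i], "_score")]],
                        nucleus = nucleus, correlation = correlation))
  })
  truth <- do.call(rbind, lapply(seq_along(records), function(i)
    truth_row(records[[i]], ids[i],
              design$subjects$subject_id[cells$subject[i]], cls[i])))

  images <- NULL
  if (render) {
    images <- lapply(seq_along(records), function(i) {
      with_seed((design$seed * 10007 + i * 7919) %% 2147483647,
                render_cell_image(records[[i]], config))
    })
    names(images) <- ids
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
    if (render) {
      for (i in seq_along(images))
        write_image(images[[i]], file.path(outdir, paste0(ids[i], ".tif")),
                    seed = design$seed)
    }
  }
  structure(list(truth = truth, records = records, images = images,
                 design = design, presets = presets),
            class = "fish_dataset")
}

#' @export
print.fish_dataset <- function(x, ...) {
  cat(sprintf("<fish_dataset> %d cells (%d low, %d high), %s\n",
              nrow(x$truth), sum(x$truth$class == "low"),
              sum(x$truth$class == "high"),
              if (is.null(x$images)) "truth only" else "rendered"))
  invisible(x)
}
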