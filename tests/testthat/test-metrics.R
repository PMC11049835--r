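fake_geometry <- function(length_um, area_um2 = 10, ps = 1 / 12) {
  structure(list(mask = matrix(TRUE, 2, 2), area_um2 = area_um2,
                 length_um = length_um, base_point = c(0, 0),
                 tip_point = c(0, 1), centroid = c(0.5, 0.5),
                 pixel_size_um = ps, too_small = FALSE),
            class = "nucleus_geometry")
}

fake_spots <- function(p1_um, p2_um, ps = 1 / 12) {
  data.frame(row = c(p1_um[1], p2_um[1]) / ps,
             col = c(p1_um[2], p2_um[2]) / ps,
             response = c(100, 90), sigma = 2, in_mask = TRUE)
}

test_that("ITD is spot distance over nucleus length", {
  g <- fake_geometry(length_um = 4.8)
  expect_equal(compute_itd(fake_spots(c(1, 1), c(3.4, 1)), g), 0.5)
  expect_equal(compute_itd(fake_spots(c(2, 2), c(2, 2)), g), 0)
  expect_error(compute_itd(fake_spots(c(1, 1), c(2, 1))[1, ], g), "2 spots")
  sp <- fake_spots(c(1, 1), c(2, 1)); sp$in_mask[2] <- FALSE
  expect_error(compute_itd(sp, g), "mask")
})

test_that("CTA is territory area over nucleus area", {
  ps <- 1 / 12
  g <- fake_geometry(length_um = 4, area_um2 = 576 * ps^2)
  ter <- structure(list(territory_mask = NULL, area_um2 = 144 * ps^2,
                        threshold_used = 1, no_signal = FALSE),
                   class = "territory_measurement")
  expect_equal(compute_cta(ter, g), 0.25)
  ter$area_um2 <- g$area_um2
  expect_equal(compute_cta(ter, g), 1)
})

test_that("measure_cell composes the stages and reports the first QC failure", {
  cell <- clean_cell(seed = 21)
  m <- measure_cell(cell$image, cell_id = "c1", subject_id = "s1",
                    class = "low")
  expect_true(m$qc_pass)
  expect_identical(m$qc_reason, "")
  expect_equal(m$itd, cell$truth$true_itd, tolerance = 0.03)
  expect_equal(m$cta, cell$truth$true_cta, tolerance = 0.03)

  three <- clean_cell(seed = 22, n_spots_override = 3)
  m3 <- measure_cell(three$image)
  expect_false(m3$qc_pass)
  expect_identical(m3$qc_reason, "spot_count")
  expect_true(is.na(m3$itd) && is.na(m3$cta))

  blank <- calibrated_image(array(0, dim = c(64, 64, 3)))
  mb <- measure_cell(blank)
  expect_false(mb$qc_pass)
  expect_identical(mb$qc_reason, "segmentation")
})

test_that("measured ITD is stable under image rotation", {
  cell <- clean_cell(seed = 23, noise_scale = 0)
  base <- measure_cell(cell$image)
  expect_true(base$qc_pass)
  for (ang in c(20, 65)) {
    rot <- lapply(1:3, function(k)
      EBImage::imageData(EBImage::rotate(EBImage::Image(cell$image$pixels[, , k]),
                                         ang, bg.col = 400)))
    px <- array(0, dim = c(dim(rot[[1]]), 3))
    for (k in 1:3) px[, , k] <- pmax(rot[[k]], 0)
    m <- measure_cell(calibrated_image(px))
    expect_true(m$qc_pass)
    expect_equal(m$itd, base$itd, tolerance = 0.02)
  }
})

test_that("round-trip errors over many rendered cells are small", {
  ds <- cached("roundtrip60", {
    design <- study_design(data.frame(subject_id = c("a", "b"),
                                      class = c("low", "high")),
                           cells_per_subject = 30, seed = 77)
    d <- generate_dataset(design)
    list(truth = d$truth, meas = measure_cells(d))
  })
  ok <- ds$meas$qc_pass
  expect_gt(mean(ok), 0.9)
  itd_err <- abs(ds$meas$itd - ds$truth$true_itd)[ok]
  cta_err <- abs(ds$meas$cta - ds$truth$true_cta)[ok]
  expect_lt(median(itd_err), 0.01)
  expect_lt(median(cta_err), 0.01)
  expect_gt(mean(itd_err <= 0.03), 0.95)
  expect_gt(mean(cta_err <= 0.03), 0.95)
})
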