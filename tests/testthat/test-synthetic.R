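test_that("generated geometry embeds the drawn ITD and CTA exactly", {
  presets <- test_presets()
  set.seed(50)
  for (i in 1:25) {
    cls <- if (i %% 2) "low_score" else "high_score"
    tr <- sample_cell_truth(presets[[cls]])
    sep <- sqrt(sum((tr$spot1 - tr$spot2)^2))
    expect_equal(sep / tr$length_px, tr$true_itd, tolerance = 1e-8)
    expect_equal(tr$territory_px / tr$nucleus_px, tr$true_cta,
                 tolerance = 0.01)
    expect_false(any(tr$territory_mask & !tr$nucleus_mask))
    # spots inside the nucleus ellipse
    for (p in list(tr$spot1, tr$spot2)) {
      dx <- p[2] - tr$center[2]; dy <- p[1] - tr$center[1]
      u <- dx * cos(tr$theta) + dy * sin(tr$theta)
      v <- -dx * sin(tr$theta) + dy * cos(tr$theta)
      expect_lt((u / tr$semi_major_px)^2 + (v / tr$semi_minor_px)^2, 1)
    }
    # territory is a single connected component
    lab <- EBImage::bwlabel(EBImage::Image(tr$territory_mask * 1))
    expect_equal(max(EBImage::imageData(lab)), 1)
  }
})

test_that("a point-mass ITD preset forces the embedded separation ratio", {
  pm <- structure(list(name = "pm",
                       itd_params = c(shape1 = 5e5, shape2 = 5e5),
                       cta_params = c(shape1 = 10, shape2 = 30),
                       target_quantiles = list(itd = c(0.49, 0.5, 0.51),
                                               cta = c(0.1, 0.25, 0.45))),
                  class = "fish_preset")
  set.seed(51)
  tr <- sample_cell_truth(pm)
  sep <- sqrt(sum((tr$spot1 - tr$spot2)^2))
  expect_equal(sep / tr$length_px, 0.5, tolerance = 2e-3)
})

test_that("dataset generation honors the design and is seed-reproducible", {
  design <- default_design(seed = 9, cells_per_subject = 2)
  d1 <- generate_dataset(design, render = FALSE)
  expect_equal(nrow(d1$truth), 10)
  expect_equal(sum(d1$truth$class == "low"), 6)
  expect_equal(sum(d1$truth$class == "high"), 4)
  d2 <- generate_dataset(design, render = FALSE)
  expect_identical(d1$truth, d2$truth)
  # rendering does not perturb the truth stream
  d3 <- generate_dataset(design, render = TRUE)
  expect_identical(d1$truth, d3$truth)
  i1 <- generate_dataset(design, render = TRUE)
  expect_identical(i1$images[[3]]$pixels, d3$images[[3]]$pixels)
  # a different seed changes the draws
  d4 <- generate_dataset(default_design(seed = 10, cells_per_subject = 2),
                         render = FALSE)
  expect_false(identical(d1$truth$true_itd, d4$truth$true_itd))
})

test_that("design validation rejects degenerate inputs", {
  expect_error(study_design(data.frame(subject_id = "a", class = "low"),
                            cells_per_subject = 0), ">= 1")
  expect_error(study_design(data.frame(subject_id = c("a", "a"),
                                       class = c("low", "high"))),
               "duplicate")
  expect_error(study_design(data.frame(subject_id = character(0),
                                       class = character(0))),
               "at least one subject")
  expect_error(generate_dataset(
    study_design(data.frame(subject_id = "a", class = "high")),
    presets = default_presets()["low_score"], render = FALSE),
    "missing preset")
})

test_that("written datasets round-trip through the TIFF reader", {
  outdir <- withr::local_tempdir()
  design <- study_design(data.frame(subject_id = "s1", class = "low"),
                         cells_per_subject = 2, seed = 5)
  d <- generate_dataset(design, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "truth.csv")))
  tifs <- list.files(outdir, pattern = "\\.tif$")
  expect_equal(length(tifs), 2)
  back <- read_image(file.path(outdir, tifs[1]))
  expect_equal(back$pixels, d$images[[sub("[.]tif$", "", tifs[1])]]$pixels)
  expect_equal(back$pixel_size_um, 1 / 12)
})
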