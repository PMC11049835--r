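# Per-cell nuclear-architecture metrics: ITD and CTA, with QC.

#' Inter-telomeric distance, normalized to nucleus length
#'
#' Euclidean distance between the two telomere spot centers (in µm) divided
#' by the nucleus length (base-to-tip Feret diameter, µm). Values slightly
#' above 1 are possible for diagonal spot pairs and are allowed up to 1.5 by
#' downstream QC.
#'
#' @param spots A `fish_spots` data frame with exactly two in-mask spots.
#' @param geometry A `nucleus_geometry` with positive length.
#' @return Dimensionless ratio.
#' @export
compute_itd <- function(spots, geometry) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  if (nrow(spots) != 2L)
    stop(sprintf("ITD requires exactly 2 spots, got %d", nrow(spots)),
         call. = FALSE)
  if (!all(spots$in_mask)) stop("both spots must lie in the nucleus mask",
                                call. = FALSE)
  if (geometry$length_um <= 0) stop("nucleus length must be positive",
                                    call. = FALSE)
  d_px <- euclid(c(spots$row[1L], spots$col[1L]),
                 c(spots$row[2L], spots$col[2L]))
  px_to_um(d_px, geometry$pixel_size_um) / geometry$length_um
}

#' Chromosomal territory area, normalized to nucleus area
#'
#' @param territory A `territory_measurement`.
#' @param geometry A `nucleus_geometry` with positive area.
#' @return Dimensionless ratio in `[0, 1]`.
#' @export
compute_cta <- function(territory, geometry) {
  stopifnot(inherits(territory, "territory_measurement"),
            inherits(geometry, "nucleus_geometry"))
  if (geometry$area_um2 <= 0) stop("nucleus area must be positive",
                                   call. = FALSE)
  territory$area_um2 / geometry$area_um2
}

measurement_row <- function(cell_id, subject_id, class,
                            itd = NA_real_, cta = NA_real_,
                            qc_pass = FALSE, qc_reason = "") {
  data.frame(cell_id = cell_id, subject_id = subject_id, class = class,
             itd = itd, cta = cta, qc_pass = qc_pass, qc_reason = qc_reason,
             stringsAsFactors = FALSE)
}

#' Measure one cell end to end
#'
#' Runs segmentation, geometry QC, spot detection with the two-spot rule,
#' and territory measurement, in that fixed order; the first failing stage
#' determines `qc_reason` (`"segmentation"`, `"area_out_of_range"`,
#' `"length_out_of_range"`, `"spot_count"`, `"territory"`) and no metric
#' values are reported for failed cells.
#'
#' @param image A [calibrated_image()] (counterstain, telomere, paint).
#' @param cell_id,subject_id,class Labels copied into the result.
#' @param limits A [qc_limits()].
#' @param params A [spot_params()].
#' @return One-row data frame: `cell_id`, `subject_id`, `class`, `itd`,
#'   `cta`, `qc_pass`, `qc_reason`.
#' @export
measure_cell <- function(image, cell_id = "", subject_id = "",
                         class = NA_character_, limits = qc_limits(),
                         params = spot_params()) {
  geometry <- tryCatch(segment_nucleus(image), error = function(e) NULL)
  if (is.null(geometry) || isTRUE(geometry$too_small))
    return(measurement_row(cell_id, subject_id, class,
                           qc_reason = "segmentation"))
  qc <- qc_geometry(geometry, limits)
  if (!qc$pass)
    return(measurement_row(cell_id, subject_id, class, qc_reason = qc$reason))
  spots <- accept_spots(detect_telomere_spots(image, geometry, params))
  if (nrow(spots) != 2L)
    return(measurement_row(cell_id, subject_id, class,
                           qc_reason = "spot_count"))
  territory <- suppressWarnings(measure_territory(image, geometry))
  if (territory$no_signal)
    return(measurement_row(cell_id, subject_id, class,
                           qc_reason = "territory"))
  itd <- compute_itd(spots, geometry)
  cta <- compute_cta(territory, geometry)
  if (itd > 1.5)
    return(measurement_row(cell_id, subject_id, class, qc_reason = "itd_range"))
  measurement_row(cell_id, subject_id, class, itd = itd, cta = cta,
                  qc_pass = TRUE)
}

#' Measure every cell of a dataset
#'
#' @param dataset A rendered `fish_dataset` from [generate_dataset()], or a
#'   named list of [calibrated_image()]s plus a `labels` data frame
#'   (`cell_id`, `subject_id`, `class`).
#' @param labels Required when `dataset` is a plain image list.
#' @param limits A [qc_limits()].
#' @param params A [spot_params()].
#' @return Data frame with one row per cell (see [measure_cell()]).
#' @export
measure_cells <- function(dataset, labels = NULL, limits = qc_limits(),
                          params = spot_params()) {
  if (inherits(dataset, "fish_dataset")) {
    if (is.null(dataset$images))
      stop("dataset was generated with render = FALSE; no images to measure",
           call. = FALSE)
    images <- dataset$images
    labels <- dataset$truth[, c("cell_id", "subject_id", "class")]
  } else {
    images <- dataset
    if (is.null(labels)) stop("`labels` required for a plain image list",
                              call. = FALSE)
  }
  out <- lapply(seq_along(images), function(i)
    measure_cell(images[[i]], cell_id = labels$cell_id[i],
                 subject_id = labels$subject_id[i], class = labels$class[i],
                 limits = limits, params = params))
  do.call(rbind, out)
}
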