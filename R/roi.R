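#' Detect tissue in a spot image
#'
#' Classifies pixels whose mean per-channel optical density exceeds a fixed
#' floor as tissue (bare glass is bright and nearly OD-free), fills enclosed
#' holes, and removes connected specks smaller than `min_speck_px` pixels
#' (dust and debris).
#'
#' @param image A [spot_image()].
#' @param od_floor Mean-OD threshold for tissue (default 0.1).
#' @param min_speck_px Minimum connected-component size kept (default 100).
#' @param epsilon Intensity offset of the OD transform.
#' @return Logical H x W tissue mask.
#' @export
detect_tissue <- function(image, od_floor = 0.1, min_speck_px = 100,
                          epsilon = 1) {
  px <- image$pixels
  od <- -log10((px + epsilon) / 255)
  total <- (od[, , 1] + od[, , 2] + od[, , 3]) / 3
  mask <- total > od_floor
  if (!any(mask)) return(mask)
  mask <- EBImage::fillHull(mask * 1) > 0
  if (min_speck_px > 0) {
    lab <- EBImage::bwlabel(mask * 1)
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_speck_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Apply the edge margin to a tissue mask
#'
#' Erodes the tissue mask so that every remaining pixel lies at least
#' `margin_px` (Euclidean) from the nearest non-tissue pixel, guarding the
#' analysis against artificially stained spot edges. `margin_px = 0`
#' returns the tissue mask itself.
#'
#' @param tissue_mask Logical tissue mask.
#' @param margin_px Margin in pixels (>= 0, default 100, i.e. about 25 um at
#'   0.25 um/px).
#' @param mpp Microns per pixel, used to express the ROI area physically.
#' @param min_roi_area_um2 Adequacy threshold passed to [area_control()].
#' @return Object of class `roi_mask`: list with `mask`, `area_um2` and
#'   `adequate`.
#' @export
apply_margin <- function(tissue_mask, margin_px = 100, mpp = 0.25,
                         min_roi_area_um2 = 37000) {
  stopifnot(margin_px >= 0)
  tissue_mask <- tissue_mask != 0
  roi <- if (!any(tissue_mask)) {
    tissue_mask
  } else if (margin_px == 0) {
    tissue_mask
  } else {
    d <- EBImage::distmap(tissue_mask * 1)
    tissue_mask & d >= margin_px
  }
  area <- sum(roi) * mpp^2
  structure(list(mask = roi, area_um2 = area,
                 adequate = area_control(area, min_roi_area_um2)),
            class = "roi_mask")
}

#' ROI area adequacy control
#'
#' A spot is adequate only if its ROI area strictly exceeds
#' `min_roi_area_um2` (default 37000 um^2, about 5% of the ROI of an intact
#' 1-mm spot).
#'
#' @param roi An `roi_mask` from [apply_margin()], or a numeric area in
#'   um^2.
#' @param min_roi_area_um2 Threshold in um^2.
#' @return Logical adequacy.
#' @export
area_control <- function(roi, min_roi_area_um2 = 37000) {
  area <- if (inherits(roi, "roi_mask")) roi$area_um2 else as.numeric(roi)
  area > min_roi_area_um2
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px, %.0f um^2, %s\n", sum(x$mask), x$area_um2,
              if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' Analyze one spot image end to end
#'
#' Runs the full digital analysis on a spot: tissue detection, ROI margin,
#' area control, stain separation, curvilinear enhancement, membrane
#' segmentation inside the ROI, skeletonization, fragment linking and
#' pruning, the connectivity statistic and the HER2 score. Spots flagged as
#' manually excluded (inadequate sample or DCIS, recorded by visual review
#' in the input metadata) are honored before any processing; spots whose
#' ROI fails the area control carry no connectivity result.
#'
#' @param image A [spot_image()].
#' @param config An [mc_config()].
#' @param manual_exclude Was the spot excluded by visual review?
#' @param exclude_reason Free-text reason recorded with a manual exclusion.
#' @return Object of class `spot_result`: list with `spot_id`, `patient_id`,
#'   `status` (one of `"analyzed"`, `"excluded_area"`, `"excluded_manual"`),
#'   `roi` (an `roi_mask`, absent for manual exclusions) and
#'   `connectivity_result` (present iff `status == "analyzed"`).
#' @export
analyze_spot <- function(image, config = mc_config(),
                         manual_exclude = FALSE,
                         exclude_reason = NA_character_) {
  config <- validate_config(config)
  res <- list(spot_id = image$spot_id, patient_id = image$patient_id,
              mpp = image$mpp, roi = NULL, connectivity_result = NULL,
              status = NA_character_, exclude_reason = exclude_reason)
  class(res) <- "spot_result"
  if (isTRUE(manual_exclude)) {
    res$status <- "excluded_manual"
    return(res)
  }
  tissue <- detect_tissue(image, od_floor = config$tissue_od_floor,
                          min_speck_px = config$tissue_min_speck_px)
  roi <- apply_margin(tissue, margin_px = config$margin_px, mpp = image$mpp,
                      min_roi_area_um2 = config$min_roi_area_um2)
  res$roi <- roi
  if (!roi$adequate) {
    res$status <- "excluded_area"
    return(res)
  }
  stain <- rgb_to_stain_od(image, stain_vectors = config$stain_vectors)
  resp <- linear_structure_response(stain, scale_um = config$ridge_scale_um,
                                    mpp = image$mpp)
  mask <- segment_membrane(resp, stain, min_dab_od = config$min_dab_od)
  mask <- mask & roi$mask
  res$connectivity_result <- measure_connectivity(mask, config)
  res$status <- "analyzed"
  res
}

#' @export
print.spot_result <- function(x, ...) {
  cat(sprintf("<spot_result> %s (patient %s): %s\n", x$spot_id,
              x$patient_id, x$status))
  if (!is.null(x$roi))
    cat(sprintf("  ROI area %.0f um^2\n", x$roi$area_um2))
  if (!is.null(x$connectivity_result)) {
    cr <- x$connectivity_result
    cat(sprintf("  connectivity %.6f -> %s\n", cr$connectivity,
                as.character(cr$her2_score)))
  }
  invisible(x)
}

#' @export
as.data.frame.spot_result <- function(x, ...) {
  cr <- x$connectivity_result
  data.frame(
    spot_id = x$spot_id, patient_id = x$patient_id, status = x$status,
    roi_area_um2 = if (is.null(x$roi)) NA_real_ else x$roi$area_um2,
    n_fragments = if (is.null(cr)) NA_integer_ else cr$n_fragments,
    total_skeleton_px = if (is.null(cr)) NA_integer_ else
      cr$total_skeleton_px,
    connectivity = if (is.null(cr)) NA_real_ else round(cr$connectivity, 6),
    her2_score = if (is.null(cr)) NA_character_ else
      as.character(cr$her2_score),
    exclude_reason = x$exclude_reason,
    stringsAsFactors = FALSE
  )
}

#' Analyze a batch of spots from a manifest
#'
#' Runs [analyze_spot()] over a manifest table. A failure on one spot is
#' recorded in its result row (`status = "error"`) and the batch continues.
#'
#' @param manifest Data frame (or path to a CSV) with columns `spot_id`,
#'   `patient_id`, `image_path`, and optionally `mpp`, `manual_exclude`
#'   (0/1) and `exclude_reason`.
#' @param config An [mc_config()]; its `mpp` is the fallback for rows
#'   without one.
#' @return Data frame with one row per spot (see
#'   [as.data.frame.spot_result()]).
#' @export
analyze_batch <- function(manifest, config = mc_config()) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("spot_id", "patient_id", "image_path")
  if (!all(need %in% names(manifest)))
    stop("input error: manifest needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    mpp <- if (!is.null(m$mpp) && is.finite(m$mpp)) m$mpp else config$mpp
    excl <- isTRUE(m$manual_exclude == 1) || isTRUE(m$manual_exclude)
    reason <- if (!is.null(m$exclude_reason)) as.character(m$exclude_reason)
              else NA_character_
    tryCatch({
      img <- read_spot_image(m$image_path, mpp = mpp, spot_id = m$spot_id,
                             patient_id = m$patient_id)
      as.data.frame(analyze_spot(img, config, manual_exclude = excl,
                                 exclude_reason = reason))
    }, error = function(e) {
      data.frame(spot_id = m$spot_id, patient_id = m$patient_id,
                 status = "error", roi_area_um2 = NA_real_,
                 n_fragments = NA_integer_, total_skeleton_px = NA_integer_,
                 connectivity = NA_real_, her2_score = NA_character_,
                 exclude_reason = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Write a membrane-mask overlay for visual inspection
#'
#' Renders the source image with membrane (or ROI) mask pixels painted
#' green, the usual debugging view of the segmentation.
#'
#' @param image A [spot_image()].
#' @param mask Logical mask with the image's dimensions.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_overlay <- function(image, mask, path) {
  px <- image$pixels / 255
  px[, , 1][mask] <- 0
  px[, , 2][mask] <- 1
  px[, , 3][mask] <- 0
  png::writePNG(px, path)
  invisible(path)
}
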