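#' Spherical region of interest
#'
#' @param center_mm World coordinates of the sphere center (length 3, mm).
#' @param diameter_mm Sphere diameter, mm (> 0). The conventional
#'   background sphere over contralateral normal brain is 15 mm in
#'   diameter.
#' @return An object of class `sphere_roi`.
#' @export
sphere_roi <- function(center_mm, diameter_mm) {
  stopifnot(length(center_mm) == 3L, all(is.finite(center_mm)))
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop_("'diameter_mm' must be > 0")
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = as.numeric(diameter_mm)),
            class = "sphere_roi")
}

#' Rasterize a spherical ROI onto an image grid
#'
#' A voxel is included iff its center lies within `diameter_mm / 2` of the
#' sphere center (center-in convention). A sphere that misses the grid
#' entirely yields an empty mask with a warning, not an error.
#'
#' @param roi A [sphere_roi()].
#' @param geom A [image_geometry()] (or a `dynamic_image`).
#' @return Logical 3D array (a voxel mask).
#' @export
sphere_mask <- function(roi, geom) {
  stopifnot(inherits(roi, "sphere_roi"))
  geom <- image_geometry(geom)
  m <- ellipsoid_mask_(geom, roi$center_mm, rep(roi$diameter_mm / 2, 3))
  if (!any(m)) warning("sphere ROI covers no voxel centers; mask is empty")
  m
}

#' Volume of a voxel mask in milliliters
#'
#' @param mask Logical 3D array.
#' @param voxel_size_mm Isotropic voxel spacing, mm.
#' @return Volume in mL (voxel count times voxel volume / 1000).
#' @export
mask_volume_ml <- function(mask, voxel_size_mm) {
  sum(mask) * voxel_size_mm^3 / 1000
}

#' Mirror a point across the midsagittal plane
#'
#' Reflects the x-coordinate about the plane `x = midsagittal_x_mm`,
#' leaving y and z unchanged: the standard construction of a contralateral
#' background location from a tumor location. The operation is an
#' involution.
#'
#' @param point_mm World point (length 3, mm).
#' @param midsagittal_x_mm x-coordinate of the midsagittal plane, mm.
#' @return The mirrored point.
#' @export
mirror_contralateral <- function(point_mm, midsagittal_x_mm) {
  stopifnot(length(point_mm) == 3L)
  c(2 * midsagittal_x_mm - point_mm[1], point_mm[2], point_mm[3])
}

#' Mean SUV in a background region
#'
#' Arithmetic mean of the frame's voxel values over a mask or spherical
#' ROI; the contralateral normal-brain SUVmean that normalizes all
#' tumor-to-background ratios.
#'
#' @param frame 3D numeric array (one time frame, SUV).
#' @param roi A logical mask with the frame's dimensions, or a
#'   [sphere_roi()] (then `geom` is required).
#' @param geom [image_geometry()] used to rasterize a `sphere_roi`.
#' @return Mean SUV (scalar).
#' @export
background_mean <- function(frame, roi, geom = NULL) {
  mask <- if (inherits(roi, "sphere_roi")) {
    if (is.null(geom)) stop_("'geom' is required when 'roi' is a sphere")
    sphere_mask(roi, geom)
  } else roi
  stopifnot(is.logical(mask), identical(dim(mask), dim(frame)))
  if (!any(mask)) stop_("background mask is empty; background mean undefined")
  mean(frame[mask])
}

#' Threshold segmentation of metabolically active tumor
#'
#' Within a search region, selects the voxels whose SUV is at least
#' `k` times the background mean (a minimum threshold, so boundary voxels
#' at exactly `k * bg` are included), optionally removing an exclusion
#' mask (e.g., blood pool or adjacent choroid plexus).
#'
#' @param frame 3D numeric array (SUV).
#' @param search Logical search mask (the tumor ROI), nonempty.
#' @param bg Background SUVmean (> 0).
#' @param k Threshold multiple (e.g., 1.3, 1.6, 1.9).
#' @param exclude Optional logical mask of voxels to drop.
#' @return Logical mask of segmented tumor voxels.
#' @export
threshold_segment <- function(frame, search, bg, k, exclude = NULL) {
  stopifnot(is.logical(search), identical(dim(search), dim(frame)))
  if (!any(search)) stop_("'search' mask is empty")
  if (!is.finite(bg) || bg <= 0) stop_("'bg' must be > 0")
  if (!is.finite(k) || k <= 0) stop_("'k' must be > 0")
  m <- search & frame >= k * bg
  if (!is.null(exclude)) {
    stopifnot(is.logical(exclude), identical(dim(exclude), dim(frame)))
    m <- m & !exclude
  }
  m
}

#' Semiquantitative uptake metrics for one lesion at one frame
#'
#' Computes SUVmax over the search region (minus exclusions), the
#' background-normalized TBmax = SUVmax / background, and, for each
#' threshold multiple k, the thresholded tumor SUVmean, its ratio
#' TBmean_k = SUVmean_k / background, and the segmented volume. An empty
#' threshold mask yields `NA` (missing) SUVmean/TBmean with zero volume,
#' so downstream statistics can exclude such frames explicitly.
#'
#' @param frame 3D numeric array (SUV).
#' @param search Logical search mask (nonempty).
#' @param bg Background SUVmean (> 0).
#' @param voxel_size_mm Voxel spacing, mm, for volumes.
#' @param thresholds Threshold multiples (default `c(1.3, 1.6, 1.9)`).
#' @param exclude Optional exclusion mask.
#' @param lesion_id,time_min Identifiers copied into the output row.
#' @return A one-row data.frame with columns `lesion_id`, `time_min`,
#'   `background_mean`, `suv_max`, `tb_max`, `suv_mean_roi` (unthresholded
#'   ROI mean, used for blood-pool/normal-tissue curves), and for each
#'   threshold k `suv_mean_<k>`, `tb_mean_<k>`, `volume_ml_<k>`.
#' @export
lesion_metrics <- function(frame, search, bg, voxel_size_mm,
                           thresholds = c(1.3, 1.6, 1.9), exclude = NULL,
                           lesion_id = NA, time_min = NA_real_) {
  stopifnot(is.logical(search), identical(dim(search), dim(frame)))
  if (!any(search)) stop_("'search' mask is empty")
  if (!is.finite(bg) || bg <= 0) stop_("'bg' must be > 0")
  eff <- search
  if (!is.null(exclude)) eff <- eff & !exclude
  if (!any(eff)) stop_("search mask is empty after exclusions")
  suv_max <- max(frame[eff])
  row <- data.frame(lesion_id = lesion_id, time_min = time_min,
                    background_mean = bg, suv_max = suv_max,
                    tb_max = suv_max / bg,
                    suv_mean_roi = mean(frame[eff]),
                    stringsAsFactors = FALSE)
  for (k in thresholds) {
    m <- threshold_segment(frame, search, bg, k, exclude)
    nk <- sum(m)
    sm <- if (nk > 0) mean(frame[m]) else NA_real_
    row[[sprintf("suv_mean_%g", k)]] <- sm
    row[[sprintf("tb_mean_%g", k)]] <- sm / bg
    row[[sprintf("volume_ml_%g", k)]] <- nk * voxel_size_mm^3 / 1000
  }
  row
}

#' Uptake metrics for a cohort of lesions across all frames
#'
#' For every lesion and frame, measures the background mean in that
#' frame (one fixed background sphere per lesion, typically the
#' contralateral mirror of the lesion), then computes [lesion_metrics()].
#'
#' @param img A [dynamic_image()].
#' @param searches Named list of logical search masks, one per lesion.
#' @param backgrounds Named list (same names) of [sphere_roi()]s or masks.
#' @param thresholds Threshold multiples.
#' @param excludes Optional named list of exclusion masks.
#' @param frames Frame indices to measure (default: all). Frames during
#'   the tracer infusion carry near-zero background activity, for which
#'   background-normalized ratios are undefined; callers typically pass
#'   the post-infusion frames.
#' @return A data.frame of class `uptake_metrics`, one row per
#'   lesion x frame.
#' @export
compute_uptake_metrics <- function(img, searches, backgrounds,
                                   thresholds = c(1.3, 1.6, 1.9),
                                   excludes = NULL, frames = NULL) {
  stopifnot(inherits(img, "dynamic_image"), length(searches) >= 1,
            !is.null(names(searches)),
            all(names(searches) %in% names(backgrounds)))
  geom <- image_geometry(img)
  bg_masks <- lapply(backgrounds, function(b) {
    if (inherits(b, "sphere_roi")) sphere_mask(b, geom) else b
  })
  if (is.null(frames)) frames <- seq_len(n_frames(img$schedule))
  rows <- list()
  for (id in names(searches)) {
    excl <- if (!is.null(excludes)) excludes[[id]] else NULL
    for (f in frames) {
      frame <- img$data[, , , f]
      bg <- background_mean(frame, bg_masks[[id]])
      rows[[length(rows) + 1L]] <- lesion_metrics(
        frame, searches[[id]], bg, img$voxel_size_mm, thresholds, excl,
        lesion_id = id, time_min = img$schedule$mid_min[f])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("uptake_metrics", "data.frame")
  out
}
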