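#' Write a dynamic image as NIfTI plus a frame-timing sidecar
#'
#' Writes `<prefix>.nii.gz` (4D, voxel spacing in the header) and
#' `<prefix>_frames.json` with fields `FrameTimesStart` (seconds from
#' injection) and `FrameDuration` (seconds).
#'
#' @param img A [dynamic_image()].
#' @param prefix Output path prefix (no extension).
#' @return Invisibly, the NIfTI path.
#' @export
write_dynamic_image <- function(img, prefix) {
  stopifnot(inherits(img, "dynamic_image"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- c(rep(img$voxel_size_mm, 3), 1)
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(nii, path)
  jsonlite::write_json(
    list(FrameTimesStart = img$schedule$start_s,
         FrameDuration = img$schedule$duration_s),
    paste0(prefix, "_frames.json"), digits = NA)
  invisible(path)
}

#' Read a dynamic image written by [write_dynamic_image()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(prefix) {
  nii <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, "_frames.json"),
                              simplifyVector = TRUE)
  starts <- as.numeric(side$FrameTimesStart)
  durs <- as.numeric(side$FrameDuration)
  sched <- make_frame_schedule(lapply(seq_along(durs), function(i) c(1, durs[i])))
  if (max(abs(sched$start_s - starts)) > 1e-6)
    stop_("frame-timing sidecar is not contiguous from t = 0")
  dynamic_image(array(as.numeric(nii), dim = dim(nii)),
                voxel_size_mm = RNifti::pixdim(nii)[1],
                schedule = sched)
}

#' Write / read a 3D mask or label volume as NIfTI
#'
#' Masks are stored as integers (0/1 for logical masks; tissue ids for
#' label volumes).
#'
#' @param mask Logical or integer 3D array.
#' @param path Output `.nii.gz` path.
#' @param voxel_size_mm Voxel spacing, mm.
#' @return `write_mask`: invisibly, `path`. `read_mask`: the array
#'   (integer; compare with `> 0` for logical use).
#' @export
write_mask <- function(mask, path, voxel_size_mm) {
  arr <- array(as.integer(mask), dim = dim(mask))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  nii <- RNifti::readNifti(path)
  array(as.integer(nii), dim = dim(nii))
}

#' Write phantom ground truth as JSON
#'
#' Per-lesion kinetics-derived truths (plateau SUV, true
#' tumor-to-background ratio, grade, center, radius) and the noiseless
#' per-tissue frame TACs; the label volume itself is written separately
#' with [write_mask()].
#'
#' @param truth The `truth` element of [render_phantom()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(tissue_ids = truth$tissue_ids,
         frame_tacs = truth$frame_tacs,
         plateau_suv = as.list(truth$plateau_suv),
         tb_true = as.list(truth$tb_true),
         brain_plateau_suv = truth$brain_plateau_suv,
         lesion_grades = as.list(truth$lesion_grades),
         lesion_centers = truth$lesion_centers,
         lesion_radii = as.list(truth$lesion_radii)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
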