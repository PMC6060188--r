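#' 4D dynamic PET image container
#'
#' A 4D array of SUV values indexed (x, y, z, frame) together with its
#' isotropic voxel spacing, frame schedule, and world origin. World
#' coordinates are in mm; the center of voxel (i, j, k) (1-based) sits at
#' `origin + (c(i, j, k) - 0.5) * voxel_size_mm`.
#'
#' @param data 4D numeric array; the fourth axis must match the schedule.
#' @param voxel_size_mm Positive isotropic voxel spacing, mm.
#' @param schedule A [make_frame_schedule()] object.
#' @param origin_mm World coordinate of the volume corner (length 3).
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_size_mm, schedule, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            inherits(schedule, "frame_schedule"))
  if (dim(data)[4] != n_frames(schedule))
    stop_("fourth axis of 'data' must equal the number of frames in 'schedule'")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L || voxel_size_mm <= 0)
    stop_("'voxel_size_mm' must be a positive scalar")
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         schedule = schedule, origin_mm = as.numeric(origin_mm)),
    class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %d x %d x %d voxels x %d frames, %.3g mm voxels\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm))
  invisible(x)
}

#' Spatial geometry of an image grid
#'
#' @param x A `dynamic_image`, or a list with fields `dim` (length 3),
#'   `voxel_size_mm`, `origin_mm`.
#' @return A list with `dim`, `voxel_size_mm`, `origin_mm`.
#' @export
image_geometry <- function(x) {
  if (inherits(x, "dynamic_image"))
    return(list(dim = dim(x$data)[1:3], voxel_size_mm = x$voxel_size_mm,
                origin_mm = x$origin_mm))
  stopifnot(is.list(x), length(x$dim) == 3L)
  list(dim = as.integer(x$dim), voxel_size_mm = as.numeric(x$voxel_size_mm),
       origin_mm = if (is.null(x$origin_mm)) c(0, 0, 0) else as.numeric(x$origin_mm))
}

# Voxel-center world coordinates along one axis.
axis_centers_ <- function(geom, axis) {
  geom$origin_mm[axis] + (seq_len(geom$dim[axis]) - 0.5) * geom$voxel_size_mm
}

# Logical 3D mask of an ellipsoid (center-in convention: a voxel belongs
# iff its center is inside). Spheres are the semi_axes-equal case.
ellipsoid_mask_ <- function(geom, center, semi_axes) {
  dx <- ((axis_centers_(geom, 1) - center[1]) / semi_axes[1])^2
  dy <- ((axis_centers_(geom, 2) - center[2]) / semi_axes[2])^2
  dz <- ((axis_centers_(geom, 3) - center[3]) / semi_axes[3])^2
  outer(outer(dx, dy, "+"), dz, "+") <= 1
}

#' Specify a synthetic dynamic brain-PET phantom
#'
#' Defines the geometry, tissue kinetics, blur, and noise of a phantom.
#' The brain is an ellipsoid of uniform normal-parenchyma kinetics holding
#' pairwise-disjoint spherical lesions and a spherical venous (blood-pool)
#' region; everything outside the brain sits at a constant `outside_suv`.
#'
#' @param grid_shape Integer length-3 vector of voxel counts per axis.
#' @param voxel_size_mm Isotropic voxel spacing, mm (> 0).
#' @param brain List `(center, semi_axes)` in mm defining the brain
#'   ellipsoid.
#' @param lesions List of lesions, each a list with `id` (unique integer
#'   >= 10), `center` (mm), `radius_mm`, `kinetics` ([tissue_kinetics()]),
#'   and `grade` (`"HGG"` or `"LGG"`).
#' @param normal_kinetics [tissue_kinetics()] for normal brain parenchyma.
#' @param venous Optional list `(center, radius_mm, kinetics)` for the
#'   venous confluence.
#' @param outside_suv Constant SUV outside the brain (default 0).
#' @param psf_fwhm_mm Gaussian point-spread FWHM, mm (default 4.6, a
#'   typical final reconstructed resolution for a high-resolution brain
#'   tomograph).
#' @param noise_sigma SD of additive Gaussian noise, SUV (>= 0).
#' @param schedule Frame schedule (default [fluciclovine_schedule()]).
#' @param seed Integer seed controlling the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm, brain, lesions,
                         normal_kinetics, venous = NULL, outside_suv = 0,
                         psf_fwhm_mm = 4.6, noise_sigma = 0,
                         schedule = fluciclovine_schedule(), seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            inherits(normal_kinetics, "tissue_kinetics"),
            inherits(schedule, "frame_schedule"))
  if (voxel_size_mm <= 0) stop_("'voxel_size_mm' must be > 0")
  if (psf_fwhm_mm < 0) stop_("'psf_fwhm_mm' must be >= 0")
  if (noise_sigma < 0) stop_("'noise_sigma' must be >= 0")
  if (length(lesions) == 0) stop_("a phantom needs at least one lesion")
  ids <- vapply(lesions, function(l) as.integer(l$id), integer(1))
  if (anyDuplicated(ids) || any(ids < 10L))
    stop_("lesion ids must be unique integers >= 10")
  for (l in lesions) {
    stopifnot(inherits(l$kinetics, "tissue_kinetics"), l$radius_mm > 0,
              l$grade %in% c("HGG", "LGG"))
  }
  if (!is.null(venous)) stopifnot(inherits(venous$kinetics, "tissue_kinetics"))
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         brain = brain, lesions = lesions, normal_kinetics = normal_kinetics,
         venous = venous, outside_suv = outside_suv, psf_fwhm_mm = psf_fwhm_mm,
         noise_sigma = noise_sigma, schedule = schedule,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Tissue label codes: 0 outside, 1 normal brain, 2 venous, lesion ids as
# given (>= 10).
render_labels_ <- function(spec) {
  geom <- list(dim = spec$grid_shape, voxel_size_mm = spec$voxel_size_mm,
               origin_mm = c(0, 0, 0))
  geom <- image_geometry(geom)
  brain <- ellipsoid_mask_(geom, spec$brain$center, spec$brain$semi_axes)
  label <- array(0L, dim = geom$dim)
  label[brain] <- 1L
  if (!is.null(spec$venous)) {
    vm <- ellipsoid_mask_(geom, spec$venous$center, rep(spec$venous$radius_mm, 3))
    if (any(vm & !brain)) stop_("venous region extends outside the brain")
    label[vm] <- 2L
  }
  for (l in spec$lesions) {
    lm <- ellipsoid_mask_(geom, l$center, rep(l$radius_mm, 3))
    if (any(lm & !brain)) stop_("lesion ", l$id, " extends outside the brain")
    if (any(label[lm] >= 10L)) stop_("overlapping lesions in phantom spec")
    if (any(label[lm] == 2L)) stop_("lesion ", l$id, " overlaps the venous region")
    label[lm] <- as.integer(l$id)
  }
  list(label = label, geom = geom)
}

#' Render a phantom into a dynamic image with ground truth
#'
#' Each voxel of each frame takes the time-average of its tissue's TAC
#' over the frame interval; the volume is then blurred with the spec's
#' Gaussian PSF and degraded with additive Gaussian noise. The returned
#' ground truth (labels, noiseless per-tissue frame TACs, true plateau
#' SUVs and true tumor-to-background ratios) describes the image before
#' blur and noise. Rendering is deterministic: the same spec and seed
#' give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a [dynamic_image()]) and `truth` (a list
#'   with `label`, `tissue_ids`, `frame_tacs` — one row per tissue —,
#'   `plateau_suv`, `tb_true`, `lesion_grades`, `lesion_centers`,
#'   `lesion_radii`).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- render_labels_(spec)
  sched <- spec$schedule
  nf <- n_frames(sched)

  ids <- c(0L, 1L, if (!is.null(spec$venous)) 2L,
           vapply(spec$lesions, function(l) as.integer(l$id), integer(1)))
  kins <- c(list(NULL, spec$normal_kinetics),
            if (!is.null(spec$venous)) list(spec$venous$kinetics),
            lapply(spec$lesions, `[[`, "kinetics"))
  frame_tacs <- matrix(0, nrow = length(ids), ncol = nf,
                       dimnames = list(as.character(ids), NULL))
  for (i in seq_along(ids)) {
    frame_tacs[i, ] <- if (ids[i] == 0L) rep(spec$outside_suv, nf)
                       else tissue_frame_averages(kins[[i]], sched)
  }

  idx <- match(lab$label, ids)
  vox <- array(0, dim = c(spec$grid_shape, nf))
  for (f in seq_len(nf)) {
    vox[, , , f] <- array(frame_tacs[, f][idx], dim = spec$grid_shape)
  }
  img <- dynamic_image(vox, spec$voxel_size_mm, sched)
  img <- apply_psf(img, spec$psf_fwhm_mm)
  img <- add_noise(img, spec$noise_sigma, seed = spec$seed)

  brain_plateau <- spec$normal_kinetics$plateau_suv
  lesion_ids <- vapply(spec$lesions, function(l) as.integer(l$id), integer(1))
  plateau <- vapply(spec$lesions, function(l) l$kinetics$plateau_suv, numeric(1))
  truth <- list(
    label = lab$label,
    tissue_ids = ids,
    frame_tacs = frame_tacs,
    plateau_suv = stats::setNames(plateau, lesion_ids),
    tb_true = stats::setNames(plateau / brain_plateau, lesion_ids),
    brain_plateau_suv = brain_plateau,
    lesion_grades = stats::setNames(
      vapply(spec$lesions, `[[`, character(1), "grade"), lesion_ids),
    lesion_centers = lapply(stats::setNames(spec$lesions, lesion_ids), `[[`, "center"),
    lesion_radii = stats::setNames(
      vapply(spec$lesions, `[[`, numeric(1), "radius_mm"), lesion_ids))
  list(image = img, truth = truth)
}

# Reflect 1-based indices into [1, n] (half-sample symmetric boundary).
reflect_index_ <- function(j, n) {
  while (any(bad <- j < 1L | j > n)) {
    j[j < 1L] <- 1L - j[j < 1L]
    j[j > n] <- 2L * n + 1L - j[j > n]
  }
  j
}

# n x n one-dimensional Gaussian blur operator with reflective boundaries;
# rows sum to 1 so constants are preserved exactly.
blur_operator_ <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in seq(-r, r)) {
    j <- reflect_index_(i + o, n)
    ij <- cbind(i, j)
    K[ij] <- K[ij] + w[o + r + 1L]
  }
  K
}

# Separable blur of a 3D array along one axis via the operator matrix.
blur_axis_ <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(arr, perm)
  m <- K %*% matrix(p, nrow = d[axis])
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Apply a Gaussian point-spread function
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` (converted from mm to voxels) and
#' reflective boundary handling, which preserves constants exactly and the
#' total of interior-supported signals to well within 0.1%. `fwhm_mm = 0`
#' is the identity.
#'
#' @param img A [dynamic_image()].
#' @param fwhm_mm Full width at half maximum of the PSF, mm (>= 0).
#' @return A blurred `dynamic_image`.
#' @export
apply_psf <- function(img, fwhm_mm) {
  stopifnot(inherits(img, "dynamic_image"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop_("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(img)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / img$voxel_size_mm
  d <- dim(img$data)
  Ks <- lapply(1:3, function(a) blur_operator_(d[a], sigma_vox))
  out <- img$data
  for (f in seq_len(d[4])) {
    v <- out[, , , f]
    for (a in 1:3) v <- blur_axis_(v, Ks[[a]], a)
    out[, , , f] <- v
  }
  img$data <- out
  img
}

#' Add i.i.d. Gaussian noise to a dynamic image
#'
#' @param img A [dynamic_image()].
#' @param sigma Noise standard deviation in SUV (>= 0; 0 is the identity).
#' @param seed Optional integer seed; the caller's RNG state is left
#'   untouched.
#' @return A noisy `dynamic_image`.
#' @export
add_noise <- function(img, sigma, seed = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  if (!is.finite(sigma) || sigma < 0) stop_("'sigma' must be >= 0")
  if (sigma == 0) return(img)
  img$data <- img$data + with_seed_(
    seed, array(stats::rnorm(length(img$data), sd = sigma), dim = dim(img$data)))
  img
}
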