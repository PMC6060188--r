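# Shared builders for small test phantoms and images.

# One-lesion phantom on a small grid; defaults are noiseless and unblurred
# so ground truth is exact.
tiny_phantom_spec <- function(noise_sigma = 0, psf_fwhm_mm = 0, seed = 1L,
                              lesion_plateau = 3, brain_plateau = 1,
                              grid = c(24, 24, 20), voxel = 3) {
  fov <- grid * voxel
  ctr <- fov / 2
  phantom_spec(
    grid_shape = grid, voxel_size_mm = voxel,
    brain = list(center = ctr, semi_axes = 0.45 * fov),
    lesions = list(list(id = 10L, center = ctr + c(10, 0, 0), radius_mm = 8,
                        kinetics = tissue_kinetics(lesion_plateau, 0.2),
                        grade = "HGG")),
    normal_kinetics = tissue_kinetics(brain_plateau, 0.25),
    psf_fwhm_mm = psf_fwhm_mm, noise_sigma = noise_sigma, seed = seed)
}

# Uniform-valued dynamic image on a trivial grid.
uniform_image <- function(value, dim3 = c(8, 8, 6), n_frames = 2, voxel = 2) {
  sched <- make_frame_schedule(list(c(n_frames, 60)))
  dynamic_image(array(value, dim = c(dim3, n_frames)), voxel, sched)
}

# Random non-negative SUV field (single frame) for property tests.
random_frame <- function(dim3 = c(10, 10, 8)) {
  array(stats::rexp(prod(dim3), rate = 0.5), dim = dim3)
}

expect_same_array <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(a, b) else expect_equal(a, b, tolerance = tol)
}
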