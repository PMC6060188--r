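geom0 <- image_geometry(list(dim = c(30, 30, 24), voxel_size_mm = 1.2))

test_that("sphere rasterization follows the center-in convention", {
  # degenerate sphere smaller than a voxel, centered on a voxel center
  ctr <- rep((10 - 0.5) * 1.2, 3)  # center of voxel (10,10,10)
  m <- sphere_mask(sphere_roi(ctr, 1), geom0)
  expect_equal(sum(m), 1L)
  expect_true(m[10, 10, 10])

  # 15-mm sphere volume within 5% of (4/3) pi 7.5^3
  m15 <- sphere_mask(sphere_roi(c(18, 18, 14.4), 15), geom0)
  expect_equal(sum(m15) * 1.2^3, 4 / 3 * pi * 7.5^3,
               tolerance = 0.05)
  expect_equal(mask_volume_ml(m15, 1.2), sum(m15) * 1.2^3 / 1000)

  # translating by one voxel pitch translates the mask identically
  m_shift <- sphere_mask(sphere_roi(c(18 + 1.2, 18, 14.4), 15), geom0)
  expect_identical(m_shift[2:30, , ], m15[1:29, , ])

  expect_warning(sphere_mask(sphere_roi(c(-50, -50, -50), 4), geom0), "empty")
})

test_that("contralateral mirroring reflects x and is an involution", {
  expect_equal(mirror_contralateral(c(10, 2, 3), 0), c(-10, 2, 3))
  expect_equal(mirror_contralateral(c(7, 1, 1), 7), c(7, 1, 1))
  set.seed(1)
  for (i in 1:10) {
    p <- rnorm(3, sd = 40)
    plane <- rnorm(1, sd = 10)
    expect_equal(mirror_contralateral(mirror_contralateral(p, plane), plane), p)
  }
})

test_that("background mean is the plain average over the sphere", {
  frame <- array(2.7, dim = c(8, 8, 6))
  mask <- array(FALSE, dim = dim(frame)); mask[3:5, 3:5, 3] <- TRUE
  expect_equal(background_mean(frame, mask), 2.7)

  two <- array(0, dim = c(4, 4, 4))
  two[1, 1, 1] <- 1; two[2, 1, 1] <- 3
  m2 <- array(FALSE, dim = dim(two)); m2[1:2, 1, 1] <- TRUE
  expect_equal(background_mean(two, m2), 2)

  expect_error(background_mean(frame, array(FALSE, dim = dim(frame))), "empty")
})

test_that("threshold segmentation keeps exactly the voxels at or above k*bg", {
  frame <- array(1, dim = c(6, 6, 6))
  search <- array(TRUE, dim = dim(frame))
  expect_equal(sum(threshold_segment(frame, search, bg = 1, k = 1.3)), 0)
  expect_identical(threshold_segment(array(2, dim = dim(frame)), search, 1, 1.3),
                   search)
  # exclusion removes blood-pool voxels from an otherwise full mask
  excl <- array(FALSE, dim = dim(frame)); excl[1:2, , ] <- TRUE
  seg <- threshold_segment(array(2, dim = dim(frame)), search, 1, 1.3, excl)
  expect_identical(seg, search & !excl)
  # boundary voxels at exactly k*bg are included (minimum threshold)
  frame[3, 3, 3] <- 1.3
  expect_true(threshold_segment(frame, search, 1, 1.3)[3, 3, 3])
  expect_error(threshold_segment(frame, search, bg = 0, k = 1.3), "bg")
})

test_that("segmentation recovers ground-truth lesions on clean phantoms", {
  r <- render_phantom(tiny_phantom_spec(lesion_plateau = 3, brain_plateau = 1))
  lab <- r$truth$label
  search <- array(TRUE, dim = dim(lab))
  frame <- r$image$data[, , , 15]
  bg <- r$truth$frame_tacs["1", 15]
  for (k in c(1.3, 1.6, 1.9)) {
    expect_identical(threshold_segment(frame, search, bg, k), lab == 10L)
  }
})

test_that("single-voxel metrics satisfy the ratio identities", {
  frame <- array(0.5, dim = c(5, 5, 5))
  frame[3, 3, 3] <- 2
  search <- array(FALSE, dim = dim(frame)); search[3, 3, 3] <- TRUE
  m <- lesion_metrics(frame, search, bg = 1, voxel_size_mm = 2,
                      thresholds = 1.3)
  expect_equal(m$suv_max, 2)
  expect_equal(m$tb_max, 2)
  expect_equal(m$suv_mean_1.3, 2)
  expect_equal(m$tb_mean_1.3, 2)
  expect_equal(m$volume_ml_1.3, 8 / 1000)
})

test_that("empty threshold masks report missing means, not zeros", {
  frame <- array(1, dim = c(5, 5, 5))
  search <- array(TRUE, dim = dim(frame))
  m <- lesion_metrics(frame, search, bg = 1, voxel_size_mm = 2,
                      thresholds = c(1.3, 1.9))
  expect_true(is.na(m$suv_mean_1.3) && is.na(m$tb_mean_1.9))
  expect_equal(m$volume_ml_1.3, 0)
})

test_that("metric invariants hold on random fields", {
  set.seed(7)
  for (i in 1:20) {
    frame <- random_frame()
    search <- array(runif(length(frame)) < 0.6, dim = dim(frame))
    if (!any(search)) next
    bg <- 0.8
    m <- lesion_metrics(frame, search, bg, voxel_size_mm = 2)
    # tb identities are exact
    expect_identical(m$tb_max, m$suv_max / bg)
    vols <- c(m$volume_ml_1.3, m$volume_ml_1.6, m$volume_ml_1.9)
    means <- c(m$suv_mean_1.3, m$suv_mean_1.6, m$suv_mean_1.9)
    # nesting: higher k never grows the volume nor lowers the mean
    expect_true(all(diff(vols) <= 0))
    ok <- !is.na(means)
    expect_true(all(diff(means[ok]) >= 0))
    # every included voxel passes its minimum threshold
    for (j in which(ok)) {
      expect_gte(means[j], c(1.3, 1.6, 1.9)[j] * bg)
      expect_gte(m$tb_max, means[j] / bg)  # tb_max >= tb_mean_k
    }
    # global rescaling of frame and bg leaves the TB ratios unchanged
    m2 <- lesion_metrics(frame * 3.7, search, bg * 3.7, voxel_size_mm = 2)
    expect_equal(m2$tb_max, m$tb_max)
    expect_equal(m2$tb_mean_1.6, m$tb_mean_1.6)
    expect_equal(m2$volume_ml_1.3, m$volume_ml_1.3)
  }
})
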