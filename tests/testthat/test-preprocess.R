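test_that("isotropic upsampling preserves extent and mask binarity", {
  v <- array(runif(16 * 16 * 10), c(16, 16, 10))
  img <- image_volume(v * 1000, c(0.99, 0.99, 2.64))
  up <- upsample_isotropic(img, 0.99)
  # z count = round(9 * 2.64 / 0.99) + 1 = 25
  expect_equal(dim(up$voxels), c(16L, 16L, 25L))
  expect_equal(up$voxel_size, rep(0.99, 3))

  # already isotropic at target: voxel-identical
  expect_identical(upsample_isotropic(up, 0.99), up)

  m <- binary_mask(v > 0.5, c(0.99, 0.99, 2.64))
  um <- upsample_isotropic(m, 0.99)
  expect_true(is.logical(um$voxels))
  expect_error(upsample_isotropic(img, -1), "target_spacing")
})

test_that("normalization divides by 1023 and validates the 10-bit range", {
  v <- array(c(0, 512, 1023, rep(100, 24)), c(3, 3, 3))
  nv <- normalize_intensity(image_volume(v, iso))
  expect_equal(nv$voxels[1, 1, 1], 0)
  expect_equal(nv$voxels[3, 1, 1], 1)
  expect_equal(nv$voxels[2, 1, 1], 512 / 1023)
  expect_error(normalize_intensity(image_volume(v + 10, iso, bit_range = c(0, 2000))),
               "10-bit")
})

test_that("rigid transforms invert and round-trip", {
  tf <- rigid_transform(euler_to_rotation(c(0.1, -0.05, 0.2)), c(3, -2, 1))
  inv <- invert_transform(tf)
  p <- c(10, 20, 30)
  q <- as.numeric(tf$rotation %*% p + tf$translation)
  back <- as.numeric(inv$rotation %*% q + inv$translation)
  expect_equal(back, p, tolerance = 1e-6)

  ph <- generate_phantom(straight_tube_spec(n = 32))
  img <- ph$volumes[[1]]$vascular
  idt <- apply_transform(img, rigid_transform(), "linear")
  expect_equal(idt$voxels, img$voxels, tolerance = 1e-8)

  m <- ph$vessel_masks[[1]]
  tm <- apply_transform(m, rigid_transform(diag(3), c(0.99, 0, 0)))
  expect_true(is.logical(tm$voxels))
})

test_that("registration recovers known translations and reduces MSE", {
  ph <- generate_phantom(y_spec(n = 48))
  psf <- gaussian_psf(iso)
  fixed <- apply_psf_and_noise(ph$volumes[[1]]$vascular, psf, noise_sigma = 20,
                               seed = 1)
  shift <- c(3.0, -2.0, 1.0)
  moving <- apply_transform(fixed, rigid_transform(diag(3), shift), "linear")
  tf <- rigid_register(moving, fixed)
  # recovered translation within 0.5 voxel per axis (transform maps moving
  # back onto fixed, so the estimate is -shift)
  expect_true(all(abs(tf$translation + shift) < 0.5 * 0.99))
  expect_lt(attr(tf, "mse_after"), attr(tf, "mse_before"))

  # self-registration: identity within 0.1 voxel
  tf0 <- rigid_register(fixed, fixed)
  expect_true(all(abs(tf0$translation) < 0.1 * 0.99))

  expect_error(rigid_register(image_volume(array(1, c(8, 8, 8)), iso), fixed),
               "degenerate|grid")
})

test_that("clean_mask fills enclosed holes and applies the 50-voxel rule", {
  d <- c(24, 24, 24)
  m <- array(FALSE, d)
  # hollow sphere shell
  ctr <- c(12, 12, 12)
  for (i in 1:24) for (j in 1:24) for (k in 1:24) {
    r <- sqrt(sum((c(i, j, k) - ctr)^2))
    if (r >= 5 && r <= 8) m[i, j, k] <- TRUE
  }
  interior <- sum(!m & as.logical(array(cpp_label3d(!m, d, 6L), d) != 1))
  cleaned <- clean_mask(binary_mask(m, iso), min_component_voxels = 10)
  # interior filled solid
  center_filled <- cleaned$voxels[12, 12, 12]
  expect_true(center_filled)
  expect_gt(sum(cleaned$voxels), sum(m))

  # 49-voxel blob removed, 50-voxel blob kept
  m2 <- array(FALSE, c(30, 30, 12))
  m2[2:8, 2:8, 2] <- TRUE          # 49 voxels
  m2[20:29, 20:24, 2] <- TRUE      # 50 voxels
  cleaned2 <- clean_mask(binary_mask(m2, iso), 50)
  expect_equal(sum(cleaned2$voxels), 50L)
  expect_false(any(cleaned2$voxels[2:8, 2:8, ]))

  # idempotence
  expect_identical(clean_mask(cleaned2, 50)$voxels, cleaned2$voxels)
})

test_that("union bridges transient gaps and is order-independent", {
  ph <- generate_phantom(straight_tube_spec(n = 36))
  m1 <- ph$vessel_masks[[1]]
  gap <- m1
  mid <- 18
  gap$voxels[mid:(mid + 4), , ] <- FALSE  # simulated stall at timepoint 2
  u <- union_masks(list(m1, gap), dilation_rounds = 3)
  lab <- cpp_label3d(u$voxels, dim(u$voxels), 26L)
  expect_equal(attr(lab, "n_components"), 1L)

  u2 <- union_masks(list(gap, m1), dilation_rounds = 3)
  expect_identical(u$voxels, u2$voxels)

  # singleton union = dilated mask; union count >= max single count
  us <- union_masks(list(m1), 3)
  expect_gte(sum(u$voxels), sum(us$voxels))
  expect_gte(sum(us$voxels), sum(m1$voxels))

  bad <- binary_mask(array(FALSE, c(5, 5, 5)), iso)
  expect_error(union_masks(list(m1, bad)), "grid")
})

test_that("segmentation metrics match voxel-counting oracles", {
  d <- c(16, 16, 4)
  X <- array(FALSE, d); X[5:6, 5:6, 2] <- TRUE        # 4-voxel square
  Y <- array(FALSE, d); Y[5:6, 6:7, 2] <- TRUE        # shifted, overlap 2
  mx <- binary_mask(X, iso); my <- binary_mask(Y, iso)
  r <- segmentation_metrics(mx, my)
  expect_equal(r$dsc, 0.5)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)

  # perfect overlap
  rp <- segmentation_metrics(mx, mx)
  expect_equal(rp$dsc, 1.0)
  expect_equal(rp$hd95, 0.0)
  expect_equal(rp$mean_surface_distance, 0.0)

  # pred strictly inside truth: recall 0.5, precision 1
  X2 <- array(FALSE, d); X2[3:10, 3:6, 2] <- TRUE
  Y2 <- array(FALSE, d); Y2[3:10, 3:4, 2] <- TRUE
  r2 <- segmentation_metrics(binary_mask(X2, iso), binary_mask(Y2, iso))
  expect_equal(r2$recall, 0.5)
  expect_equal(r2$precision, 1.0)

  # symmetry: dsc symmetric; precision(X,Y) = recall(Y,X)
  r_ab <- segmentation_metrics(mx, my)
  r_ba <- segmentation_metrics(my, mx)
  expect_equal(r_ab$dsc, r_ba$dsc)
  expect_equal(r_ab$precision, r_ba$recall)
  expect_gte(r_ab$hd95, 0)

  expect_error(segmentation_metrics(mx, binary_mask(array(FALSE, d), iso)),
               "empty")
})

test_that("threshold segmentation separates a two-level phantom exactly", {
  ph <- generate_phantom(straight_tube_spec(intensity = 500))
  img <- ph$volumes[[1]]$vascular
  img$voxels[img$voxels == 0] <- 10
  seg <- threshold_segment(image_volume(img$voxels, iso), "otsu")
  expect_identical(seg$voxels, ph$vessel_masks[[1]]$voxels)

  expect_true(all(!threshold_segment(img, "fixed", threshold = 1000)$voxels))
  expect_true(all(threshold_segment(img, "fixed", threshold = 0)$voxels))
  expect_error(threshold_segment(image_volume(array(5, c(4, 4, 4)), iso), "otsu"),
               "constant")
})
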