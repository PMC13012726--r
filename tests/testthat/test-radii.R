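test_that("distance-transform prior approximates R/3 for cylinders", {
  ph <- generate_phantom(straight_tube_spec(radius = 6, n = 44))
  sk <- prune_hairs(skeletonize(ph$vessel_masks[[1]]))
  g <- build_graph(sk)
  pr <- prior_radius_dt(ph$vessel_masks[[1]], g)
  # analytic mean of (R - r) over the disk is R/3 = 2.0; voxelization adds
  # about half a voxel
  expect_gt(pr[[1]], 1.6)
  expect_lt(pr[[1]], 2.8)
  expect_true(all(pr > 0))

  # two parallel identical tubes: identical priors within a few percent
  n <- 48
  mid <- (n - 1) * 0.99 / 2
  sp2 <- phantom_spec(c(n, n, n), iso, tubes = list(
    list(centerline = rbind(c(2, 14, mid), c((n - 1) * 0.99 - 2, 14, mid)),
         radius = 3, intensity = 600),
    list(centerline = rbind(c(2, 32, mid), c((n - 1) * 0.99 - 2, 32, mid)),
         radius = 3, intensity = 600)))
  ph2 <- generate_phantom(sp2)
  g2 <- build_graph(prune_hairs(skeletonize(ph2$vessel_masks[[1]])))
  pr2 <- prior_radius_dt(ph2$vessel_masks[[1]], g2)
  expect_equal(length(pr2), 2L)
  expect_lt(abs(pr2[1] - pr2[2]) / mean(pr2), 0.02)
})

test_that("Richardson-Lucy deconvolution: identity, sharpening, conservation", {
  ph <- generate_phantom(straight_tube_spec(n = 32))
  img <- ph$volumes[[1]]$vascular

  # delta PSF: unchanged at any iteration count
  out <- deconvolve(img, delta_psf(iso), iterations = 5)
  expect_equal(out$voxels, img$voxels, tolerance = 1e-6)
  # zero iterations: unchanged
  expect_identical(deconvolve(img, gaussian_psf(iso), 0)$voxels, img$voxels)

  psf <- gaussian_psf(iso)
  blurred <- apply_psf_and_noise(img, psf, noise_sigma = 0)
  dec <- deconvolve(blurred, psf, 10)
  expect_true(all(dec$voxels >= 0))
  # total intensity conserved within 1%
  expect_lt(abs(sum(dec$voxels) - sum(blurred$voxels)) / sum(blurred$voxels),
            0.01)
  # edge gradient increases after deconvolution
  mid <- dim(img$voxels)[3] %/% 2
  gb <- max(abs(diff(blurred$voxels[, 16, mid])))
  gd <- max(abs(diff(dec$voxels[, 16, mid])))
  expect_gt(gd, gb)

  badpsf <- psf
  badpsf$kernel <- badpsf$kernel * 2
  expect_error(deconvolve(img, badpsf), "normalized")
})

test_that("orthogonal planes compensate tube obliquity", {
  # axis-aligned tangent: plane equals the sampled xy slice
  ph <- generate_phantom(straight_tube_spec(radius = 3, n = 36))
  img <- ph$volumes[[1]]$vascular
  mid <- (36 - 1) * 0.99 / 2
  pl <- extract_orthogonal_plane(img, c(mid, mid, mid), c(0, 0, 1), 8)
  d <- dim(pl)
  expect_equal(pl[(d[1] + 1) / 2, (d[2] + 1) / 2], 600)

  # tube tilted 30 degrees: orthogonal section still circular, radius ~truth
  n <- 56
  c0 <- (n - 1) * 0.99 / 2
  dirv <- c(cos(pi / 6), 0, sin(pi / 6))
  sp <- phantom_spec(c(n, n, n), iso, tubes = list(
    list(centerline = rbind(c(c0, c0, c0) - 20 * dirv, c(c0, c0, c0) + 20 * dirv),
         radius = 3, intensity = 600)))
  ph2 <- generate_phantom(sp)
  psf <- gaussian_psf(iso)
  blurred <- apply_psf_and_noise(ph2$volumes[[1]]$vascular, psf, noise_sigma = 0)
  pl2 <- extract_orthogonal_plane(blurred, c(c0, c0, c0), dirv, 10)
  det <- detect_boundary_profiles(pl2, prior_radius = 1.5)
  expect_lt(abs(det$radius - 3) / 3, 0.07)

  expect_error(extract_orthogonal_plane(img, c(mid, mid, mid), c(0, 0, 0), 8),
               "degenerate")
})

test_that("boundary detection is accurate, recenters, and rejects outliers", {
  pl <- make_cross_section_planes(1, radius_range = c(5, 5), snr = Inf,
                                  seed = 4)[[1]]
  det <- detect_boundary_profiles(pl$image, pl$prior)
  expect_lt(abs(det$radius - 5), 0.5)
  expect_lte(sum(det$outlier_flags), 2)

  # 2-SD rejection arithmetic: one corrupted spoke flagged, mean stable
  d2 <- det$boundary_distances
  d2[7] <- 30
  fl <- radial_outliers(d2, 2)
  expect_true(fl[7])
  expect_lt(abs(mean(d2[!fl]) - det$radius), 0.1)

  # disk offset ~3 px from the plane centre: recentred and same radius
  m <- 31
  ctr <- c((m + 1) / 2 + 3, (m + 1) / 2)
  xs <- (seq_len(m) - ctr[1]) * 0.99
  ys <- (seq_len(m) - ctr[2]) * 0.99
  img <- matrix(0, m, m)
  img[outer(xs^2, ys^2, "+") < 25] <- 600
  img <- microvasc:::smooth2d(img, 0.42)
  attr(img, "spacing") <- 0.99
  det2 <- detect_boundary_profiles(img, 5 / 3)
  expect_lt(abs(det2$center[1] - ctr[1]), 1.1)
  expect_lt(abs(det2$radius - det$radius), 0.35)

  # flat plane: no interior maximum is an error
  flat <- matrix(0, 31, 31)
  attr(flat, "spacing") <- 0.99
  expect_error(detect_boundary_profiles(flat, -1), "prior_radius")
})

test_that("noiseless scale equivariance within 2%", {
  pl <- make_cross_section_planes(3, radius_range = c(2.5, 5), snr = Inf,
                                  seed = 6)
  for (p in pl) {
    base <- detect_boundary_profiles(p$image, p$prior)$radius
    for (s in c(0.7, 1.4)) {
      rs <- rescale_plane(p$image, s)
      est <- detect_boundary_profiles(rs, p$prior)$radius
      expect_lt(abs(est - s * base) / (s * base), 0.02 + 0.02)
    }
  }
})

test_that("vertex radii recover phantom tubes and dilation time points", {
  n <- 40
  nx <- 60
  mid <- (n - 1) * 0.99 / 2
  # slight tilt avoids a grid-aligned tube whose sub-voxel dilation would
  # not rasterize; a ~54 um tube averages ~50 vertex estimates
  sp <- phantom_spec(c(nx, n, n), iso,
                     tubes = list(list(centerline = rbind(c(2, mid - 1.3, mid - 0.9),
                                                          c(56, mid + 1.3, mid + 0.9)),
                                       radius = 3, intensity = 900)),
                     background_level = 300, timepoints = list(1, 1.10))
  ph <- generate_phantom(sp)
  psf <- gaussian_psf(iso)
  vols <- lapply(1:2, function(t)
    deconvolve(apply_psf_and_noise(ph$volumes[[t]]$vascular, psf,
                                   target_snr = 6.9,
                                   foreground_mask = ph$vessel_masks[[t]],
                                   seed = t), psf, 10))
  g <- smooth_and_tangents(ph$graph)
  priors <- setNames(3 / 3, "1")
  rec <- estimate_vertex_radii(vols, g, priors)
  r1 <- mean(rec$radius[rec$timepoint == 1], na.rm = TRUE)
  r2 <- mean(rec$radius[rec$timepoint == 2], na.rm = TRUE)
  expect_lt(abs(r1 - 3) / 3, 0.15)
  # x1.10 modulation recovered as +10 +/- 3 percent
  expect_lt(abs(100 * (r2 - r1) / r1 - 10), 3)
  # intra-edge SD well below the radius on a constant tube
  sds <- tapply(rec$radius[rec$timepoint == 1], rec$edge[rec$timepoint == 1],
                sd, na.rm = TRUE)
  expect_lt(sds[[1]] / r1, 0.10)
})

test_that("neuron distances subtract the vessel radius and clip at zero", {
  n <- 48
  mid <- (n - 1) * 0.99 / 2
  soma_center <- c(mid, mid + 18, mid)
  sp <- phantom_spec(c(n, n, n), iso,
                     tubes = list(list(centerline = rbind(c(2, mid, mid),
                                                          c(40, mid, mid)),
                                       radius = 2, intensity = 600)),
                     neurons = list(list(center = soma_center, radius = 4,
                                         intensity = 300)))
  ph <- generate_phantom(sp)
  rec <- data.frame(edge = 1, vertex = 1:3,
                    x = mid + c(-2, 0, 2), y = mid, z = mid, timepoint = 1,
                    radius = 2, radius_sd = 0.1, retained = 36)
  out <- neuron_distance(ph$neuron_mask, rec)
  # soma surface is 18 - 4 = 14 um from the axis; minus radius 2 -> ~12
  expect_lt(max(abs(out$neuron_distance - 12)), 1.2)

  # wall touching the soma clips at 0
  rec2 <- rec
  rec2$radius <- 30
  out2 <- neuron_distance(ph$neuron_mask, rec2)
  expect_true(all(out2$neuron_distance == 0))

  # empty neuron mask: infinite sentinel
  empty <- binary_mask(array(FALSE, c(n, n, n)), iso, "neuron")
  expect_true(all(is.infinite(neuron_distance(empty, rec)$neuron_distance)))
})
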