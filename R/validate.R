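# The three self-contained boundary-detection validation experiments:
# rescaling (scale equivariance), noise injection (robustness), and
# simulated fluorescent beads (accuracy and averaging-induced precision).

#' Generate synthetic vessel cross-section planes
#'
#' Builds 2D orthogonal-plane images of tube cross-sections: a bright disk of
#' known radius (with sub-pixel centre jitter) on a dark background, blurred
#' with the lateral PSF and degraded with Gaussian noise to a target SNR.
#'
#' @param n number of planes.
#' @param radius_range true radius range, um (drawn uniformly).
#' @param snr target signal-to-noise ratio (mean foreground over background
#'   SD); `Inf` for noiseless planes.
#' @param intensity foreground intensity, SU.
#' @param background background level, SU.
#' @param spacing pixel size, um.
#' @param psf_fwhm lateral PSF full width at half maximum, um.
#' @param seed integer seed.
#' @return List of planes; each has elements `image` (matrix with `spacing`
#'   attribute), `true_radius` (um), `prior` (um, the R/3 distance-transform
#'   scale a cylinder mask would yield) and `noise_sigma` (SU).
#' @export
make_cross_section_planes <- function(n, radius_range = c(1.5, 6), snr = 6.9,
                                      intensity = 600, background = 0,
                                      spacing = 0.99, psf_fwhm = 0.99,
                                      seed = 1L) {
  set.seed(seed)
  sigma_psf <- psf_fwhm / (2 * sqrt(2 * log(2))) / spacing  # px
  lapply(seq_len(n), function(i) {
    R <- runif(1, radius_range[1], radius_range[2])
    prior <- R / 3
    spoke <- max(4 * prior, 10)
    half <- spoke + 2
    m <- 2 * floor(half / spacing) + 1
    ctr <- (m + 1) / 2 + runif(2, -0.5, 0.5)
    xs <- (seq_len(m) - ctr[1]) * spacing
    ys <- (seq_len(m) - ctr[2]) * spacing
    d2 <- outer(xs^2, ys^2, "+")
    img <- matrix(background, m, m)
    img[d2 < R^2] <- intensity
    img <- smooth2d(img, sigma_psf)
    ns <- 0
    if (is.finite(snr)) {
      fg <- d2 < R^2
      ns <- sqrt(max((mean(img[fg]) / snr)^2 - var(img[!fg]), 0))
      img <- img + matrix(rnorm(m * m, 0, ns), m, m)
    }
    attr(img, "spacing") <- spacing
    list(image = img, true_radius = R, prior = prior, noise_sigma = ns)
  })
}

#' Effective PSF of the acquisition chain
#'
#' The point-spread function as it would be measured from a sub-resolution
#' point source imaged through the chain: optical Gaussian blur at the
#' native (anisotropic) sampling followed by isotropic upsampling. The
#' interpolation's axial smoothing is therefore part of the kernel, exactly
#' as it is part of a bead-measured PSF.
#'
#' @param acq_voxel_size native acquisition sampling, um per axis.
#' @param target_spacing isotropic working spacing, um.
#' @param fwhm optical full width at half maximum per axis, um.
#' @return A [psf_model()] sampled at the working spacing.
#' @export
chain_psf <- function(acq_voxel_size = c(0.99, 0.99, 2.64),
                      target_spacing = 0.99,
                      fwhm = c(0.99, 0.99, 2.64)) {
  opt <- gaussian_psf(voxel_size = acq_voxel_size, fwhm = fwhm)
  kd <- dim(opt$kernel)
  pad <- 2L
  d <- kd + 2L * pad
  vol <- array(0, d)
  ctr <- (d + 1L) %/% 2L
  vol[ctr[1], ctr[2], ctr[3]] <- 1
  blurred <- convolve3(vol, opt$kernel)
  up <- upsample_isotropic(image_volume(blurred, acq_voxel_size,
                                        bit_range = c(0, 1)),
                           target_spacing)
  k <- up$voxels
  k[k < 0] <- 0
  psf_model(k / sum(k), rep(target_spacing, 3))
}

#' Rescale a plane image about its centre (bicubic)
#'
#' Emulates a caliber change: features in the output appear `factor` times
#' larger on the same pixel grid.
#'
#' @param plane plane matrix (with a `spacing` attribute).
#' @param factor scale factor (> 0).
#' @return The rescaled plane on the same grid.
#' @export
rescale_plane <- function(plane, factor) {
  stopifnot(factor > 0)
  m1 <- nrow(plane); m2 <- ncol(plane)
  ctr <- c((m1 + 1) / 2, (m2 + 1) / 2)
  px <- (rep(seq_len(m1), times = m2) - ctr[1]) / factor + ctr[1]
  py <- (rep(seq_len(m2), each = m1) - ctr[2]) / factor + ctr[2]
  out <- matrix(cpp_bicubic2d(plane, cbind(px - 1, py - 1)), m1, m2)
  attr(out, "spacing") <- attr(plane, "spacing")
  out
}

#' Rescaling validation of the boundary detector
#'
#' Each simulation rescales a cross-section plane by a factor drawn uniformly
#' from [0.5, 2] (bicubic) and re-estimates the radius; the coefficient of
#' determination of the post-rescale estimate against factor x baseline
#' estimate quantifies scale equivariance.
#'
#' @param planes list from [make_cross_section_planes()].
#' @param n_sims number of simulations (planes are cycled).
#' @param seed integer seed for the factors.
#' @param factor_range rescaling factor range (default `c(0.5, 2)`).
#' @return A list: `results` data frame (`plane`, `factor`,
#'   `estimate_before`, `estimate_after`) and `r_squared`.
#' @export
run_rescaling_validation <- function(planes, n_sims = 5000, seed = 1L,
                                     factor_range = c(0.5, 2)) {
  base <- vapply(planes, function(p)
    tryCatch(detect_boundary_profiles(p$image, p$prior)$radius,
             error = function(e) NA_real_), 0)
  set.seed(seed)
  np <- length(planes)
  idx <- ((seq_len(n_sims) - 1L) %% np) + 1L
  u <- runif(n_sims, factor_range[1], factor_range[2])
  est_after <- vapply(seq_len(n_sims), function(k) {
    i <- idx[k]
    if (is.na(base[i])) return(NA_real_)
    rp <- rescale_plane(planes[[i]]$image, u[k])
    tryCatch(detect_boundary_profiles(rp, planes[[i]]$prior)$radius,
             error = function(e) NA_real_)
  }, 0)
  res <- data.frame(plane = idx, factor = u, estimate_before = base[idx],
                    estimate_after = est_after)
  ok <- stats::complete.cases(res)
  fit <- lm(estimate_after ~ I(factor * estimate_before), data = res[ok, ])
  list(results = res, r_squared = summary(fit)$r.squared,
       n_used = sum(ok))
}

#' Noise-injection validation of the boundary detector
#'
#' Gaussian noise with a sigma drawn uniformly from `sigma_range` is added to
#' each plane (after PSF handling and plane extraction, before the detector's
#' Gaussian smoothing); the percent change in the estimated radius relative
#' to the plane's baseline estimate is reported per simulation.
#'
#' @param planes list from [make_cross_section_planes()].
#' @param sigma_range noise sigma range, SU (default `c(0, 500)`).
#' @param n_sims number of simulations.
#' @param seed integer seed.
#' @return Data frame: `plane`, `sigma`, `estimate`, `baseline`,
#'   `pct_change`.
#' @export
run_noise_validation <- function(planes, sigma_range = c(0, 500),
                                 n_sims = 1000, seed = 1L) {
  base <- vapply(planes, function(p)
    tryCatch(detect_boundary_profiles(p$image, p$prior)$radius,
             error = function(e) NA_real_), 0)
  set.seed(seed)
  np <- length(planes)
  idx <- ((seq_len(n_sims) - 1L) %% np) + 1L
  sig <- runif(n_sims, sigma_range[1], sigma_range[2])
  est <- vapply(seq_len(n_sims), function(k) {
    i <- idx[k]
    if (is.na(base[i])) return(NA_real_)
    img <- planes[[i]]$image
    noisy <- img + matrix(rnorm(length(img), 0, sig[k]), nrow(img))
    attr(noisy, "spacing") <- attr(img, "spacing")
    tryCatch(detect_boundary_profiles(noisy, planes[[i]]$prior)$radius,
             error = function(e) NA_real_)
  }, 0)
  data.frame(plane = idx, sigma = sig, estimate = est, baseline = base[idx],
             pct_change = 100 * (est - base[idx]) / base[idx])
}

#' Simulated fluorescent-bead validation
#'
#' Spheres with true diameters drawn from a normal distribution are imaged
#' synthetically through the full acquisition chain: rasterization at the
#' native anisotropic sampling (0.99 um lateral, 2.64 um axial), PSF blur,
#' Gaussian acquisition noise at the native bead SNR, isotropic upsampling to
#' 0.99 um, Richardson-Lucy deconvolution, and a Gaussian noise top-up
#' bringing the SNR down to the vessel-channel level. Each bead is then
#' threshold-segmented; orthogonal planes with random unit normals are
#' extracted through its centroid; the bead diameter is twice the mean
#' retained boundary distance averaged over the level's planes. The mean and
#' SD of the per-bead diameter estimates are reported per averaging level.
#'
#' @param n_beads number of beads (default 289).
#' @param diameter_mean,diameter_sd true-diameter distribution, um (defaults
#'   7.32 and 0.27).
#' @param levels list of `c(n_planes, n_spokes)` averaging levels.
#' @param acquisition_snr SNR of the simulated raw bead acquisition before
#'   deconvolution (default 6.79, the native SNR of bead images under the
#'   vessel imaging configuration); the deconvolution therefore operates on
#'   realistically noisy data.
#' @param target_snr SNR after the post-deconvolution noise top-up (default
#'   5.05, matching the vessel-channel level the beads are degraded to).
#' @param intensity bead foreground intensity, SU.
#' @param spacing isotropic working voxel size, um.
#' @param z_step native axial sampling before isotropic upsampling, um
#'   (default 2.64).
#' @param vol_dim cubic working-volume side, voxels.
#' @param psf [psf_model()]; default the anisotropic Gaussian microscope
#'   model.
#' @param rl_iterations Richardson-Lucy iterations (default 10).
#' @param seed integer seed.
#' @return A list: `table` (data frame with `n_planes`, `n_spokes`, `mean`,
#'   `sd` per level), `estimates` (beads x levels matrix, um),
#'   `true_diameters`, `excluded` (indices of beads touching the volume
#'   edge, if any).
#' @export
run_bead_validation <- function(n_beads = 289, diameter_mean = 7.32,
                                diameter_sd = 0.27,
                                levels = list(c(1, 3), c(2, 4), c(4, 12), c(10, 36)),
                                acquisition_snr = 6.79,
                                target_snr = 5.05, intensity = 430,
                                spacing = 0.99, z_step = 2.64, vol_dim = 33L,
                                psf = NULL, rl_iterations = 10, seed = 1L) {
  set.seed(seed)
  acq_sp <- c(spacing, spacing, z_step)
  psf_acq <- gaussian_psf(voxel_size = acq_sp)
  if (is.null(psf)) psf <- gaussian_psf(voxel_size = rep(spacing, 3))
  dims <- rep(as.integer(vol_dim), 3)
  extent <- (dims - 1) * spacing
  acq_dims <- as.integer(round(extent / acq_sp) + 1L)
  center0 <- (dims - 1) * spacing / 2
  truth <- rnorm(n_beads, diameter_mean, diameter_sd)
  est <- matrix(NA_real_, n_beads, length(levels))
  excluded <- integer(0)
  for (b in seq_len(n_beads)) {
    Rtrue <- truth[b] / 2
    ctr <- center0 + runif(3, -0.5, 0.5) * spacing
    m <- sphere_mask(ctr, Rtrue, dims, rep(spacing, 3))
    if (any(m[1, , ]) || any(m[dims[1], , ]) || any(m[, 1, ]) ||
        any(m[, dims[2], ]) || any(m[, , 1]) || any(m[, , dims[3]])) {
      excluded <- c(excluded, b)
      next
    }
    # native-resolution acquisition: raster, blur, white acquisition noise
    m_acq <- sphere_mask(ctr, Rtrue, acq_dims, acq_sp)
    vox <- array(0, acq_dims)
    vox[m_acq] <- intensity
    bl_vox <- convolve3(vox, psf_acq$kernel)
    if (is.finite(acquisition_snr)) {
      ns0 <- sqrt(max((mean(bl_vox[m_acq]) / acquisition_snr)^2 -
                        var(bl_vox[!m_acq]), 0))
      bl_vox <- bl_vox + array(rnorm(prod(acq_dims), 0, ns0), acq_dims)
      bl_vox[bl_vox < 0] <- 0
    }
    acq <- image_volume(bl_vox, acq_sp, "vascular")
    blurred <- upsample_isotropic(acq, spacing)
    stopifnot(identical(dim(blurred$voxels), dims))
    dec <- deconvolve(blurred, psf, iterations = rl_iterations)
    # top-up noise after deconvolution down to the vessel-channel SNR
    mu_fg <- mean(dec$voxels[m])
    ns <- sqrt(max((mu_fg / target_snr)^2 - var(dec$voxels[!m]), 0))
    noisy_vox <- dec$voxels + array(rnorm(prod(dims), 0, ns), dims)
    noisy <- image_volume(noisy_vox, rep(spacing, 3), "vascular",
                          bit_range = range(noisy_vox))
    # half-maximum threshold (robust max: 99th percentile), the standard
    # segmentation for isolated bright beads; Otsu is unreliable when the
    # foreground occupies a tiny fraction of the volume
    thr <- 0.5 * quantile(noisy_vox, 0.999, names = FALSE)
    seg <- threshold_segment(noisy, "fixed", threshold = thr)
    lab <- cpp_label3d(seg$voxels, dims, 26L)
    ncomp <- attr(lab, "n_components")
    if (ncomp < 1) { excluded <- c(excluded, b); next }
    sizes <- tabulate(lab[lab != 0], nbins = ncomp)
    comp <- array(lab, dims) == which.max(sizes)
    idx <- which(comp, arr.ind = TRUE)
    centroid <- colMeans(sweep(idx - 1, 2, rep(spacing, 3), "*"))
    dt <- cpp_edt3d(!comp, dims, rep(spacing, 3))
    prior <- mean(dt[comp])
    for (lv in seq_along(levels)) {
      npl <- levels[[lv]][1]
      nsp <- levels[[lv]][2]
      radii <- vapply(seq_len(npl), function(p) {
        nv <- rnorm(3)
        nv <- nv / sqrt(sum(nv^2))
        tryCatch({
          pl <- extract_orthogonal_plane(noisy, centroid, nv,
                                         half_width = 12, spacing = spacing)
          detect_boundary_profiles(pl, prior, n_spokes = nsp)$radius
        }, error = function(e) NA_real_)
      }, 0)
      est[b, lv] <- 2 * mean(radii, na.rm = TRUE)
    }
  }
  tab <- data.frame(
    n_planes = vapply(levels, `[`, 0, 1),
    n_spokes = vapply(levels, `[`, 0, 2),
    mean = apply(est, 2, mean, na.rm = TRUE),
    sd = apply(est, 2, sd, na.rm = TRUE))
  list(table = tab, estimates = est, true_diameters = truth,
       excluded = excluded)
}
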