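# Core data containers: gridded volumes, binary masks and PSF models.
# Conventions used throughout the package:
#  * arrays are indexed (x, y, z); voxel (i, j, k) (1-based in R) is centred
#    at physical position (i-1, j-1, k-1) * voxel_size, in micrometers;
#  * z is depth below the first slice (cortical surface at z = 0);
#  * raw intensities are 10-bit "signal units" (SU) in [0, 1023].

#' Create an image volume
#'
#' A 3D scalar field with a physical voxel size and a channel role. Raw
#' two-photon data are 10-bit (0--1023 SU); normalized volumes span [0, 1].
#'
#' @param voxels 3D numeric array of intensities.
#' @param voxel_size numeric length-3, micrometers per voxel along (x, y, z).
#' @param channel `"vascular"` or `"neuron"`.
#' @param bit_range numeric length-2 intensity range, default `c(0, 1023)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, voxel_size, channel = c("vascular", "neuron"),
                         bit_range = c(0, 1023)) {
  channel <- match.arg(channel)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (um)")
  structure(list(voxels = voxels, voxel_size = voxel_size, channel = channel,
                 bit_range = as.numeric(bit_range)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s channel, %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g] (nominal [%g, %g])\n",
              min(x$voxels), max(x$voxels), x$bit_range[1], x$bit_range[2]))
  invisible(x)
}

#' Create a binary mask
#'
#' @param voxels 3D logical (or 0/1) array.
#' @param voxel_size micrometers per voxel along (x, y, z).
#' @param label `"vessel"` or `"neuron"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, voxel_size, label = c("vessel", "neuron")) {
  label <- match.arg(label)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("mask values must be in {0, 1}")
    voxels <- array(voxels != 0, dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask must be logical or 0/1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (um)")
  structure(list(voxels = voxels, voxel_size = voxel_size, label = label),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %s, %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              x$label, d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

#' Create a point-spread-function model
#'
#' @param kernel 3D nonnegative array summing to 1.
#' @param voxel_size micrometers per kernel voxel along (x, y, z).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(kernel, voxel_size) {
  kernel <- as.array(kernel)
  if (length(dim(kernel)) != 3L) stop("PSF kernel must be a 3D array")
  if (!all(is.finite(kernel)) || any(kernel < 0))
    stop("PSF kernel must be finite and nonnegative")
  if (abs(sum(kernel) - 1) > 1e-6) stop("PSF kernel must sum to 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(kernel = kernel, voxel_size = voxel_size), class = "psf_model")
}

#' Default synthetic PSF: anisotropic Gaussian
#'
#' Models the microscope blur as a separable Gaussian with full width at half
#' maximum matching the nominal lateral (0.99 um) and axial (2.64 um)
#' resolutions of the imaging configuration. Used whenever a measured PSF
#' volume is not supplied.
#'
#' @param voxel_size kernel sampling, micrometers per voxel.
#' @param fwhm full width at half maximum per axis, micrometers.
#' @param truncate kernel support in standard deviations.
#' @return A [psf_model()].
#' @export
gaussian_psf <- function(voxel_size = c(0.99, 0.99, 0.99),
                         fwhm = c(0.99, 0.99, 2.64), truncate = 4) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  ax <- lapply(1:3, function(a) {
    s <- sigma[a] / voxel_size[a]  # in voxels
    r <- max(1L, ceiling(truncate * s))
    k <- dnorm(seq(-r, r), sd = max(s, 1e-8))
    k / sum(k)
  })
  kern <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  kern <- kern / sum(kern)
  psf_model(kern, voxel_size)
}

#' A delta-function PSF (identity blur)
#' @param voxel_size kernel voxel size in micrometers.
#' @return A [psf_model()] whose kernel is a single unit voxel.
#' @export
delta_psf <- function(voxel_size = c(0.99, 0.99, 0.99)) {
  psf_model(array(1, c(1, 1, 1)), voxel_size)
}

#' Normalize 10-bit intensities to [0, 1]
#'
#' Divides raw signal units by 1023 so intensities span 0 to 1; the mapping is
#' invertible (multiply by 1023).
#'
#' @param volume an [image_volume()] with raw values in [0, 1023].
#' @return The normalized [image_volume()] with `bit_range = c(0, 1)`.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  if (min(v) < 0 || max(v) > 1023)
    stop("intensities outside the 10-bit range [0, 1023]")
  image_volume(v / 1023, volume$voxel_size, volume$channel, bit_range = c(0, 1))
}

#' Signal-to-noise ratio of a volume
#'
#' SNR is defined as the mean intensity over foreground voxels divided by the
#' standard deviation of the intensity over background voxels, on the raw
#' signal-unit scale.
#'
#' @param image an [image_volume()] (or bare 3D array).
#' @param foreground_mask logical array (or [binary_mask()]) marking signal
#'   voxels; everything else is background.
#' @return The SNR (dimensionless ratio).
#' @export
measure_snr <- function(image, foreground_mask) {
  v <- if (inherits(image, "image_volume")) image$voxels else as.array(image)
  m <- if (inherits(foreground_mask, "binary_mask")) foreground_mask$voxels else
    as.array(foreground_mask) != 0
  if (!identical(dim(v), dim(m))) stop("image and mask grids differ")
  nf <- sum(m)
  if (nf < 1 || nf >= length(m)) stop("mask needs >= 1 foreground and >= 1 background voxel")
  s <- sd(v[!m])
  if (s == 0) stop("zero background variance: SNR undefined")
  mean(v[m]) / s
}

# grid equality helper used across modules
same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-9))
}
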