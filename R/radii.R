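# Vertex-wise vessel radius estimation: distance-transform prior,
# Richardson-Lucy deconvolution, orthogonal-plane extraction and radial
# gradient-minimum boundary detection with outlier rejection, plus
# radius-subtracted distances to labeled neurons.

#' Vessel-wise prior radius from the mask distance transform
#'
#' The Euclidean distance from every vessel voxel to the nearest background
#' voxel is averaged over the voxels assigned (by nearest centerline vertex)
#' to each vessel segment. For an ideal cylinder of radius R this average is
#' R/3: the prior is a kernel-scale parameter for the boundary detector, not
#' an unbiased radius estimate.
#'
#' @param mask the union vessel [binary_mask()].
#' @param graph the `vascular_graph` extracted from it.
#' @return Named numeric vector: per-edge prior radius, micrometers.
#' @export
prior_radius_dt <- function(mask, graph) {
  stopifnot(inherits(mask, "binary_mask"), inherits(graph, "vascular_graph"))
  d <- dim(mask$voxels)
  sp <- mask$voxel_size
  dt <- cpp_edt3d(!mask$voxels, d, sp)  # distance to background
  idx <- which(mask$voxels, arr.ind = TRUE)
  qpos <- sweep(idx - 1, 2, sp, "*")
  sites <- do.call(rbind, lapply(graph$edges, function(e) e$path))
  lab <- unlist(lapply(graph$edges, function(e) rep(e$id, nrow(e$path))))
  assign <- cpp_nearest_label(sites, as.integer(lab), qpos)
  vals <- dt[mask$voxels]
  out <- tapply(vals, factor(assign, levels = vapply(graph$edges, `[[`, 0, "id")),
                mean)
  out <- as.numeric(out)
  names(out) <- vapply(graph$edges, `[[`, 0, "id")
  if (anyNA(out)) stop("edge with no assigned mask voxels")
  out
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy updates with the supplied PSF;
#' convolution is FFT-based with replicate edge padding, so total intensity
#' is conserved up to edge effects.
#'
#' @param volume a nonnegative [image_volume()].
#' @param psf a normalized [psf_model()].
#' @param iterations number of update rounds (default 10; 0 returns the
#'   input unchanged).
#' @return The deconvolved [image_volume()].
#' @export
deconvolve <- function(volume, psf, iterations = 10) {
  stopifnot(inherits(volume, "image_volume"), inherits(psf, "psf_model"))
  if (abs(sum(psf$kernel) - 1) > 1e-6) stop("PSF must be normalized")
  lo <- min(volume$voxels)
  if (lo < -1e-6 * max(abs(volume$voxels)))
    stop("deconvolution requires a nonnegative image")
  if (iterations == 0) return(volume)
  volume$voxels[volume$voxels < 0] <- 0  # clamp FFT round-off
  k <- psf$kernel
  kf <- k[dim(k)[1]:1, dim(k)[2]:1, dim(k)[3]:1, drop = FALSE]  # flipped
  eps <- 1e-8 * max(volume$voxels + 1e-12)
  est <- volume$voxels + eps
  obs <- volume$voxels
  for (it in seq_len(iterations)) {
    denom <- convolve3(est, k)
    ratio <- obs / pmax(denom, eps)
    est <- est * convolve3(array(ratio, dim(obs)), kf)
    est[est < 0] <- 0
  }
  image_volume(array(est, dim(obs)), volume$voxel_size, volume$channel,
               volume$bit_range)
}

# right-handed orthonormal completion of a unit tangent; deterministic
plane_basis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  ax <- diag(3)[, which.min(abs(t))]
  u <- c(t[2] * ax[3] - t[3] * ax[2],
         t[3] * ax[1] - t[1] * ax[3],
         t[1] * ax[2] - t[2] * ax[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v)
}

#' Extract the image plane orthogonal to a vessel tangent
#'
#' Samples the volume on a square grid centred at `position`, spanned by two
#' orthonormal vectors completing `tangent` to a right-handed basis, at
#' `spacing` micrometers with trilinear interpolation. Samples falling
#' outside the volume are filled with `fill` (default: the volume median)
#' and counted in the `frac_filled` attribute.
#'
#' @param volume an [image_volume()].
#' @param position plane centre, um.
#' @param tangent unit tangent vector of the vessel at that vertex.
#' @param half_width half-extent of the plane, um.
#' @param spacing in-plane sample spacing, um (default 0.99).
#' @param fill value for out-of-volume samples.
#' @return A numeric matrix (the plane), with attributes `spacing`,
#'   `half_width` and `frac_filled`.
#' @export
extract_orthogonal_plane <- function(volume, position, tangent, half_width,
                                     spacing = 0.99, fill = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  nt <- sqrt(sum(tangent^2))
  if (nt < 1e-9) stop("degenerate tangent")
  b <- plane_basis(tangent)
  offs <- seq(-half_width, half_width, by = spacing)
  m <- length(offs)
  if (is.null(fill)) fill <- median(volume$voxels)
  U <- outer(offs, b$u)  # m x 3
  P <- matrix(position, m * m, 3, byrow = TRUE) +
    U[rep(seq_len(m), times = m), ] +
    outer(offs, b$v)[rep(seq_len(m), each = m), ]
  Q <- sweep(P, 2, volume$voxel_size, "/")
  s <- cpp_trilinear(as.numeric(volume$voxels), dim(volume$voxels), Q, fill)
  plane <- matrix(s$values, m, m)
  attr(plane, "spacing") <- spacing
  attr(plane, "half_width") <- half_width
  attr(plane, "frac_filled") <- mean(s$outside)
  plane
}

#' Flag boundary-distance outliers with a 2-SD gate
#'
#' Spoke boundary distances farther than `sd_gate` standard deviations from
#' the across-spoke mean are flagged; the retained mean defines the vertex
#' radius.
#'
#' @param distances numeric vector of per-spoke boundary distances, um.
#' @param sd_gate exclusion threshold in standard deviations (default 2).
#' @return Logical vector: TRUE where the spoke is an outlier.
#' @export
radial_outliers <- function(distances, sd_gate = 2) {
  mu <- mean(distances)
  s <- sd(distances)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(distances)))
  abs(distances - mu) > sd_gate * s
}

#' Radial gradient-minimum boundary detection in an orthogonal plane
#'
#' The plane is low-pass filtered with a 2D Gaussian of sigma 0.8 x the
#' vessel-wise prior radius; the lumen centre is the local intensity maximum
#' nearest the plane centre within a 10-pixel search radius. Radial intensity
#' profiles are sampled every 10 degrees (36 spokes) at 5x sub-pixel
#' (bicubic) resolution, smoothed with a 1D Gaussian of the same sigma, and
#' each spoke's boundary is placed at the minimum of the profile gradient.
#' Boundaries more than 2 SD from the across-spoke mean are excluded; the
#' vertex radius is the mean of the retained boundary distances.
#'
#' @param plane plane image from [extract_orthogonal_plane()] (pixel spacing
#'   taken from its `spacing` attribute, default 0.99 um).
#' @param prior_radius vessel-wise prior radius, um (> 0).
#' @param n_spokes number of radial spokes (default 36).
#' @param center_search_px lumen-centre search radius in pixels (default 10).
#' @param sd_gate outlier gate in standard deviations (default 2).
#' @param upsample sub-pixel radial sampling factor (default 5).
#' @param spoke_length spoke length in um; default 4 x prior radius, at least
#'   10 um, capped at the plane half-width.
#' @param max_outliers error if more spokes than this are flagged (default
#'   half the spokes: the vertex is unreliable).
#' @return An object of class `radial_profile_set`: `center` (pixel coords),
#'   `angles`, `profiles` (spokes x samples), `boundary_distances` (um),
#'   `outlier_flags`, `radius` (um), `radius_sd` (um), `retained`.
#' @export
detect_boundary_profiles <- function(plane, prior_radius, n_spokes = 36,
                                     center_search_px = 10, sd_gate = 2,
                                     upsample = 5, spoke_length = NULL,
                                     max_outliers = floor(n_spokes / 2)) {
  if (prior_radius <= 0) stop("prior_radius must be > 0")
  spacing <- attr(plane, "spacing")
  if (is.null(spacing)) spacing <- 0.99
  m1 <- nrow(plane); m2 <- ncol(plane)
  ctr <- c((m1 + 1) / 2, (m2 + 1) / 2)

  sigma_px <- 0.8 * prior_radius / spacing
  sm <- smooth2d(plane, sigma_px)

  # lumen centre: local maximum of the smoothed plane nearest the centre
  ii <- rep(seq_len(m1), times = m2)
  jj <- rep(seq_len(m2), each = m1)
  d2 <- (ii - ctr[1])^2 + (jj - ctr[2])^2
  insearch <- d2 <= center_search_px^2
  if (!any(insearch)) stop("no interior search region")
  is_locmax <- matrix(TRUE, m1, m2)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- sm[pmin(pmax(seq_len(m1) + di, 1), m1),
                  pmin(pmax(seq_len(m2) + dj, 1), m2)]
    is_locmax <- is_locmax & (sm >= shifted)
  }
  cand <- which(insearch & as.vector(is_locmax))
  if (!length(cand)) stop("no interior intensity maximum found")
  best <- cand[order(d2[cand], -sm[cand])][1]
  center <- c(ii[best], jj[best])

  half_width_um <- min(ctr - 1) * spacing
  if (is.null(spoke_length))
    spoke_length <- min(max(4 * prior_radius, 10), half_width_um)
  step <- spacing / upsample
  rr <- seq(0, spoke_length, by = step)
  angles <- (seq_len(n_spokes) - 1) * (360 / n_spokes) * pi / 180

  px <- as.vector(outer(rr / spacing, cos(angles))) + center[1]
  py <- as.vector(outer(rr / spacing, sin(angles))) + center[2]
  vals <- cpp_bicubic2d(plane, cbind(px - 1, py - 1))
  profiles <- matrix(vals, length(rr), n_spokes)

  sigma_samp <- 0.8 * prior_radius / step
  dists <- numeric(n_spokes)
  for (s in seq_len(n_spokes)) {
    prof <- smooth1d(profiles[, s], sigma_samp)
    g <- c(prof[2] - prof[1], (prof[-(1:2)] - prof[seq_len(length(prof) - 2)]) / 2,
           prof[length(prof)] - prof[length(prof) - 1])
    # steepest descent marks the wall; ties broken toward the centre
    k <- which(g == min(g))[1]
    dists[s] <- rr[k]
  }
  out <- radial_outliers(dists, sd_gate)
  if (sum(out) > max_outliers) stop("unreliable vertex: too many outlier spokes")
  kept <- dists[!out]
  structure(list(center = center, angles = angles, profiles = t(profiles),
                 boundary_distances = dists, outlier_flags = out,
                 radius = mean(kept), radius_sd = sd(kept),
                 retained = sum(!out)),
            class = "radial_profile_set")
}

#' @export
print.radial_profile_set <- function(x, ...) {
  cat(sprintf("<radial_profile_set> radius %.3f um (SD %.3f), %d/%d spokes retained\n",
              x$radius, x$radius_sd, x$retained, length(x$boundary_distances)))
  invisible(x)
}

#' Estimate radii at every centerline vertex and time point
#'
#' Runs [detect_boundary_profiles()] at every vertex of every edge, for every
#' (deconvolved, registered) volume. Per-vertex failures are recorded as
#' missing, not fatal; an edge on which every vertex fails is flagged.
#'
#' @param volumes list of deconvolved [image_volume()]s, one per time point.
#' @param graph a `vascular_graph` with tangents (see [smooth_and_tangents()]).
#' @param priors named per-edge prior radii from [prior_radius_dt()], um.
#' @param ... further arguments passed to [detect_boundary_profiles()].
#' @param max_fill_frac vertices whose plane has more than this fraction of
#'   out-of-volume samples are marked missing (default 0.25).
#' @return A data frame (one row per edge x vertex x time point):
#'   `edge`, `vertex`, `x`, `y`, `z`, `timepoint`, `radius`, `radius_sd`,
#'   `retained`.
#' @export
estimate_vertex_radii <- function(volumes, graph, priors, ...,
                                  max_fill_frac = 0.25) {
  stopifnot(inherits(graph, "vascular_graph"))
  if (is.null(graph$edges[[1]]$tangents))
    stop("graph lacks tangents: run smooth_and_tangents() first")
  rows <- list()
  for (e in graph$edges) {
    pr <- priors[[as.character(e$id)]]
    half_width <- min(max(4 * pr, 10), 40) + 2
    S <- e$smoothed
    Tg <- e$tangents
    for (t in seq_along(volumes)) {
      vol <- volumes[[t]]
      for (vi in seq_len(nrow(S))) {
        rec <- tryCatch({
          pl <- extract_orthogonal_plane(vol, S[vi, ], Tg[vi, ], half_width,
                                         spacing = 0.99)
          if (attr(pl, "frac_filled") > max_fill_frac)
            stop("plane mostly outside volume")
          detect_boundary_profiles(pl, pr, ...)
        }, error = function(err) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          edge = e$id, vertex = vi, x = S[vi, 1], y = S[vi, 2], z = S[vi, 3],
          timepoint = t,
          radius = if (is.null(rec)) NA_real_ else rec$radius,
          radius_sd = if (is.null(rec)) NA_real_ else rec$radius_sd,
          retained = if (is.null(rec)) NA_integer_ else rec$retained)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- tapply(out$radius, out$edge, function(r) all(is.na(r)))
  attr(out, "unusable_edges") <- as.integer(names(bad)[bad])
  out
}

#' Radius-subtracted distance from vessel vertices to the nearest neuron
#'
#' The Euclidean distance transform from the neuron soma mask is sampled at
#' each vertex position and the vertex's vessel radius subtracted, clipping
#' at zero (wall touching the soma). With an empty neuron mask all distances
#' are `Inf`.
#'
#' @param neuron_mask [binary_mask()] of labeled neuron somas.
#' @param records vertex table from [estimate_vertex_radii()].
#' @param radius_timepoint which time point's radius to subtract (default 1,
#'   the baseline).
#' @return `records` with a `neuron_distance` column (um).
#' @export
neuron_distance <- function(neuron_mask, records, radius_timepoint = 1) {
  stopifnot(inherits(neuron_mask, "binary_mask"))
  base <- records[records$timepoint == radius_timepoint,
                  c("edge", "vertex", "radius")]
  names(base)[3] <- "base_radius"
  out <- merge(records, base, by = c("edge", "vertex"), sort = FALSE)
  if (!any(neuron_mask$voxels)) {
    out$neuron_distance <- Inf
    return(out)
  }
  d <- dim(neuron_mask$voxels)
  sp <- neuron_mask$voxel_size
  dt <- cpp_edt3d(neuron_mask$voxels, d, sp)
  Q <- sweep(as.matrix(out[, c("x", "y", "z")]), 2, sp, "/")
  s <- cpp_trilinear(as.numeric(dt), d, Q, NA_real_)
  out$neuron_distance <- pmax(s$values - out$base_radius, 0)
  out$base_radius <- NULL
  out
}
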