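# Synthetic phantom generation: tubes on curved centerlines, beads of known
# diameter, spherical neuron somas, PSF blur and calibrated Gaussian noise.
# Every downstream stage of the pipeline is testable against these phantoms
# without any microscope data.

#' Describe a synthetic two-channel phantom
#'
#' A declarative description of tubes (vessels), beads and neuron somas placed
#' in a volume, together with acquisition-like parameters. Geometry is given
#' in micrometers; intensities in 10-bit signal units (SU).
#'
#' @param volume_shape integer length-3, voxel counts along (x, y, z).
#' @param voxel_size micrometers per voxel, default 0.99 um isotropic.
#' @param tubes list of tubes; each a list with `centerline` (n x 3 matrix of
#'   control points, um), `radius` (scalar um, or function of arc length um),
#'   and `intensity` (SU).
#' @param beads list of beads; each a list with `center` (um), `diameter`
#'   (um) and `intensity` (SU). Beads render into the vascular channel.
#' @param neurons list of somas; each a list with `center` (um), `radius`
#'   (um) and `intensity` (SU). Somas render into the neuron channel.
#' @param background_level background intensity, SU.
#' @param timepoints list of per-tube radius multipliers, one element per
#'   time point; each element is a scalar (applied to all tubes) or a vector
#'   with one multiplier per tube.
#' @param seed integer seed controlling any randomized stage downstream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape, voxel_size = c(0.99, 0.99, 0.99),
                         tubes = list(), beads = list(), neurons = list(),
                         background_level = 0, timepoints = list(1),
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3L, all(volume_shape > 0))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  extent <- (volume_shape - 1L) * voxel_size
  for (tb in tubes) {
    cl <- as.matrix(tb$centerline)
    if (ncol(cl) != 3L) stop("tube centerline must be an n x 3 matrix (um)")
    if (any(cl < 0) || any(sweep(cl, 2, extent) > 1e-9))
      stop("tube centerline control points must lie inside the volume")
    if (is.numeric(tb$radius) && any(tb$radius <= 0)) stop("tube radius must be > 0")
    if (tb$intensity < 0 || tb$intensity > 1023) stop("intensities must be in [0, 1023]")
  }
  for (b in beads) {
    if (b$diameter <= 0) stop("bead diameter must be > 0")
    if (b$intensity < 0 || b$intensity > 1023) stop("intensities must be in [0, 1023]")
  }
  for (nn in neurons) {
    if (nn$radius <= 0) stop("neuron radius must be > 0")
    if (nn$intensity < 0 || nn$intensity > 1023) stop("intensities must be in [0, 1023]")
  }
  for (tp in timepoints) if (any(tp <= 0)) stop("radius multipliers must be > 0")
  if (background_level < 0 || background_level > 1023)
    stop("background_level must be in [0, 1023]")
  structure(list(volume_shape = volume_shape, voxel_size = voxel_size,
                 tubes = tubes, beads = beads, neurons = neurons,
                 background_level = background_level,
                 timepoints = timepoints, seed = as.integer(seed)),
            class = "phantom_spec")
}

# densely resample a centerline (control polygon or spline) at a fixed arc
# length step; returns matrix of positions plus cumulative arc length
resample_centerline <- function(ctrl, step = 1.0) {
  ctrl <- as.matrix(ctrl)
  n <- nrow(ctrl)
  if (n < 2) stop("centerline needs >= 2 control points")
  # chordal parameterisation
  t0 <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  if (t0[n] == 0) stop("degenerate centerline")
  tt <- seq(0, t0[n], length.out = max(2L, ceiling(t0[n] / (step / 4)) + 1L))
  dense <- if (n == 2) {
    cbind(approx(t0, ctrl[, 1], tt)$y, approx(t0, ctrl[, 2], tt)$y,
          approx(t0, ctrl[, 3], tt)$y)
  } else {
    cbind(spline(t0, ctrl[, 1], xout = tt)$y, spline(t0, ctrl[, 2], xout = tt)$y,
          spline(t0, ctrl[, 3], xout = tt)$y)
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- arc[length(arc)]
  s_out <- seq(0, total, by = step)
  if (s_out[length(s_out)] < total - 1e-9) s_out <- c(s_out, total)
  out <- cbind(approx(arc, dense[, 1], s_out)$y, approx(arc, dense[, 2], s_out)$y,
               approx(arc, dense[, 3], s_out)$y)
  list(positions = out, arclen = s_out)
}

# distance of every voxel (within reach) to a polyline, plus the local tube
# radius at the nearest point; used for exact rasterization
polyline_distance_field <- function(samples, radii, dims, spacing, reach) {
  dmin <- array(Inf, dims)
  rnear <- array(0, dims)
  nseg <- nrow(samples) - 1L
  for (s in seq_len(nseg)) {
    p1 <- samples[s, ]; p2 <- samples[s + 1L, ]
    r12 <- max(radii[s], radii[s + 1L])
    lo <- pmin(p1, p2) - (r12 + reach)
    hi <- pmax(p1, p2) + (r12 + reach)
    i0 <- pmax(1L, floor(lo / spacing) + 1L)
    i1 <- pmin(dims, ceiling(hi / spacing) + 1L)
    if (any(i0 > i1)) next
    xs <- (seq(i0[1], i1[1]) - 1) * spacing[1]
    ys <- (seq(i0[2], i1[2]) - 1) * spacing[2]
    zs <- (seq(i0[3], i1[3]) - 1) * spacing[3]
    d <- p2 - p1
    len2 <- sum(d^2)
    # projection parameter for each voxel centre, clamped to the segment
    gx <- array(rep(xs, times = length(ys) * length(zs)),
                c(length(xs), length(ys), length(zs)))
    gy <- array(rep(rep(ys, each = length(xs)), times = length(zs)),
                c(length(xs), length(ys), length(zs)))
    gz <- array(rep(zs, each = length(xs) * length(ys)),
                c(length(xs), length(ys), length(zs)))
    tt <- if (len2 > 0)
      pmin(pmax(((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2] + (gz - p1[3]) * d[3]) / len2, 0), 1)
    else 0
    dx <- gx - (p1[1] + tt * d[1])
    dy <- gy - (p1[2] + tt * d[2])
    dz <- gz - (p1[3] + tt * d[3])
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    rloc <- radii[s] + tt * (radii[s + 1L] - radii[s])
    sub <- dmin[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    upd <- dist < sub
    sub[upd] <- dist[upd]
    dmin[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
    rsub <- rnear[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    rsub[upd] <- rloc[upd]
    rnear[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- rsub
  }
  list(dmin = dmin, rnear = rnear)
}

# voxel-centre sphere rasterization
sphere_mask <- function(center, radius, dims, spacing) {
  lo <- pmax(1L, floor((center - radius) / spacing) + 1L - 1L)
  hi <- pmin(dims, ceiling((center + radius) / spacing) + 1L + 1L)
  m <- array(FALSE, dims)
  if (any(lo > hi)) return(m)
  xs <- (seq(lo[1], hi[1]) - 1) * spacing[1]
  ys <- (seq(lo[2], hi[2]) - 1) * spacing[2]
  zs <- (seq(lo[3], hi[3]) - 1) * spacing[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- d2 < radius^2
  m
}

#' Generate a synthetic phantom with ground truth
#'
#' Rasterizes the spec into per-time-point two-channel volumes. A voxel is
#' tube foreground iff its centre lies closer to the centerline polyline than
#' the local radius times the time point's multiplier (no sub-voxel
#' antialiasing: PSF blur supplies edge softness downstream). Ground truth
#' comprises the vessel graph with per-vertex true radii at every time point,
#' and the exact foreground masks.
#'
#' @param spec a [phantom_spec()].
#' @param vertex_spacing arc-length spacing of ground-truth vertices, um
#'   (must be <= 1.73 um).
#' @return A list with elements `volumes` (per time point, a list with
#'   `vascular` and `neuron` [image_volume()]s), `vessel_masks` (per time
#'   point [binary_mask()]), `neuron_mask`, `graph` (ground-truth
#'   [vascular_graph]), and `spec`.
#' @export
generate_phantom <- function(spec, vertex_spacing = 1.0) {
  stopifnot(inherits(spec, "phantom_spec"), vertex_spacing <= 1.73)
  dims <- spec$volume_shape
  sp <- spec$voxel_size
  ntp <- length(spec$timepoints)
  ntube <- length(spec$tubes)

  fields <- vector("list", ntube)
  paths <- vector("list", ntube)
  for (i in seq_len(ntube)) {
    tb <- spec$tubes[[i]]
    cl <- resample_centerline(tb$centerline, step = vertex_spacing)
    rad <- if (is.function(tb$radius)) tb$radius(cl$arclen) else
      rep(tb$radius, length(cl$arclen))
    if (any(rad <= 0)) stop("tube radius must be > 0 along full length")
    fields[[i]] <- polyline_distance_field(cl$positions, rad, dims, sp,
                                           reach = 1.01 * max(unlist(spec$timepoints)))
    paths[[i]] <- list(positions = cl$positions, arclen = cl$arclen, radius = rad)
  }

  neuron_vox <- array(spec$background_level, dims)
  for (nn in spec$neurons) {
    m <- sphere_mask(nn$center, nn$radius, dims, sp)
    neuron_vox[m] <- nn$intensity
  }
  neuron_mask <- array(FALSE, dims)
  for (nn in spec$neurons) neuron_mask <- neuron_mask | sphere_mask(nn$center, nn$radius, dims, sp)

  volumes <- vector("list", ntp)
  vessel_masks <- vector("list", ntp)
  for (t in seq_len(ntp)) {
    mult <- spec$timepoints[[t]]
    if (length(mult) == 1L) mult <- rep(mult, max(1L, ntube))
    if (ntube > 0 && length(mult) != ntube)
      stop("timepoint multipliers must be scalar or one per tube")
    vox <- array(spec$background_level, dims)
    owner <- array(0L, dims)
    for (i in seq_len(ntube)) {
      inside <- fields[[i]]$dmin < fields[[i]]$rnear * mult[i]
      clash <- inside & owner != 0L & vox != spec$tubes[[i]]$intensity
      if (any(clash))
        stop("overlapping phantom primitives with conflicting intensities")
      vox[inside] <- spec$tubes[[i]]$intensity
      owner[inside] <- i
    }
    for (b in spec$beads) {
      m <- sphere_mask(b$center, b$diameter / 2, dims, sp)
      clash <- m & owner != 0L & vox != b$intensity
      if (any(clash))
        stop("overlapping phantom primitives with conflicting intensities")
      vox[m] <- b$intensity
      owner[m] <- -1L
    }
    vessel_masks[[t]] <- binary_mask(owner != 0L, sp, label = "vessel")
    volumes[[t]] <- list(
      vascular = image_volume(vox, sp, channel = "vascular"),
      neuron = image_volume(neuron_vox, sp, channel = "neuron"))
  }

  graph <- phantom_truth_graph(paths, spec, dims)
  list(volumes = volumes, vessel_masks = vessel_masks,
       neuron_mask = binary_mask(neuron_mask, sp, label = "neuron"),
       graph = graph, spec = spec)
}

# ground-truth graph: one edge per tube; coincident tube endpoints (within
# 0.5 um) merge into shared junction nodes
phantom_truth_graph <- function(paths, spec, dims) {
  ntube <- length(paths)
  ends <- list()
  node_pos <- matrix(numeric(0), 0, 3)
  find_node <- function(p) {
    if (nrow(node_pos) > 0) {
      d <- sqrt(rowSums(sweep(node_pos, 2, p)^2))
      hit <- which(d < 0.5)
      if (length(hit)) return(hit[1])
    }
    node_pos <<- rbind(node_pos, p)
    nrow(node_pos)
  }
  edges <- vector("list", ntube)
  for (i in seq_len(ntube)) {
    pp <- paths[[i]]
    n1 <- find_node(pp$positions[1, ])
    n2 <- find_node(pp$positions[nrow(pp$positions), ])
    ntp <- length(spec$timepoints)
    tr <- matrix(NA_real_, nrow(pp$positions), ntp)
    for (t in seq_len(ntp)) {
      mult <- spec$timepoints[[t]]
      if (length(mult) == 1L) mult <- rep(mult, ntube)
      tr[, t] <- pp$radius * mult[i]
    }
    edges[[i]] <- list(id = i, from = n1, to = n2, path = pp$positions,
                       length = pp$arclen[length(pp$arclen)],
                       true_radii = tr)
  }
  deg <- tabulate(unlist(lapply(edges, function(e) c(e$from, e$to))),
                  nbins = nrow(node_pos))
  nodes <- data.frame(id = seq_len(nrow(node_pos)), x = node_pos[, 1],
                      y = node_pos[, 2], z = node_pos[, 3], degree = deg)
  new_vascular_graph(nodes, edges, spec$voxel_size, dims)
}

#' Apply PSF blur and Gaussian noise to a volume
#'
#' Emulates acquisition: the volume is convolved with the PSF, then
#' independent Gaussian noise is added and values are clipped to the 10-bit
#' range. The noise level is given either directly (`noise_sigma`, SU) or as
#' a target signal-to-noise ratio, in which case sigma is solved so the
#' measured SNR (see [measure_snr()]) matches the target: the background
#' variance after blurring is accounted for, so
#' sigma^2 = (mean foreground / target)^2 - var(blurred background).
#'
#' @param image an [image_volume()].
#' @param psf a [psf_model()].
#' @param noise_sigma Gaussian noise standard deviation, SU (exclusive with
#'   `target_snr`).
#' @param target_snr desired SNR; requires `foreground_mask`.
#' @param foreground_mask [binary_mask()] or logical array of signal voxels
#'   (needed for `target_snr`).
#' @param seed integer seed for the noise draw.
#' @param clip clip the result to the volume's bit range (default TRUE).
#' @return The degraded [image_volume()]; the solved sigma is attached as
#'   attribute `"noise_sigma"`.
#' @export
apply_psf_and_noise <- function(image, psf, noise_sigma = NULL,
                                target_snr = NULL, foreground_mask = NULL,
                                seed = 1L, clip = TRUE) {
  stopifnot(inherits(image, "image_volume"), inherits(psf, "psf_model"))
  if (is.null(noise_sigma) == is.null(target_snr))
    stop("give exactly one of noise_sigma or target_snr")
  blurred <- convolve3(image$voxels, psf$kernel)
  if (!is.null(target_snr)) {
    if (is.null(foreground_mask)) stop("target_snr requires foreground_mask")
    m <- if (inherits(foreground_mask, "binary_mask")) foreground_mask$voxels else
      as.array(foreground_mask) != 0
    mu_fg <- mean(blurred[m])
    bg <- blurred[!m]
    if (mu_fg - mean(bg) <= 1e-9 * max(1, abs(mu_fg)))
      stop("target_snr unreachable: foreground <= background")
    s2 <- (mu_fg / target_snr)^2 - var(bg)
    if (s2 <= 0) stop("target_snr unreachable at this contrast")
    noise_sigma <- sqrt(s2)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  out <- blurred
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- out + rnorm(length(out), 0, noise_sigma)
  }
  if (clip) out <- pmin(pmax(out, image$bit_range[1]), image$bit_range[2])
  res <- image_volume(array(out, dim(blurred)), image$voxel_size,
                      image$channel, image$bit_range)
  attr(res, "noise_sigma") <- noise_sigma
  res
}
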