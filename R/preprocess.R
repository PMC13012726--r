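# Preprocessing: isotropic upsampling, rigid registration, mask cleanup,
# dilation + union across time points, and segmentation evaluation metrics.

#' Resample a volume or mask to isotropic spacing
#'
#' Intensity volumes are resampled with trilinear interpolation, masks with
#' nearest neighbour. The physical extent is preserved: the output has
#' `round((n-1) * spacing / target) + 1` voxels per axis.
#'
#' @param x an [image_volume()] or [binary_mask()].
#' @param target_spacing isotropic output spacing, um (default 0.99).
#' @return The resampled object with isotropic `voxel_size`.
#' @export
upsample_isotropic <- function(x, target_spacing = 0.99) {
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("x must be an image_volume or binary_mask")
  sp <- x$voxel_size
  if (all(abs(sp - target_spacing) < 1e-12)) return(x)
  d <- dim(x$voxels)
  nd <- as.integer(round((d - 1L) * sp / target_spacing) + 1L)
  gx <- (seq_len(nd[1]) - 1) * target_spacing / sp[1]
  gy <- (seq_len(nd[2]) - 1) * target_spacing / sp[2]
  gz <- (seq_len(nd[3]) - 1) * target_spacing / sp[3]
  pts <- cbind(rep(gx, times = nd[2] * nd[3]),
               rep(rep(gy, each = nd[1]), times = nd[3]),
               rep(gz, each = nd[1] * nd[2]))
  if (is_mask) {
    v <- cpp_nearest3(as.numeric(x$voxels), d, pts, 0)
    binary_mask(array(v$values != 0, nd), rep(target_spacing, 3), x$label)
  } else {
    v <- cpp_trilinear(as.numeric(x$voxels), d, pts, 0)
    image_volume(array(v$values, nd), rep(target_spacing, 3), x$channel,
                 x$bit_range)
  }
}

#' Rigid transform in physical (micrometer) coordinates
#'
#' Maps a point `p` in the moving frame to `R p + t` in the fixed frame.
#'
#' @param rotation 3x3 rotation matrix (determinant +1).
#' @param translation length-3 translation, um.
#' @param reference_frame identifier of the fixed image.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            reference_frame = "fixed") {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (abs(det(rotation) - 1) > 1e-6) stop("rotation determinant must be +1")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 reference_frame = reference_frame),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) um\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  rigid_transform(R, -R %*% transform$translation, transform$reference_frame)
}

# Euler angles (radians, xyz order) to rotation matrix
euler_to_rotation <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Resample a volume through a rigid transform
#'
#' Pulls the moving volume into the fixed frame: each fixed-grid voxel is
#' sampled from the moving volume at the inverse-transformed position.
#' Intensity volumes use linear interpolation, masks nearest neighbour.
#'
#' @param x [image_volume()] or [binary_mask()] (the moving image).
#' @param transform [rigid_transform()] mapping moving to fixed coordinates.
#' @param interpolation `"linear"` or `"nearest"` (masks always use nearest).
#' @param fill value for samples outside the moving volume.
#' @return The resampled object on the same grid.
#' @export
apply_transform <- function(x, transform,
                            interpolation = c("linear", "nearest"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(x, "binary_mask")
  if (is_mask) interpolation <- "nearest"
  d <- dim(x$voxels)
  sp <- x$voxel_size
  inv <- invert_transform(transform)
  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  P <- cbind(rep(gx, times = d[2] * d[3]),
             rep(rep(gy, each = d[1]), times = d[3]),
             rep(gz, each = d[1] * d[2]))
  Q <- P %*% t(inv$rotation)
  Q <- sweep(Q, 2, -as.numeric(inv$translation))
  Q <- sweep(Q, 2, sp, "/")  # to voxel coords
  if (interpolation == "linear") {
    v <- cpp_trilinear(as.numeric(x$voxels), d, Q, fill)
    image_volume(array(v$values, d), sp, x$channel, x$bit_range)
  } else {
    v <- cpp_nearest3(as.numeric(x$voxels), d, Q, fill)
    if (is_mask) binary_mask(array(v$values != 0, d), sp, x$label)
    else image_volume(array(v$values, d), sp, x$channel, x$bit_range)
  }
}

# MSE of fixed vs transformed moving, over in-bounds voxels only
transform_mse <- function(par, mov, fix, sp, d) {
  R <- euler_to_rotation(par[1:3])
  tr <- par[4:6]
  gx <- (seq_len(d[1]) - 1) * sp[1]
  gy <- (seq_len(d[2]) - 1) * sp[2]
  gz <- (seq_len(d[3]) - 1) * sp[3]
  P <- cbind(rep(gx, times = d[2] * d[3]),
             rep(rep(gy, each = d[1]), times = d[3]),
             rep(gz, each = d[1] * d[2]))
  Q <- (P - matrix(tr, nrow(P), 3, byrow = TRUE)) %*% R  # R^-1 = t(R); (p-t) %*% t(R^-1)... R orthonormal
  Q <- sweep(Q, 2, sp, "/")
  v <- cpp_trilinear(mov, d, Q, NA_real_)
  ok <- !v$outside
  if (mean(ok) < 0.5) return(Inf)
  mean((v$values[ok] - fix[ok])^2)
}

#' Rigid registration by mean-squared-error minimization
#'
#' Estimates the rigid transform aligning `moving` to `fixed`. Both images
#' are Gaussian-smoothed (sigma 2 voxels), translation is initialized by FFT
#' cross-correlation, and the 6 rigid parameters are refined by Nelder-Mead
#' descent on the MSE. Deterministic for fixed inputs.
#'
#' @param moving,fixed [image_volume()]s on the same grid.
#' @param smooth_sigma smoothing sigma in voxels applied to both images
#'   before optimization (default 2).
#' @param maxit optimizer iteration budget.
#' @return A [rigid_transform()] mapping moving into the fixed frame, with
#'   attributes `mse_before` and `mse_after`.
#' @export
rigid_register <- function(moving, fixed, smooth_sigma = 2, maxit = 400) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  if (!identical(dim(moving$voxels), dim(fixed$voxels)))
    stop("moving and fixed must share a grid")
  if (sd(moving$voxels) == 0 || sd(fixed$voxels) == 0)
    stop("degenerate (constant) image: registration undefined")
  d <- dim(fixed$voxels)
  sp <- fixed$voxel_size
  ks <- gaussian_kernel1d(smooth_sigma)
  kern <- outer(outer(ks, ks), ks)
  kern <- kern / sum(kern)
  mv <- convolve3(moving$voxels, kern)
  fx <- convolve3(fixed$voxels, kern)

  # integer-shift initialization by circular cross-correlation
  Fm <- fft(mv); Ff <- fft(fx)
  cc <- Re(fft(Ff * Conj(Fm), inverse = TRUE))
  w <- which.max(cc)
  k0 <- (w - 1) %/% (d[1] * d[2])
  rem <- (w - 1) %% (d[1] * d[2])
  shift <- c(rem %% d[1], rem %/% d[1], k0)
  shift <- ifelse(shift > d / 2, shift - d, shift)
  init <- c(0, 0, 0, shift * sp)

  mv_v <- as.numeric(mv); fx_v <- as.numeric(fx)
  obj <- function(par) transform_mse(par, mv_v, fx_v, sp, d)
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9,
                              parscale = c(0.02, 0.02, 0.02, 1, 1, 1)))
  tf <- rigid_transform(euler_to_rotation(fit$par[1:3]), fit$par[4:6],
                        reference_frame = "fixed")
  attr(tf, "mse_before") <- mean((moving$voxels - fixed$voxels)^2)
  attr(tf, "mse_after") <- transform_mse(fit$par, as.numeric(moving$voxels),
                                         as.numeric(fixed$voxels), sp, d)
  tf
}

#' Fill enclosed holes and drop small components of a vessel mask
#'
#' Background components (6-connected) that do not touch the volume boundary
#' and whose entire 26-neighbourhood outside the component is vessel are
#' relabelled vessel; vessel components (26-connected) smaller than
#' `min_component_voxels` are removed. Idempotent.
#'
#' @param mask a [binary_mask()].
#' @param min_component_voxels minimum size of a retained vessel component
#'   (default 50 voxels; components strictly under the threshold are removed).
#' @return The cleaned [binary_mask()].
#' @export
clean_mask <- function(mask, min_component_voxels = 50) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$voxels
  d <- dim(m)
  # 1) fill enclosed background
  bg_lab <- cpp_label3d(!m, d, 6L)
  ncomp <- attr(bg_lab, "n_components")
  labs <- array(bg_lab, d)
  if (ncomp > 0) {
    border <- unique(c(labs[1, , ], labs[d[1], , ], labs[, 1, ], labs[, d[2], ],
                       labs[, , 1], labs[, , d[3]]))
    border <- border[border != 0]
    interior <- setdiff(seq_len(ncomp), border)
    for (cc in interior) m[labs == cc] <- TRUE
  }
  # 2) drop small vessel components
  vl <- cpp_label3d(m, d, 26L)
  nvc <- attr(vl, "n_components")
  if (nvc > 0) {
    sizes <- tabulate(vl[vl != 0], nbins = nvc)
    drop <- which(sizes < min_component_voxels)
    if (length(drop)) m[array(vl, d) %in% drop] <- FALSE
  }
  binary_mask(m, mask$voxel_size, mask$label)
}

#' Dilate and union registered masks across time points
#'
#' Each mask is dilated `dilation_rounds` times with a radius-1 disk applied
#' slicewise in the xy plane, then the voxelwise union over all time points
#' is taken. The union bridges transient gaps (e.g. red-blood-cell stalls)
#' present at individual time points.
#'
#' @param masks list of registered, cleaned [binary_mask()]s on one grid.
#' @param dilation_rounds number of dilation passes (default 3).
#' @return The union [binary_mask()].
#' @export
union_masks <- function(masks, dilation_rounds = 3) {
  stopifnot(length(masks) >= 1)
  d <- dim(masks[[1]]$voxels)
  for (m in masks) {
    stopifnot(inherits(m, "binary_mask"))
    if (!same_grid(m, masks[[1]])) stop("masks must share one grid")
  }
  acc <- array(FALSE, d)
  for (m in masks) {
    dm <- cpp_dilate_xy_disk(m$voxels, d, as.integer(dilation_rounds))
    acc <- acc | array(dm, d)
  }
  binary_mask(acc, masks[[1]]$voxel_size, masks[[1]]$label)
}

# boundary voxels: foreground with at least one 6-neighbour background
# (volume border counts as background)
boundary_voxels <- function(m) {
  d <- dim(m)
  shift_bg <- function(ax, dir) {
    out <- array(TRUE, d)
    if (ax == 1) {
      if (dir > 0) out[-d[1], , ] <- !m[-1, , ] else out[-1, , ] <- !m[-d[1], , ]
    } else if (ax == 2) {
      if (dir > 0) out[, -d[2], ] <- !m[, -1, ] else out[, -1, ] <- !m[, -d[2], ]
    } else {
      if (dir > 0) out[, , -d[3]] <- !m[, , -1] else out[, , -1] <- !m[, , -d[3]]
    }
    out
  }
  nb_bg <- shift_bg(1, 1) | shift_bg(1, -1) | shift_bg(2, 1) | shift_bg(2, -1) |
    shift_bg(3, 1) | shift_bg(3, -1)
  m & nb_bg
}

#' Segmentation evaluation metrics
#'
#' Computes the Dice similarity coefficient, precision, recall, the 95th
#' percentile Hausdorff distance (HD95) and the mean surface distance between
#' a ground-truth mask `truth` (X) and a prediction `pred` (Y). Surface
#' distances are Euclidean distances in micrometers between boundary voxel
#' centres (boundary = foreground voxel with a background 6-neighbour);
#' HD95 is the maximum of the two directed 95th-percentile distances, and
#' the mean surface distance averages both directed distance sets.
#'
#' @param truth,pred [binary_mask()]s on the same grid.
#' @return A list with `dsc`, `precision`, `recall`, `hd95`, `mean_surface_distance`.
#' @export
segmentation_metrics <- function(truth, pred) {
  stopifnot(inherits(truth, "binary_mask"), inherits(pred, "binary_mask"))
  if (!same_grid(truth, pred)) stop("masks must share a grid")
  X <- truth$voxels; Y <- pred$voxels
  if (!any(X) || !any(Y)) stop("empty foreground: metrics undefined")
  tp <- sum(X & Y)
  dsc <- 2 * tp / (sum(X) + sum(Y))
  precision <- tp / sum(Y)
  recall <- tp / sum(X)
  d <- dim(X)
  sp <- truth$voxel_size
  bx <- boundary_voxels(X)
  by <- boundary_voxels(Y)
  dtY <- cpp_edt3d(as.logical(by), d, sp)  # distance to Y boundary
  dtX <- cpp_edt3d(as.logical(bx), d, sp)
  dxy <- dtY[bx]  # directed X -> Y
  dyx <- dtX[by]
  hd95 <- max(quantile(dxy, 0.95, names = FALSE),
              quantile(dyx, 0.95, names = FALSE))
  msd <- (sum(dxy) + sum(dyx)) / (length(dxy) + length(dyx))
  list(dsc = dsc, precision = precision, recall = recall,
       hd95 = hd95, mean_surface_distance = msd)
}

#' Threshold segmentation (phantom and bead use)
#'
#' @param volume an [image_volume()].
#' @param method `"otsu"` (histogram-based automatic threshold) or `"fixed"`.
#' @param threshold fixed threshold (required for `method = "fixed"`);
#'   voxels strictly above threshold are foreground.
#' @param label mask label for the result.
#' @return A [binary_mask()].
#' @export
threshold_segment <- function(volume, method = c("otsu", "fixed"),
                              threshold = NULL, label = "vessel") {
  method <- match.arg(method)
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  if (method == "otsu") {
    if (max(v) == min(v)) stop("constant image: Otsu threshold undefined")
    threshold <- otsu_threshold(as.numeric(v))
  } else if (is.null(threshold)) stop("fixed method needs a threshold")
  binary_mask(v > threshold, volume$voxel_size, label)
}

# Otsu's method on a 256-bin histogram
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}
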