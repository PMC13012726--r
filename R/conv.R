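# FFT-based convolution and Gaussian smoothing helpers (internal).
# 3D convolution pads with edge replication so constant backgrounds stay
# constant at the volume border; kernels are centred.

pad_indices <- function(n, p) pmin(pmax(seq_len(n + 2 * p) - p, 1L), n)

# replicate-pad a 3D array by p voxels per axis (p length-3)
pad_replicate3 <- function(a, p) {
  d <- dim(a)
  a[pad_indices(d[1], p[1]), pad_indices(d[2], p[2]), pad_indices(d[3], p[3]),
    drop = FALSE]
}

# circular FFT convolution of two arrays of identical dims; kernel given as a
# small centred array, embedded with its centre at the origin
embed_kernel3 <- function(kern, d) {
  kd <- dim(kern)
  big <- array(0, d)
  big[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kern
  ctr <- (kd - 1L) %/% 2L
  for (ax in 1:3) {
    if (ctr[ax] > 0) {
      idx <- c(seq(ctr[ax] + 1L, d[ax]), seq_len(ctr[ax]))
      big <- switch(ax, big[idx, , , drop = FALSE], big[, idx, , drop = FALSE],
                    big[, , idx, drop = FALSE])
    }
  }
  big
}

# convolve 3D array with centred kernel, replicate edge handling
convolve3 <- function(a, kern) {
  d <- dim(a)
  kd <- dim(kern)
  p <- (kd - 1L) %/% 2L + 1L
  ap <- pad_replicate3(a, p)
  dp <- dim(ap)
  K <- embed_kernel3(kern, dp)
  out <- Re(fft(fft(ap) * fft(K), inverse = TRUE)) / prod(dp)
  out[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]),
      drop = FALSE]
}

# 1D Gaussian kernel in sample units
gaussian_kernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1D smoothing with replicate padding
smooth1d <- function(x, sigma) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  if (r == 0) return(x)
  n <- length(x)
  xp <- x[pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)]
  as.numeric(stats::convolve(xp, rev(k), type = "filter"))
}

# separable 2D Gaussian smoothing with replicate padding (sigma in pixels)
smooth2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  n1 <- nrow(img); n2 <- ncol(img)
  i1 <- pmin(pmax(seq_len(n1 + 2 * r) - r, 1L), n1)
  i2 <- pmin(pmax(seq_len(n2 + 2 * r) - r, 1L), n2)
  a <- img[i1, , drop = FALSE]
  a <- apply(a, 2, function(col) stats::convolve(col, rev(k), type = "filter"))
  a <- a[, i2, drop = FALSE]
  t(apply(a, 1, function(row) stats::convolve(row, rev(k), type = "filter")))
}

# smoothing along vertex index with linear extrapolation padding: exact on
# straight (affine) centerlines, so smoothing never bends a straight vessel
smooth_linear_extrap <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 2) return(x)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  s0 <- x[2] - x[1]
  s1 <- x[n] - x[n - 1]
  xp <- c(x[1] - s0 * (r:1), x, x[n] + s1 * (1:r))
  as.numeric(stats::convolve(xp, rev(k), type = "filter"))
}
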