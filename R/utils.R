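# Internal numerics shared across modules: padding index maps, shifted-slab
# separable convolution, axis shifts, ball-structuring-element morphology,
# and the single-seed fan-out used for reproducibility.

# Map arbitrary integer positions onto 1..n under a boundary rule.
# "reflect" is symmetric (edge value repeated: 0 -> 1, -1 -> 2), applied
# repeatedly so any half-width works on any axis length.
pad_index <- function(i, n, padding = c("reflect", "periodic", "replicate")) {
  padding <- match.arg(padding)
  if (n == 1L) return(rep(1L, length(i)))
  switch(padding,
    periodic = ((i - 1L) %% n) + 1L,
    replicate = pmin.int(pmax.int(i, 1L), n),
    reflect = {
      j <- (i - 1L) %% (2L * n)
      ifelse(j >= n, 2L * n - 1L - j, j) + 1L
    }
  )
}

# Take a slab of a 3D array along one axis using an index vector.
slab3d <- function(a, axis, idx) {
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

# Correlate a 3D array with a 1D kernel along one axis (kernel length 2w+1).
# Kernels used here are symmetric, so correlation equals convolution.
conv_axis <- function(a, kernel, axis, padding = "reflect") {
  d <- dim(a)
  n <- d[axis]
  w <- (length(kernel) - 1L) %/% 2L
  if (w == 0L) return(a * kernel[1L])
  padded <- slab3d(a, axis, pad_index((1L - w):(n + w), n, padding))
  out <- array(0, d)
  for (o in seq(-w, w)) {
    out <- out + kernel[o + w + 1L] * slab3d(padded, axis, (1L + w + o):(n + w + o))
  }
  out
}

# Separable 3D Gaussian smoothing with per-axis normalized truncated kernels;
# equals correlation with the cube-normalized kernel exp(-(i^2+j^2+k^2)/2s^2)/B
# because that kernel factorizes and B = (sum of 1D weights)^3.
gaussian_smooth3d <- function(a, sigma, w, padding = "reflect") {
  g <- exp(-(seq(-w, w))^2 / (2 * sigma^2))
  g <- g / sum(g)
  for (axis in 1:3) a <- conv_axis(a, g, axis, padding)
  a
}

# Shift a 3D array by one voxel along an axis, replicating the vacated face
# (used by finite differences before boundary replication).
shift3d <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin.int(pmax.int(seq_len(n) + by, 1L), n)
  slab3d(a, axis, idx)
}

# Integer offsets of a digital ball of Euclidean radius r (including origin).
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Binary dilation/erosion of a logical 3D array by a ball structuring element.
# Outside the grid counts as background.
dilate3d <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  out <- mask
  for (k in seq_len(nrow(off <- ball_offsets(radius)))) {
    o <- off[k, ]
    if (all(o == 0)) next
    sh <- offset_shift(mask, o, fill = FALSE)
    out <- out | sh
  }
  out
}

erode3d <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  out <- mask
  for (k in seq_len(nrow(off <- ball_offsets(radius)))) {
    o <- off[k, ]
    if (all(o == 0)) next
    sh <- offset_shift(mask, o, fill = FALSE)
    out <- out & sh
  }
  out
}

# Shift a logical array by an integer offset, filling vacated voxels.
offset_shift <- function(mask, offset, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (axis in 1:3) {
    o <- offset[axis]
    n <- d[axis]
    if (abs(o) >= n) return(out)
    if (o >= 0) {
      dst[[axis]] <- (1L + o):n
      src[[axis]] <- 1L:(n - o)
    } else {
      dst[[axis]] <- 1L:(n + o)
      src[[axis]] <- (1L - o):n
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    mask[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Fan a single user seed out to per-stage seeds. Keeps results < 2^31 so the
# value is a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + salt * 16807 + 12345) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
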