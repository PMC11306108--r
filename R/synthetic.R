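# Parametric synthetic cleared-brain scenes with exact ground truth.
# A scene emulates the ingredients the detection chain has to cope with:
# bright quasi-spherical cells (isotropic Gaussian blobs), elongated
# vessel-like tubes (Gaussian-profile tubes along polylines), a smooth
# low-frequency autofluorescence field multiplying everything, and additive
# camera noise. Foreground is multiplicative on the background
# (volume = background * (1 + sum of kernels) + noise), so contrasts are
# expressed relative to the local background, matching what division
# normalization assumes.

#' Specify a synthetic cleared-brain scene
#'
#' Either pass explicit `cells` / `vessels` tables, or give counts and let
#' the generator place structures at random (margin from the faces, enforced
#' pairwise separation, vessels kept clear of cells) reproducibly by `seed`.
#'
#' Defaults encode the study conditions the test-suite properties run under:
#' a 128^3 grid at mesoSPIM-like spacing, 20 cells of radius 3-5 voxels with
#' peak contrast 4-8x the local background, 5 vessel-like tubes, a smooth
#' background field of 20% relative amplitude and 40-voxel length scale over
#' base level 100, and 2% additive Gaussian camera noise.
#'
#' @param shape Grid dimensions `(z, y, x)` in voxels.
#' @param spacing Voxel size in um `(z, y, x)`.
#' @param n_cells,n_vessels Structure counts used when `cells` / `vessels`
#'   are not supplied.
#' @param cells Optional tibble with columns `z, y, x, radius, amplitude`
#'   (center in voxels, radius in voxels, peak amplitude as a multiple of the
#'   local background).
#' @param vessels Optional list of `list(points = k x 3 matrix, radius,
#'   amplitude)` polyline tubes.
#' @param cell_radius,cell_amplitude Ranges used for random cells.
#' @param vessel_radius,vessel_amplitude Ranges used for random vessels.
#' @param background `list(level, length_scale, amplitude)`: base intensity,
#'   smoothing length scale in voxels of the low-frequency field, and its
#'   relative amplitude.
#' @param noise_sd Gaussian camera-noise standard deviation as a fraction of
#'   the base level.
#' @param seed Integer seed; fixed seed makes rendering bit-reproducible.
#' @return A list of class `synthetic_scene`.
#' @export
synthetic_scene <- function(shape = c(128, 128, 128),
                            spacing = c(3, 3.26, 3.26),
                            n_cells = 20, n_vessels = 5,
                            cells = NULL, vessels = NULL,
                            cell_radius = c(3, 5), cell_amplitude = c(4, 8),
                            vessel_radius = c(1.5, 2.5), vessel_amplitude = c(3, 6),
                            background = list(level = 100, length_scale = 40,
                                              amplitude = 0.2),
                            noise_sd = 0.02, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (noise_sd < 0) stop("noise level must be >= 0", call. = FALSE)
  bg <- modifyList(list(level = 100, length_scale = 40, amplitude = 0.2),
                   as.list(background))
  if (bg$level < 0 || bg$amplitude < 0 || bg$length_scale <= 0) {
    stop("background level/amplitude must be >= 0 and length_scale > 0", call. = FALSE)
  }
  set.seed(derive_seed(seed, "placement"))
  if (is.null(cells)) {
    cells <- place_cells(n_cells, shape, cell_radius, cell_amplitude)
  } else {
    cells <- tibble::as_tibble(cells)
  }
  if (is.null(vessels)) {
    vessels <- place_vessels(n_vessels, shape, vessel_radius, vessel_amplitude,
                             avoid = cells)
  }
  if (nrow(cells)) {
    if (any(cells$radius <= 0)) stop("cell radii must be > 0", call. = FALSE)
    if (any(cells$amplitude < 0)) stop("cell amplitudes must be >= 0", call. = FALSE)
    inside <- cells$z >= 1 & cells$z <= shape[1] &
      cells$y >= 1 & cells$y <= shape[2] &
      cells$x >= 1 & cells$x <= shape[3]
    if (!all(inside)) stop("cell centers must lie inside the grid", call. = FALSE)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 cells = cells, vessels = vessels,
                 background = bg, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Rejection-sample non-overlapping cell centers with a margin from the faces.
place_cells <- function(n, shape, radius_range, amplitude_range,
                        min_separation = 16, margin = 10) {
  if (n == 0) {
    return(tibble::tibble(z = numeric(), y = numeric(), x = numeric(),
                          radius = numeric(), amplitude = numeric()))
  }
  lo <- pmin(margin, pmax(1, floor(shape / 4)))
  centers <- matrix(NA_real_, 0L, 3L)
  tries <- 0L
  while (nrow(centers) < n && tries < 20000L) {
    tries <- tries + 1L
    p <- c(runif(1, lo[1], shape[1] - lo[1] + 1),
           runif(1, lo[2], shape[2] - lo[2] + 1),
           runif(1, lo[3], shape[3] - lo[3] + 1))
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums(sweep(centers, 2L, p)^2))) >= min_separation) {
      centers <- rbind(centers, p)
    }
  }
  if (nrow(centers) < n) {
    stop("could not place ", n, " non-overlapping cells in this grid", call. = FALSE)
  }
  tibble::tibble(
    z = centers[, 1L], y = centers[, 2L], x = centers[, 3L],
    radius = runif(n, radius_range[1L], radius_range[2L]),
    amplitude = runif(n, amplitude_range[1L], amplitude_range[2L])
  )
}

# Random gently-curved polyline tubes, kept clear of the planted cells.
place_vessels <- function(n, shape, radius_range, amplitude_range,
                          avoid = NULL, clearance = 14, margin = 6) {
  if (n == 0) return(list())
  out <- vector("list", n)
  k <- 0L
  tries <- 0L
  while (k < n && tries < 20000L) {
    tries <- tries + 1L
    axis <- sample.int(3L, 1L)
    p0 <- runif(3, margin, shape - margin + 1)
    p1 <- p0
    p0[axis] <- margin
    p1[axis] <- shape[axis] - margin + 1
    mid <- (p0 + p1) / 2 + rnorm(3, 0, shape / 20)
    mid <- pmin(pmax(mid, margin), shape - margin + 1)
    pts <- rbind(p0, mid, p1)
    ok <- TRUE
    if (!is.null(avoid) && nrow(avoid)) {
      samp <- polyline_points(pts, step = 2)
      centers <- as.matrix(avoid[, c("z", "y", "x")])
      dmin <- min(apply(samp, 1L, function(q) {
        min(sqrt(rowSums(sweep(centers, 2L, q)^2)))
      }))
      ok <- dmin >= clearance
    }
    if (ok) {
      k <- k + 1L
      out[[k]] <- list(points = unname(pts),
                       radius = runif(1, radius_range[1L], radius_range[2L]),
                       amplitude = runif(1, amplitude_range[1L], amplitude_range[2L]))
    }
  }
  if (k < n) stop("could not place ", n, " vessels clear of the cells", call. = FALSE)
  out
}

polyline_points <- function(pts, step = 2) {
  segs <- lapply(seq_len(nrow(pts) - 1L), function(i) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
          a[3] + t * (b[3] - a[3]))
  })
  do.call(rbind, segs)
}

#' Render a synthetic scene to a volume with exact ground truth
#'
#' Produces `background_field * (1 + sum of foreground kernels) + noise`,
#' clipped at 0. Cells render as isotropic Gaussian blobs
#' `amplitude * exp(-r^2 / 2 s^2)` with `s = radius / 2`; vessels as
#' Gaussian-profile tubes along their polylines. The truth mask of a
#' structure marks voxels where its noiseless contribution exceeds half its
#' peak (the half-peak isosurface — well defined and resolution independent).
#' The background field is `level * (1 + amplitude * u)` where `u` is
#' unit-variance, zero-mean Gaussian-smoothed white noise with the requested
#' length scale; its smoothing length is much larger than a cell radius, so
#' structures stay small compared with background intensity variation.
#'
#' @param scene A [synthetic_scene].
#' @return A list: `volume` ([volume3d]), `cell_mask` and `vessel_mask`
#'   (logical 3D arrays), and `truth` — a tibble with `id`, `class`
#'   (`"cell"`/`"vessel"`), center `z, y, x`, `volume_vox`, `volume_um3`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  shape <- scene$shape
  set.seed(derive_seed(scene$seed, "render"))
  bg <- scene$background

  field <- array(bg$level, shape)
  if (bg$amplitude > 0) {
    u <- smooth_noise_field(shape, bg$length_scale)
    field <- bg$level * (1 + bg$amplitude * u)
  }

  fg <- array(0, shape)
  cell_mask <- array(FALSE, shape)
  vessel_mask <- array(FALSE, shape)
  truth <- list()

  if (nrow(scene$cells)) {
    for (i in seq_len(nrow(scene$cells))) {
      cl <- scene$cells[i, ]
      s <- cl$radius / 2
      box <- structure_box(c(cl$z, cl$y, cl$x), 5 * s, shape)
      r2 <- radius2_grid(box, c(cl$z, cl$y, cl$x))
      kern <- cl$amplitude * exp(-r2 / (2 * s^2))
      fg[box$z, box$y, box$x] <- fg[box$z, box$y, box$x] + kern
      m <- r2 < 2 * log(2) * s^2  # contribution > half peak
      cell_mask[box$z, box$y, box$x] <- cell_mask[box$z, box$y, box$x] | m
      truth[[length(truth) + 1L]] <- tibble::tibble(
        class = "cell", z = cl$z, y = cl$y, x = cl$x,
        volume_vox = sum(m)
      )
    }
  }

  for (v in scene$vessels) {
    s <- v$radius / 2
    prof <- vessel_profile(v$points, s, shape)
    fg <- fg + v$amplitude * prof
    m <- prof > 0.5
    vessel_mask <- vessel_mask | m
    ctr <- colMeans(polyline_points(v$points, step = 1))
    truth[[length(truth) + 1L]] <- tibble::tibble(
      class = "vessel", z = ctr[1L], y = ctr[2L], x = ctr[3L],
      volume_vox = sum(m)
    )
  }

  vol <- field * (1 + fg)
  if (scene$noise_sd > 0) {
    vol <- vol + rnorm(length(vol), 0, scene$noise_sd * bg$level)
  }
  vol[vol < 0] <- 0
  dim(vol) <- shape

  truth_tbl <- if (length(truth)) {
    dplyr::bind_rows(truth)
  } else {
    tibble::tibble(class = character(), z = numeric(), y = numeric(),
                   x = numeric(), volume_vox = integer())
  }
  truth_tbl <- dplyr::mutate(
    truth_tbl,
    id = dplyr::row_number(),
    volume_um3 = .data$volume_vox * prod(scene$spacing),
    .before = 1L
  )

  list(
    volume = volume3d(vol, spacing = scene$spacing,
                      name = sprintf("synthetic_seed%d", scene$seed)),
    cell_mask = cell_mask,
    vessel_mask = vessel_mask,
    truth = truth_tbl[, c("id", "class", "z", "y", "x", "volume_vox", "volume_um3")]
  )
}

# Zero-mean, unit-variance smooth Gaussian random field synthesized from a
# random cosine series (Neumann boundaries): mode (mz, my, mx) with
# wavenumber k = pi * m / n per axis gets an independent N(0, 1) coefficient
# weighted by exp(-L^2 |k|^2 / 2). Cosine modes make the field's natural
# continuation across each face its mirror image, i.e. the field carries no
# systematic gradient into the faces — background variation is a property of
# the scene interior, not an edge artifact.
smooth_noise_field <- function(shape, length_scale) {
  m_max <- vapply(shape, function(n) {
    as.integer(min(n - 1L, max(2L, ceiling(4.5 * n / (pi * length_scale)))))
  }, integer(1))
  basis <- lapply(1:3, function(a) {
    n <- shape[a]
    m <- 0:m_max[a]
    outer(seq_len(n) - 0.5, m, function(p, mm) cos(pi * mm * p / n))
  })
  wts <- lapply(1:3, function(a) {
    k <- pi * (0:m_max[a]) / shape[a]
    exp(-length_scale^2 * k^2 / 2)
  })
  coef <- array(rnorm(prod(m_max + 1L)), m_max + 1L)
  coef <- coef * outer(outer(wts[[1L]], wts[[2L]]), wts[[3L]])
  coef[1L, 1L, 1L] <- 0  # constant mode is the base level itself
  # contract mode coefficients with the cosine bases, one axis at a time
  tmp <- basis[[1L]] %*% matrix(coef, nrow = dim(coef)[1L])
  dim(tmp) <- c(shape[1L], dim(coef)[2L], dim(coef)[3L])
  tmp <- aperm(tmp, c(2L, 1L, 3L))
  tmp2 <- basis[[2L]] %*% matrix(tmp, nrow = dim(tmp)[1L])
  dim(tmp2) <- c(shape[2L], shape[1L], dim(coef)[3L])
  tmp2 <- aperm(tmp2, c(3L, 2L, 1L))
  tmp3 <- basis[[3L]] %*% matrix(tmp2, nrow = dim(tmp2)[1L])
  dim(tmp3) <- c(shape[3L], shape[1L], shape[2L])
  sm <- aperm(tmp3, c(2L, 3L, 1L))
  (sm - mean(sm)) / sd(sm)
}

structure_box <- function(center, reach, shape) {
  lo <- pmax(1L, floor(center - reach))
  hi <- pmin(shape, ceiling(center + reach))
  list(z = lo[1L]:hi[1L], y = lo[2L]:hi[2L], x = lo[3L]:hi[3L])
}

radius2_grid <- function(box, center) {
  dz <- box$z - center[1L]
  dy <- box$y - center[2L]
  dx <- box$x - center[3L]
  outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
}

# Unit-amplitude Gaussian tube profile along a polyline; per-vessel fields
# take the max over segments so joints do not double-count.
vessel_profile <- function(points, s, shape) {
  prof <- array(0, shape)
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    lo <- pmax(1L, floor(pmin(a, b) - 5 * s))
    hi <- pmin(shape, ceiling(pmax(a, b) + 5 * s))
    zz <- lo[1L]:hi[1L]; yy <- lo[2L]:hi[2L]; xx <- lo[3L]:hi[3L]
    g <- expand.grid(z = zz, y = yy, x = xx)
    d2 <- point_segment_dist2(as.matrix(g), a, b)
    val <- exp(-d2 / (2 * s^2))
    dim(val) <- c(length(zz), length(yy), length(xx))
    prof[zz, yy, xx] <- pmax(prof[zz, yy, xx], val)
  }
  prof
}

point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(p, 2L, a)
  t <- if (len2 > 0) pmin(pmax((rel %*% ab) / len2, 0), 1) else rep(0, nrow(p))
  diff <- rel - t %*% t(ab)
  rowSums(diff^2)
}

#' Toy box atlas for regional quantification tests
#'
#' Fills axis-aligned, non-overlapping boxes with integer labels on a coarse
#' grid — a stand-in for a registered annotation volume.
#'
#' @param shape Atlas grid dimensions `(z, y, x)`.
#' @param spacing Atlas voxel size in um (default 25 isotropic).
#' @param boxes Tibble/data frame with columns `label`, `region`,
#'   `super_region`, corner `z, y, x` (1-based, inclusive) and size
#'   `dz, dy, dx` in voxels.
#' @return An [atlas_volume]; voxels outside every box carry label 0.
#' @export
make_toy_atlas <- function(shape, spacing = c(25, 25, 25), boxes) {
  shape <- as.integer(shape)
  boxes <- tibble::as_tibble(boxes)
  labels <- array(0L, shape)
  if (nrow(boxes)) {
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      z1 <- b$z + b$dz - 1L; y1 <- b$y + b$dy - 1L; x1 <- b$x + b$dx - 1L
      if (b$z < 1 || b$y < 1 || b$x < 1 ||
          z1 > shape[1L] || y1 > shape[2L] || x1 > shape[3L]) {
        stop("box for label ", b$label, " extends outside the grid", call. = FALSE)
      }
      patch <- labels[b$z:z1, b$y:y1, b$x:x1]
      if (any(patch != 0L)) {
        stop("boxes overlap at label ", b$label, call. = FALSE)
      }
      labels[b$z:z1, b$y:y1, b$x:x1] <- as.integer(b$label)
    }
  }
  rt <- if (nrow(boxes)) {
    boxes[, c("label", "region", "super_region")]
  } else {
    tibble::tibble(label = integer(), region = character(),
                   super_region = character())
  }
  atlas_volume(labels, spacing = spacing, region_table = rt)
}

#' Labeled morphology-feature fixture
#'
#' Draws feature rows from two class-conditional distributions — compact,
#' bright, low-anisotropy "cell" objects versus elongated, dimmer "vessel"
#' objects — standing in for manually labeled training objects. Features are
#' derived from latent ellipsoid axes so the gyration-tensor identities
#' (eigenvalue ordering, `rg2 = sum(lambda)`, `kappa2` in `[0, 1]`) hold by
#' construction.
#'
#' `separation` is the effect size (Cohen's d) applied to every
#' class-discriminating latent (elongation and intensity); at 0 the two
#' classes share one distribution and a classifier can only reach chance.
#' The default 3 is the moderate-separation setting the held-out accuracy
#' properties run under.
#'
#' @param n_cells,n_vessels Row counts per class (>= 0).
#' @param separation Class separation as Cohen's d on the latents.
#' @param seed Integer seed; fixed seed reproduces the table.
#' @return Tibble with `id`, [feature_columns()] and `label`
#'   (`"cell"`/`"non-cell"`).
#' @export
make_feature_fixture <- function(n_cells, n_vessels, separation = 3, seed = 1) {
  if (n_cells < 0 || n_vessels < 0) stop("counts must be >= 0", call. = FALSE)
  set.seed(derive_seed(seed, "feature_fixture"))
  n <- n_cells + n_vessels
  label <- rep(c("cell", "non-cell"), c(n_cells, n_vessels))
  if (n == 0L) {
    return(tibble::tibble(id = integer(),
                          !!!setNames(rep(list(numeric()), 10L), feature_columns()),
                          label = character()))
  }
  sgn <- ifelse(label == "cell", -1, 1)       # vessels: more elongated, dimmer
  sd_e <- 0.4; sd_i <- 0.3
  elong <- rnorm(n, 0.15 + sgn * separation * sd_e / 2, sd_e)
  b <- rlnorm(n, log(2), 0.25)                 # semi-minor radius, voxels
  r1 <- b * exp(pmax(elong, 0))
  r3 <- b * exp(-abs(rnorm(n, 0, 0.15)))
  lam <- cbind(r1^2, b^2, r3^2) / 5            # solid-ellipsoid eigenvalues
  lam <- t(apply(lam, 1L, sort, decreasing = TRUE))
  rg2 <- rowSums(lam)
  asp <- lam[, 1L] - (lam[, 2L] + lam[, 3L]) / 2
  acy <- lam[, 2L] - lam[, 3L]
  kappa2 <- ifelse(rg2 > 0, (asp^2 + 0.75 * acy^2) / rg2^2, 0)
  vol <- pmax(1, round(4 * pi / 3 * r1 * b * r3))
  sphere_ratio <- vol / (4 * pi / 3 * rg2^1.5)
  contrast <- rlnorm(n, log(1.5) - sgn * separation * sd_i / 2, sd_i)
  max_id <- 1 + contrast
  mean_id <- 1 + contrast * runif(n, 0.35, 0.6)
  tibble::tibble(
    id = seq_len(n),
    rg2 = rg2, lambda1 = lam[, 1L], lambda2 = lam[, 2L], lambda3 = lam[, 3L],
    asphericity = asp, acylindricity = acy,
    kappa2 = pmin(pmax(kappa2, 0), 1), sphere_ratio = sphere_ratio,
    mean_Id = mean_id, max_Id = max_id,
    label = label
  )
}

#' Label detected candidates against truth masks
#'
#' Assigns `"cell"` to candidates whose (rounded) centroid falls inside the
#' cell truth mask and `"non-cell"` otherwise — the synthetic analogue of
#' manual object labeling for classifier training.
#'
#' @param candidates Candidate tibble (needs centroid columns `z, y, x`).
#' @param cell_mask Logical 3D array of true cell voxels.
#' @return The tibble with a `label` column appended.
#' @export
label_candidates_by_truth <- function(candidates, cell_mask) {
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, label = character()))
  }
  d <- dim(cell_mask)
  zi <- pmin(pmax(round(candidates$z), 1L), d[1L])
  yi <- pmin(pmax(round(candidates$y), 1L), d[2L])
  xi <- pmin(pmax(round(candidates$x), 1L), d[3L])
  hit <- cell_mask[cbind(zi, yi, xi)]
  dplyr::mutate(candidates, label = ifelse(hit, "cell", "non-cell"))
}
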