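# Independent brute-force oracles (deliberately naive implementations, kept
# separate from the package's vectorized/compiled code paths) plus shared
# fixtures.

# Symmetric-reflection index (edge repeated), matching the package's default
# boundary rule but computed directly.
oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i      # reflect below: 0 -> 1, -1 -> 2
    if (i > n) i <- 2L * n + 1L - i  # reflect above: n+1 -> n
  }
  i
}

# Triple-loop cubic-kernel convolution, Eq-style: weights
# exp(-(i^2+j^2+k^2)/2s^2) normalized over the (2w+1)^3 cube.
oracle_background <- function(a, sigma, w, padding = "reflect") {
  d <- dim(a)
  idx <- seq(-w, w)
  kern <- array(0, rep(2L * w + 1L, 3L))
  for (i in idx) for (j in idx) for (k in idx) {
    kern[i + w + 1L, j + w + 1L, k + w + 1L] <-
      exp(-(i^2 + j^2 + k^2) / (2 * sigma^2))
  }
  kern <- kern / sum(kern)
  out <- array(0, d)
  pad_one <- function(i, n) {
    if (padding == "periodic") ((i - 1L) %% n) + 1L else oracle_reflect(i, n)
  }
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (i in idx) for (j in idx) for (k in idx) {
      acc <- acc + kern[i + w + 1L, j + w + 1L, k + w + 1L] *
        a[pad_one(z + i, d[1]), pad_one(y + j, d[2]), pad_one(x + k, d[3])]
    }
    out[z, y, x] <- acc
  }
  out
}

# Direct second central differences, interior voxels only.
oracle_neg_laplacian_interior <- function(a) {
  d <- dim(a)
  out <- array(NA_real_, d)
  for (z in 2:(d[1] - 1L)) for (y in 2:(d[2] - 1L)) for (x in 2:(d[3] - 1L)) {
    out[z, y, x] <- -(
      a[z + 1L, y, x] - 2 * a[z, y, x] + a[z - 1L, y, x] +
      a[z, y + 1L, x] - 2 * a[z, y, x] + a[z, y - 1L, x] +
      a[z, y, x + 1L] - 2 * a[z, y, x] + a[z, y, x - 1L]
    )
  }
  out
}

# Recursive-free flood fill over a logical array; returns a list of sorted
# linear-index vectors, one per component, ordered by smallest index.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(offsets$dz) + abs(offsets$dy) + abs(offsets$dx)
  keep <- m > 0 & m <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3)
  offsets <- as.matrix(offsets[keep, ])
  seen <- array(FALSE, d)
  comps <- list()
  for (start in which(mask)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      members <- c(members, v)
      pos <- arrayInd(v, d)
      for (r in seq_len(nrow(offsets))) {
        p <- pos + offsets[r, ]
        if (any(p < 1L) || any(p > d)) next
        lin <- as.integer(p[1L] + d[1L] * ((p[2L] - 1L) + d[2L] * (p[3L] - 1L)))
        if (mask[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  # order components by their lexicographically smallest (z, y, x) voxel
  keys <- vapply(comps, function(m) {
    pos <- arrayInd(m, d)
    o <- order(pos[, 1L], pos[, 2L], pos[, 3L])[1L]
    sum(pos[o, ] * c(1e8, 1e4, 1))
  }, numeric(1))
  comps[order(keys)]
}

# Voxel set of a solid ball of radius R centered on the origin.
rasterize_ball <- function(R) {
  g <- as.matrix(expand.grid(z = -R:R, y = -R:R, x = -R:R))
  g[rowSums(g^2) <= R^2, , drop = FALSE]
}

# Gyration tensor by explicit double loop over coordinate pairs.
oracle_gyration <- function(vox) {
  n <- nrow(vox)
  ctr <- colMeans(vox)
  s <- matrix(0, 3, 3)
  for (m in 1:3) for (q in 1:3) {
    acc <- 0
    for (p in seq_len(n)) acc <- acc + (vox[p, m] - ctr[m]) * (vox[p, q] - ctr[q])
    s[m, q] <- acc / n
  }
  s
}

# --- shared end-to-end run (heavyweight; computed once per test session) ---

.e2e_cache <- new.env(parent = emptyenv())

e2e_scene <- function(seed) {
  sc <- synthetic_scene(seed = seed)
  r <- render_scene(sc)
  res <- restore_volume(r$volume)
  cand <- detect_cells(res$denoised)
  feats <- shape_features(cand)
  list(scene = sc, rendered = r,
       features = label_candidates_by_truth(feats, r$cell_mask))
}

# Trains on two scenes labeled from truth, evaluates detection recall /
# precision and boundary-tolerant validation on 10 held-out scenes.
e2e_suite <- function() {
  if (!is.null(.e2e_cache$result)) return(.e2e_cache$result)
  train <- lapply(c(101, 102), e2e_scene)
  feats <- dplyr::bind_rows(lapply(train, `[[`, "features"))
  sp <- split_labels(feats, 0.8, seed = 42)
  model <- train_classifier(sp$train, sp$test, seed = 42)
  per_scene <- purrr::map_dfr(1:10, function(s) {
    x <- e2e_scene(s)
    r <- x$rendered; f <- x$features
    truth_cells <- r$truth[r$truth$class == "cell", ]
    matched <- integer(0)
    if (any(f$label == "cell")) {
      cc <- as.matrix(f[f$label == "cell", c("z", "y", "x")])
      tc <- as.matrix(truth_cells[, c("z", "y", "x")])
      matched <- unique(apply(cc, 1L, function(p) {
        which.min(colSums((t(tc) - p)^2))
      }))
    }
    any_mask <- r$cell_mask | r$vessel_mask
    intersects <- vapply(f$voxels, function(v) any(any_mask[v]), logical(1))
    pred <- predict(model, f)
    pred_mask <- candidates_to_mask(f[pred == "cell", ], dim(r$cell_mask))
    vr <- core_match_metrics(pred_mask, r$cell_mask,
                             core_radius = 1, band_radius = 1)
    tibble::tibble(
      seed = s, n_cells = nrow(truth_cells), n_matched = length(matched),
      n_candidates = nrow(f), n_intersecting = sum(intersects),
      tp_fraction = vr$tp_fraction, tn_fraction = vr$tn_fraction
    )
  })
  .e2e_cache$result <- list(model = model, per_scene = per_scene)
  .e2e_cache$result
}
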