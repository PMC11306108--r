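# build a candidate-like tibble from explicit voxel matrices
cells_from_voxels <- function(vox_list, spacing = c(3, 3.26, 3.26)) {
  tibble::tibble(
    id = seq_along(vox_list),
    z = vapply(vox_list, function(m) mean(m[, 1]), numeric(1)),
    y = vapply(vox_list, function(m) mean(m[, 2]), numeric(1)),
    x = vapply(vox_list, function(m) mean(m[, 3]), numeric(1)),
    volume_vox = vapply(vox_list, nrow, integer(1)),
    volume_um3 = vapply(vox_list, nrow, integer(1)) * prod(spacing),
    voxels = vox_list
  )
}

# 20-voxel block spanning z and y only (a single fine-x column), so each
# block maps into exactly one coarse voxel along x
block_voxels <- function(z0, y0, x0) {
  as.matrix(expand.grid(z = z0:(z0 + 4L), y = y0:(y0 + 3L), x = x0))
}

test_that("a cell inside one coarse voxel deposits exactly its physical volume there", {
  spacing <- c(3, 3.26, 3.26)
  cells <- cells_from_voxels(list(block_voxels(2L, 2L, 2L)), spacing)
  dm <- density_map(cells, c(40, 40, 40), spacing, 25)
  expect_equal(sum(dm$grid > 0), 1L)
  expect_equal(max(dm$grid), 20 * 3 * 3.26 * 3.26)
  expect_equal(sum(dm$counts), 20L)
})

test_that("empty input gives an all-zero map; totals are conserved for random cells", {
  dm0 <- density_map(cells_from_voxels(list())[0, ], c(30, 30, 30),
                     c(3, 3.26, 3.26), 25)
  expect_true(all(dm0$grid == 0))

  set.seed(51)
  vox_list <- lapply(1:15, function(i) {
    n <- sample(5:60, 1)
    cbind(z = sample(1:50, n, TRUE), y = sample(1:50, n, TRUE),
          x = sample(1:50, n, TRUE))
  })
  cells <- cells_from_voxels(vox_list)
  dm <- density_map(cells, c(50, 50, 50), c(3, 3.26, 3.26), 25)
  expect_equal(sum(dm$grid), sum(cells$volume_um3), tolerance = 1e-12)
  expect_equal(sum(dm$counts), sum(cells$volume_vox))
  expect_error(density_map(cells, c(50, 50, 50), c(3, 3.26, 3.26), -1),
               "positive")
})

five_regions <- c("brainstem", "hippocampus", "hypothalamus", "cortex",
                  "thalamus")

slab_atlas <- function(dims) {
  cuts <- unique(round(seq(1, dims[3] + 1, length.out = 6)))
  boxes <- tibble::tibble(
    label = 1:5, region = five_regions, super_region = five_regions,
    z = 1L, y = 1L, x = as.integer(head(cuts, -1)),
    dz = dims[1], dy = dims[2], dx = as.integer(diff(cuts))
  )
  make_toy_atlas(dims, c(25, 25, 25), boxes)
}

test_that("region assignment reproduces constructed per-box totals and conserves volume", {
  spacing <- c(3, 3.26, 3.26)
  fine_shape <- c(60L, 60L, 60L)
  dims <- dim(density_map(cells_from_voxels(list())[0, ], fine_shape, spacing,
                          25)$grid)
  atlas <- slab_atlas(dims)
  # plant k cells per region at fine-x positions centered in each slab
  k_per_region <- c(2L, 3L, 1L, 4L, 2L)
  vox_list <- list()
  for (rgn in 1:5) {
    xs <- which(atlas$labels[1, 1, ] == rgn)
    fine_x <- round((mean(xs) - 0.5) * 25 / spacing[3])
    for (i in seq_len(k_per_region[rgn])) {
      vox_list[[length(vox_list) + 1L]] <-
        block_voxels(5L + 4L * i, 5L + 4L * i, as.integer(fine_x))
    }
  }
  cells <- cells_from_voxels(vox_list, spacing)
  dm <- density_map(cells, fine_shape, spacing, 25)
  tot <- assign_regions(dm, atlas)
  cell_vol <- 20 * prod(spacing)
  for (rgn in 1:5) {
    expect_equal(tot$volume_um3[tot$region == five_regions[rgn]],
                 k_per_region[rgn] * cell_vol, tolerance = 1e-12)
  }
  expect_equal(sum(tot$volume_um3), sum(dm$grid), tolerance = 1e-12)
  expect_equal(sum(tot$volume_um3), sum(cells$volume_um3), tolerance = 1e-12)
})

test_that("unassigned voxels are kept in their own bucket; label shuffling permutes totals", {
  spacing <- c(3, 3.26, 3.26)
  cells <- cells_from_voxels(list(block_voxels(2L, 2L, 2L)), spacing)
  dims <- dim(density_map(cells, c(40, 40, 40), spacing, 25)$grid)
  rt <- tibble::tibble(label = 1L, region = "cortex", super_region = "cortex")
  labs <- array(0L, dims)  # label 0 everywhere: nothing assigned
  atlas0 <- atlas_volume(labs, c(25, 25, 25), rt)
  dm <- density_map(cells, c(40, 40, 40), spacing, 25)
  tot <- assign_regions(dm, atlas0)
  expect_equal(tot$volume_um3[tot$region == "unassigned"], sum(dm$grid))

  atlas <- slab_atlas(dims)
  base <- assign_regions(dm, atlas)
  # swap two slab labels: totals follow the labels
  perm_labels <- atlas$labels
  perm_labels[atlas$labels == 1L] <- 4L
  perm_labels[atlas$labels == 4L] <- 1L
  atlas_perm <- atlas_volume(perm_labels, c(25, 25, 25), atlas$region_table)
  perm <- assign_regions(dm, atlas_perm)
  get <- function(tbl, rgn) tbl$volume_um3[tbl$region == rgn]
  expect_equal(get(perm, "brainstem"), get(base, "cortex"))
  expect_equal(get(perm, "cortex"), get(base, "brainstem"))

  bad <- atlas_volume(array(0L, dims + 1L), c(25, 25, 25), rt)
  expect_error(assign_regions(dm, bad), "congruent")
})

test_that("centroid mode assigns whole objects and still conserves volume", {
  spacing <- c(3, 3.26, 3.26)
  cells <- cells_from_voxels(list(block_voxels(2L, 2L, 2L),
                                  block_voxels(30L, 30L, 50L)), spacing)
  dm <- density_map(cells, c(60, 60, 60), spacing, 25)
  atlas <- slab_atlas(dim(dm$grid))
  tot <- assign_regions(dm, atlas, method = "centroid", cells = cells)
  expect_equal(sum(tot$volume_um3), sum(cells$volume_um3), tolerance = 1e-12)
})

make_report <- function(values) {
  tabs <- lapply(values, function(v) {
    tibble::tibble(region = c(five_regions, "unassigned"),
                   volume_um3 = c(v, 0))
  })
  names(tabs) <- paste0("s", seq_along(tabs))
  groups <- stats::setNames(rep("g1", length(tabs)), names(tabs))
  do.call(region_report, c(tabs, list(groups = groups)))
}

test_that("region exclusion drops the region, is idempotent and recorded", {
  rep1 <- make_report(list(1:5, 2:6))
  rep1 <- dplyr::bind_rows(rep1, tibble::tibble(
    sample = "s1", group = "g1", region = "cerebellum", volume_um3 = 99
  ))
  class(rep1) <- c("region_report", class(tibble::tibble()))
  attr(rep1, "excluded_regions") <- character()
  ex <- exclude_region(rep1, "cerebellum")
  expect_false("cerebellum" %in% ex$region)
  expect_equal(attr(ex, "excluded_regions"), "cerebellum")
  ex2 <- exclude_region(ex, "cerebellum")
  expect_identical(tibble::as_tibble(ex2), tibble::as_tibble(ex))
  expect_warning(exclude_region(ex, "nonexistent"), "not present")

  all_gone <- ex
  for (r in five_regions) {
    suppressWarnings(all_gone <- exclude_region(all_gone, r))
  }
  expect_true(all(all_gone$region == "unassigned"))
})

test_that("group statistics match direct mean/SD and flag single-sample groups", {
  twin <- make_report(list(c(5, 4, 3, 2, 1), c(5, 4, 3, 2, 1)))
  g <- group_stats(twin)
  expect_true(all(g$sd_volume_um3 == 0))

  ab <- make_report(list(rep(2, 5), rep(8, 5)))
  g2 <- group_stats(ab)
  expect_true(all(g2$mean_volume_um3[g2$region != "unassigned"] == 5))

  set.seed(52)
  vals <- lapply(1:7, function(i) runif(5, 0, 100))
  g3 <- group_stats(make_report(vals))
  m <- do.call(rbind, vals)
  for (j in 1:5) {
    row <- g3[g3$region == five_regions[j], ]
    expect_equal(row$mean_volume_um3, mean(m[, j]))
    expect_equal(row$sd_volume_um3, sd(m[, j]))
  }

  single <- make_report(list(1:5))
  gs <- group_stats(single)
  expect_true(all(gs$single_sample))
  expect_true(all(is.na(gs$sd_volume_um3)))
})

test_that("report totals are invariant to sample and cell order", {
  set.seed(53)
  vox_list <- lapply(1:10, function(i) {
    cbind(z = sample(1:40, 12, TRUE), y = sample(1:40, 12, TRUE),
          x = sample(1:40, 12, TRUE))
  })
  spacing <- c(3, 3.26, 3.26)
  a <- density_map(cells_from_voxels(vox_list, spacing), c(40, 40, 40),
                   spacing, 25)
  b <- density_map(cells_from_voxels(rev(vox_list), spacing), c(40, 40, 40),
                   spacing, 25)
  expect_equal(a$grid, b$grid)
})

test_that("planted per-region density ordering is recovered exactly", {
  spacing <- c(3, 3.26, 3.26)
  fine_shape <- c(60L, 60L, 60L)
  dims <- dim(density_map(cells_from_voxels(list())[0, ], fine_shape, spacing,
                          25)$grid)
  atlas <- slab_atlas(dims)
  # cortex > hippocampus > brainstem > hypothalamus > thalamus
  planted <- c(cortex = 10L, hippocampus = 7L, brainstem = 5L,
               hypothalamus = 3L, thalamus = 1L)
  vox_list <- list()
  for (rgn_name in names(planted)) {
    rgn <- match(rgn_name, five_regions)
    xs <- which(atlas$labels[1, 1, ] == rgn)
    fine_x <- round((mean(xs) - 0.5) * 25 / spacing[3])
    for (i in seq_len(planted[rgn_name])) {
      vox_list[[length(vox_list) + 1L]] <-
        block_voxels(3L + 4L * i, 3L + 4L * i, as.integer(fine_x))
    }
  }
  cells <- cells_from_voxels(vox_list, spacing)
  dm <- density_map(cells, fine_shape, spacing, 25)
  tot <- assign_regions(dm, atlas)
  tot <- tot[tot$region != "unassigned", ]
  ranked <- tot$region[order(tot$volume_um3, decreasing = TRUE)]
  expect_equal(ranked, names(planted))
})
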