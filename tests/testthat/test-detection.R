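test_that("LoG of a quadratic is exact and boundary faces replicate interior values", {
  n <- 7
  ax <- seq_len(n)
  vol <- volume3d(outer(outer(rep(1, n), rep(1, n)), ax^2), c(1, 1, 1))
  il <- log_response(vol)$data
  expect_true(all(abs(il[2:6, 2:6, 2:6] + 2) < 1e-12))
  expect_equal(il[1, , ], il[2, , ])
  expect_equal(il[, n, ], il[, n - 1, ])

  expect_error(log_response(volume3d(array(1, c(2, 5, 5)), c(1, 1, 1))),
               "length >= 3")
})

test_that("LoG matches brute-force central differences on a random fixture", {
  set.seed(31)
  a <- array(runif(125), c(5, 5, 5))
  il <- log_response(volume3d(a, c(1, 1, 1)))$data
  want <- oracle_neg_laplacian_interior(a)
  inter <- 2:4
  expect_identical(il[inter, inter, inter], want[inter, inter, inter])
})

test_that("LoG of a Gaussian blob changes sign on the s*sqrt(3) shell", {
  n <- 64; s <- 4; A <- 5
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  r <- sqrt(r2)
  il <- log_response(volume3d(1 + A * exp(-r2 / (2 * s^2)), c(1, 1, 1)))$data
  edge <- s * sqrt(3)
  shell <- r >= edge - 0.5 & r <= edge + 0.5
  expect_lt(abs(mean(il[shell])), 0.02 * max(abs(il)))
  expect_true(all(il[r < 0.8 * edge] > 0))
  # outside: strictly negative where the response is numerically resolved
  # (beyond ~3.5 s the double-precision response underflows to rounding noise)
  outside <- r > 1.2 * edge & r <= 3 * s
  expect_true(all(il[outside] < 0))
})

test_that("LoG is linear in its input", {
  set.seed(32)
  a <- array(runif(216), c(6, 6, 6))
  b <- array(runif(216), c(6, 6, 6))
  la <- log_response(volume3d(a, c(1, 1, 1)))$data
  lb <- log_response(volume3d(b, c(1, 1, 1)))$data
  lab <- log_response(volume3d(2 * a + 3 * b, c(1, 1, 1)))$data
  expect_equal(lab, 2 * la + 3 * lb, tolerance = 1e-12)
})

test_that("physical spacing mode divides each axis term by its h^2", {
  set.seed(33)
  a <- array(runif(125), c(5, 5, 5))
  iso <- log_response(volume3d(a, c(2, 2, 2)),
                      detection_params(spacing_mode = "physical"))$data
  vox <- log_response(volume3d(a, c(1, 1, 1)))$data
  expect_equal(iso, vox / 4, tolerance = 1e-12)
})

two_blob_volume <- function() {
  n <- 40
  ax <- seq_len(n)
  mk <- function(c0, s) {
    r2 <- outer(outer((ax - c0[1])^2, (ax - c0[2])^2, `+`), (ax - c0[3])^2, `+`)
    exp(-r2 / (2 * s^2))
  }
  volume3d(1 + 5 * mk(c(12, 12, 12), 2) + 5 * mk(c(30, 30, 30), 2), c(1, 1, 1))
}

test_that("candidate extraction matches a flood-fill oracle and thresholds behave", {
  v <- two_blob_volume()
  il <- log_response(v)
  params <- detection_params()
  cand <- extract_candidates(il, v, params)
  expect_equal(nrow(cand), 2L)

  comps <- oracle_flood_fill(il$data > params$alpha, 26)
  comps <- Filter(function(x) length(x) >= params$min_voxels, comps)
  expect_equal(nrow(cand), length(comps))
  got_lin <- lapply(cand$voxels, function(m) {
    as.integer(sort(m[, 1] + dim(v$data)[1] * ((m[, 2] - 1) + dim(v$data)[2] * (m[, 3] - 1))))
  })
  expect_equal(got_lin, comps)

  # alpha above the whole response: nothing detected
  high <- detection_params(alpha = max(il$data) + 1)
  expect_equal(nrow(extract_candidates(il, v, high)), 0L)

  # intensity summaries agree with direct computation on the voxel sets
  vals <- v$data[cand$voxels[[1]]]
  expect_equal(cand$max_Id[1], max(vals))
  expect_equal(cand$mean_Id[1], mean(vals))
  expect_equal(cand$volume_um3, cand$volume_vox * voxel_volume(v))
})

test_that("raising alpha refines the candidate partition", {
  v <- two_blob_volume()
  il <- log_response(v)
  a1 <- extract_candidates(il, v, detection_params(alpha = 1e-3))
  a2 <- extract_candidates(il, v, detection_params(alpha = 5e-2))
  expect_gt(nrow(a2), 0L)
  lin <- function(m, d) m[, 1] + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  d <- dim(v$data)
  sets1 <- lapply(a1$voxels, lin, d = d)
  for (m in a2$voxels) {
    inside <- vapply(sets1, function(s) all(lin(m, d) %in% s), logical(1))
    expect_equal(sum(inside), 1L)
  }
})

test_that("connectivity rule controls component merging", {
  # two voxels touching only at a corner: one object at 26, two at 6
  a <- array(0, c(5, 5, 5))
  a[2, 2, 2] <- 1; a[3, 3, 3] <- 1
  # use the LoG grid directly as a synthetic response field
  lv <- volume3d(a, c(1, 1, 1))
  dv <- volume3d(a + 2, c(1, 1, 1))
  c26 <- extract_candidates(lv, dv, detection_params(alpha = 0.5, min_voxels = 1))
  c6 <- extract_candidates(lv, dv, detection_params(alpha = 0.5, min_voxels = 1,
                                                    connectivity = 6))
  expect_equal(nrow(c26), 1L)
  expect_equal(nrow(c6), 2L)
})

test_that("intensity filter applies I_d,min and keeps a ledger", {
  cand <- tibble::tibble(id = 1:2, max_Id = c(1.05, 1.2))
  kept <- filter_by_intensity(cand, detection_params())
  expect_equal(kept$id, 2L)
  expect_equal(attr(kept, "ledger"), c(n_in = 2L, n_kept = 1L))

  all_kept <- filter_by_intensity(cand, detection_params(i_d_min = 0))
  expect_equal(nrow(all_kept), 2L)

  none <- filter_by_intensity(cand[0, ], detection_params())
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "ledger"), c(n_in = 0L, n_kept = 0L))
})

test_that("detection recovers planted cells with high recall and precision", {
  r <- e2e_suite()$per_scene
  expect_gte(sum(r$n_matched) / sum(r$n_cells), 0.95)
  expect_gte(sum(r$n_intersecting) / sum(r$n_candidates), 0.95)
})
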