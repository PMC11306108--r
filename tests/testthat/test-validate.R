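# a small truth mask with two well-separated solid balls
two_ball_truth <- function(shape = c(24, 24, 24)) {
  truth <- array(FALSE, shape)
  for (ctr in list(c(7, 7, 7), c(17, 17, 17))) {
    ax <- lapply(1:3, function(a) (seq_len(shape[a]) - ctr[a])^2)
    r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    truth <- truth | (r2 <= 3^2)
  }
  truth
}

test_that("perfect prediction scores 100/100; empty prediction 0/100", {
  truth <- two_ball_truth()
  perfect <- core_match_metrics(truth, truth)
  expect_equal(perfect$tp_fraction, 100)
  expect_equal(perfect$tn_fraction, 100)
  expect_equal(perfect$n_true_cells, 2L)

  none <- core_match_metrics(array(FALSE, dim(truth)), truth)
  expect_equal(none$tp_fraction, 0)
  expect_equal(none$tn_fraction, 100)
})

test_that("boundary mismatch is ignored: dilated prediction still scores 100/100", {
  truth <- two_ball_truth()
  dilated <- clearcount:::dilate3d(truth, 1)
  m <- core_match_metrics(dilated, truth, core_radius = 1, band_radius = 1)
  expect_equal(m$tp_fraction, 100)
  expect_equal(m$tn_fraction, 100)
  # with no boundary tolerance the same prediction is penalized on TN
  strict <- core_match_metrics(dilated, truth, core_radius = 1, band_radius = 0)
  expect_lt(strict$tn_fraction, 100)
  expect_error(core_match_metrics(truth[1:10, , ], truth), "shapes|3D")
})

test_that("a core hit credits the whole cell; a boundary-only graze does not", {
  truth <- array(FALSE, c(15, 15, 15))
  ax <- lapply(1:3, function(a) (seq_len(15) - 8)^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  truth <- r2 <= 4^2
  # prediction covering only the center voxel hits the eroded core
  center_only <- array(FALSE, dim(truth)); center_only[8, 8, 8] <- TRUE
  expect_equal(core_match_metrics(center_only, truth)$tp_fraction, 100)
  # prediction touching only a surface voxel misses the core
  surface <- array(FALSE, dim(truth)); surface[8, 8, 12] <- TRUE
  expect_equal(core_match_metrics(surface, truth)$tp_fraction, 0)
})

test_that("tiny components fall back to their deepest voxel", {
  truth <- array(FALSE, c(9, 9, 9))
  truth[4, 4, 4] <- TRUE  # single voxel: erosion by 1 empties it
  hit <- array(FALSE, dim(truth)); hit[4, 4, 4] <- TRUE
  expect_equal(core_match_metrics(hit, truth)$tp_fraction, 100)
  miss <- array(FALSE, dim(truth)); miss[8, 8, 8] <- TRUE
  expect_equal(core_match_metrics(miss, truth)$tp_fraction, 0)
})

test_that("tolerance monotonicity: tp non-increasing in core radius, tn non-decreasing in band radius", {
  truth <- two_ball_truth(c(30, 30, 30))
  # boundary-type errors: predictions are the truth displaced diagonally.
  # A large displacement stops reaching the shrinking core: under the
  # intersects-the-core rule a larger erosion radius only makes matching
  # harder, so tp is monotone non-increasing in core_radius.
  pred_far <- clearcount:::offset_shift(truth, c(3, 3, 0), fill = FALSE)
  tp <- vapply(0:3, function(r) {
    core_match_metrics(pred_far, truth, core_radius = r)$tp_fraction
  }, numeric(1))
  expect_true(all(diff(tp) <= 0))
  expect_lt(tp[4], tp[1])
  # a one-voxel displacement concentrates false positives at cell
  # boundaries; widening the excluded band absorbs them, so tn rises.
  pred_near <- clearcount:::offset_shift(truth, c(1, 1, 0), fill = FALSE)
  tn <- vapply(0:3, function(r) {
    core_match_metrics(pred_near, truth, band_radius = r)$tn_fraction
  }, numeric(1))
  expect_true(all(diff(tn) >= 0))
  expect_equal(tn[4], 100)
})

test_that("convergence series ends at the whole-volume metrics and is flat for perfect prediction", {
  truth <- two_ball_truth()
  rep_perfect <- convergence_series(truth, truth)
  series <- tidy(rep_perfect)
  expect_equal(nrow(series), dim(truth)[1])
  expect_true(all(series$tp_fraction == 100))
  expect_true(all(series$tn_fraction == 100))

  set.seed(62)
  pred <- truth
  pred[sample(which(!truth), 120)] <- TRUE  # scattered false positives
  rep1 <- convergence_series(pred, truth)
  s <- tidy(rep1)
  expect_equal(s$tp_fraction[nrow(s)], rep1$tp_fraction)
  expect_equal(s$tn_fraction[nrow(s)], rep1$tn_fraction)
  # terminal entries have stabilized
  tail5 <- utils::tail(s$tn_fraction, 5)
  expect_true(all(abs(tail5 - s$tn_fraction[nrow(s)]) < 1))
})

test_that("single-slice volumes reduce to 2D metrics", {
  truth <- array(FALSE, c(1, 12, 12))
  truth[1, 5:7, 5:7] <- TRUE
  rep1 <- convergence_series(truth, truth)
  expect_equal(nrow(tidy(rep1)), 1L)
  expect_equal(rep1$tp_fraction, 100)
})

test_that("the full chain on default scenes meets the boundary-tolerant thresholds", {
  r <- e2e_suite()$per_scene
  expect_gte(mean(r$tp_fraction), 95)
  expect_gte(mean(r$tn_fraction), 99)
})
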