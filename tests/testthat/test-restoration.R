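test_that("background kernel is normalized, symmetric and matches direct evaluation", {
  k <- gaussian_kernel(10, 30)
  expect_lt(abs(sum(k) - 1), 1e-12)
  # central symmetry: weight at (i,j,k) equals weight at (-i,-j,-k)
  expect_equal(k, k[61:1, 61:1, 61:1])

  k1 <- gaussian_kernel(1, 1)
  direct <- array(0, c(3, 3, 3))
  for (i in -1:1) for (j in -1:1) for (l in -1:1) {
    direct[i + 2, j + 2, l + 2] <- exp(-(i^2 + j^2 + l^2) / 2)
  }
  expect_equal(k1, direct / sum(direct), tolerance = 1e-15)

  expect_error(gaussian_kernel(0, 3), "positive")
  expect_error(gaussian_kernel(1, 0), ">= 1")
})

test_that("background estimation matches the brute-force cubic convolution", {
  set.seed(21)
  a <- array(runif(343, 10, 100), c(7, 7, 7))
  p <- restoration_params(sigma_bg = 1.5, w = 2)
  got <- estimate_background(volume3d(a, c(1, 1, 1)), p)$data
  want <- oracle_background(a, 1.5, 2, "reflect")
  expect_equal(got, want, tolerance = 1e-10)

  # same equivalence under periodic padding
  pp <- restoration_params(sigma_bg = 1.5, w = 2, padding = "periodic")
  expect_equal(estimate_background(volume3d(a, c(1, 1, 1)), pp)$data,
               oracle_background(a, 1.5, 2, "periodic"), tolerance = 1e-10)
})

test_that("background of a constant volume is that constant; periodic padding conserves the mean", {
  v <- volume3d(array(5.5, c(9, 9, 9)), c(1, 1, 1))
  p <- restoration_params(sigma_bg = 2, w = 4)
  expect_equal(estimate_background(v, p)$data, v$data, tolerance = 1e-12)

  set.seed(3)
  a <- array(runif(8 * 9 * 10), c(8, 9, 10))
  pp <- restoration_params(sigma_bg = 2, w = 4, padding = "periodic")
  bg <- estimate_background(volume3d(a, c(1, 1, 1)), pp)$data
  expect_equal(mean(bg), mean(a), tolerance = 1e-13)
})

test_that("division normalization is exact, floored, and scale invariant", {
  set.seed(4)
  a <- array(runif(5^3, 50, 150), c(5, 5, 5))
  v <- volume3d(a, c(1, 1, 1))
  expect_equal(normalize_volume(v, v)$data, array(1, dim(a)))

  # scale invariance: normalize(c * I) == normalize(I)
  p <- restoration_params(sigma_bg = 1, w = 2)
  i_n1 <- normalize_volume(v, estimate_background(v, p))$data
  v2 <- volume3d(37.5 * a, c(1, 1, 1))
  i_n2 <- normalize_volume(v2, estimate_background(v2, p))$data
  expect_equal(i_n1, i_n2, tolerance = 1e-12)

  # zero background under the floor maps to 1, not NaN
  z <- volume3d(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_warning(bg0 <- estimate_background(z, p), "zero")
  expect_equal(normalize_volume(z, bg0)$data, array(1, c(3, 3, 3)))

  expect_error(
    normalize_volume(v, volume3d(array(1, c(4, 4, 4)), c(1, 1, 1))),
    "shapes"
  )
})

test_that("normalized blob peak matches the analytic Gaussian-convolution value", {
  # one cell, amplitude A on a flat background: applying the background
  # convolution analytically, peak I_n = (1 + A) / (1 + A c) with
  # c = (s^2 / (s^2 + sigma^2))^(3/2)
  sc <- synthetic_scene(
    shape = c(48, 48, 48), n_vessels = 0, noise_sd = 0,
    background = list(level = 100, amplitude = 0),
    cells = tibble::tibble(z = 24, y = 24, x = 24, radius = 4,
                           amplitude = 5),
    seed = 1
  )
  r <- render_scene(sc)
  res <- restore_volume(r$volume, restoration_params(sigma_bg = 10))
  s <- 2; A <- 5
  c_fac <- (s^2 / (s^2 + 10^2))^1.5
  expect_equal(max(res$normalized$data), (1 + A) / (1 + A * c_fac),
               tolerance = 0.02)
})

test_that("denoising matches brute force, preserves constants and scales noise variance by sum(k^2)", {
  set.seed(5)
  a <- array(runif(9^3), c(9, 9, 9))
  p <- restoration_params(sigma_denoise = 1)
  got <- denoise_volume(volume3d(a, c(1, 1, 1)), p)$data
  want <- oracle_background(a, 1, 3, "reflect")
  expect_equal(got, want, tolerance = 1e-10)

  cv <- volume3d(array(2.5, c(6, 6, 6)), c(1, 1, 1))
  expect_equal(denoise_volume(cv, p)$data, cv$data, tolerance = 1e-12)
  p0 <- restoration_params(sigma_denoise = 0)
  expect_identical(denoise_volume(cv, p0)$data, cv$data)

  set.seed(6)
  noise <- array(rnorm(30^3, sd = 2), c(30, 30, 30))
  d <- denoise_volume(volume3d(noise + 10, c(1, 1, 1)), p)$data
  k <- gaussian_kernel(1, 3)
  interior <- d[4:27, 4:27, 4:27]
  expect_equal(var(as.vector(interior)), 4 * sum(k^2), tolerance = 0.1)
})

test_that("background-only scenes normalize flat: median near 1, upper tail under the detection floor", {
  stats <- purrr::map_dfr(1:20, function(s) {
    sc <- synthetic_scene(shape = c(48, 48, 48), n_cells = 0, n_vessels = 0,
                          seed = 400 + s)
    i_n <- restore_volume(render_scene(sc)$volume)$normalized$data
    tibble::tibble(med = median(i_n), p99 = quantile(i_n, 0.99))
  })
  expect_true(all(abs(stats$med - 1) < 0.05))
  expect_true(all(stats$p99 < detection_params()$i_d_min))
})
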