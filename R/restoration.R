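#' Restoration parameters
#'
#' Settings for the image-restoration stage: background estimation by Gaussian
#' smoothing, division normalization, and Gaussian denoising.
#'
#' @param sigma_bg Background Gaussian scale in voxels. Default 10: larger
#'   than a typical cell radius, smaller than the length scale of
#'   autofluorescent background regions.
#' @param w Kernel half-width in voxels (support is a cube of side `2w + 1`).
#'   `NULL` (default) uses `ceiling(3 * sigma_bg)`, which captures > 99.7% of
#'   the Gaussian mass per axis.
#' @param sigma_denoise Denoising Gaussian scale in voxels; 0 disables.
#'   Default 1: suppresses single-voxel digitization noise without blurring
#'   cells of 4-8 voxel diameter.
#' @param padding Boundary rule for convolutions: `"reflect"` (default;
#'   preserves local intensity statistics at the faces so the normalized image
#'   stays near 1 at borders), `"periodic"` or `"replicate"`.
#' @return A list of class `restoration_params`.
#' @export
restoration_params <- function(sigma_bg = 10, w = NULL, sigma_denoise = 1,
                               padding = c("reflect", "periodic", "replicate")) {
  padding <- match.arg(padding)
  if (!is.numeric(sigma_bg) || sigma_bg <= 0) stop("`sigma_bg` must be > 0", call. = FALSE)
  if (is.null(w)) w <- ceiling(3 * sigma_bg)
  if (!is.numeric(w) || w < 1 || w != round(w)) stop("`w` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(sigma_denoise) || sigma_denoise < 0) {
    stop("`sigma_denoise` must be >= 0", call. = FALSE)
  }
  structure(list(sigma_bg = sigma_bg, w = as.integer(w),
                 sigma_denoise = sigma_denoise, padding = padding),
            class = "restoration_params")
}

#' Cube-normalized discrete Gaussian kernel
#'
#' The 3D weight grid used for background estimation: weights proportional to
#' `exp(-(i^2 + j^2 + k^2) / (2 sigma^2))` over `i, j, k` in `[-w, w]`,
#' scaled by the normalization factor so the sum over the cubic support of
#' side `2w + 1` is exactly 1.
#'
#' @param sigma Gaussian scale in voxels, > 0.
#' @param w Half-width; support is `(2w+1)^3`. Integer >= 1.
#' @return A `(2w+1)^3` numeric array summing to 1, centrally symmetric.
#' @export
gaussian_kernel <- function(sigma, w) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w)) {
    stop("`w` must be an integer >= 1", call. = FALSE)
  }
  i <- seq(-w, w)
  g <- exp(-i^2 / (2 * sigma^2))
  k <- outer(outer(g, g), g)  # separable: exp(-(i^2+j^2+k^2)/2s^2)
  k / sum(k)
}

#' Estimate the smooth background field I_sigma
#'
#' Models the background (autofluorescence) intensity as the convolution of
#' the raw data with the cube-normalized Gaussian kernel. Valid when the
#' structures of interest are small compared with the length scale of
#' background intensity variation.
#'
#' @param volume Raw intensity [volume3d] (`I`).
#' @param params A [restoration_params].
#' @return A [volume3d] holding the background field `I_sigma`.
#' @export
estimate_background <- function(volume, params = restoration_params()) {
  stopifnot(inherits(volume, "volume3d"), inherits(params, "restoration_params"))
  if (all(volume$data == 0)) {
    warning("volume is identically zero; downstream division normalization is undefined")
  }
  bg <- gaussian_smooth3d(volume$data, params$sigma_bg, params$w, params$padding)
  with_data(volume, bg, paste0(volume$name, ":I_sigma"))
}

#' Division normalization: I_n = I / I_sigma
#'
#' Removes smooth background undulations by dividing the raw data by the
#' estimated background. Background voxels come out around 1; foreground
#' structures come out much greater than 1. The operation is invariant to any
#' global intensity gain, which is why raw camera counts can be used directly.
#'
#' @param volume Raw [volume3d] (`I`).
#' @param background Background [volume3d] (`I_sigma`), congruent with `volume`.
#' @param floor Division floor: where `I_sigma` falls at or below
#'   `floor * mean(I)` the output is set to 1 (treated as pure background)
#'   to avoid 0/0. Default `1e-12`.
#' @return A [volume3d] holding `I_n`.
#' @export
normalize_volume <- function(volume, background, floor = 1e-12) {
  stopifnot(inherits(volume, "volume3d"), inherits(background, "volume3d"))
  if (!identical(dim(volume$data), dim(background$data))) {
    stop("volume and background shapes differ", call. = FALSE)
  }
  thr <- floor * mean(volume$data)
  ok <- background$data > thr
  out <- array(1, dim(volume$data))
  out[ok] <- volume$data[ok] / background$data[ok]
  with_data(volume, out, paste0(volume$name, ":I_n"))
}

#' Gaussian denoising: I_n to I_d
#'
#' Suppresses camera digitization noise by convolving the normalized image
#' with a Gaussian kernel (same cube-normalized construction as the
#' background kernel, at a much smaller scale).
#'
#' @param volume Normalized [volume3d] (`I_n`).
#' @param params A [restoration_params]; `sigma_denoise = 0` returns the
#'   input unchanged.
#' @return A [volume3d] holding `I_d`.
#' @export
denoise_volume <- function(volume, params = restoration_params()) {
  stopifnot(inherits(volume, "volume3d"), inherits(params, "restoration_params"))
  s <- params$sigma_denoise
  if (s < 0) stop("`sigma_denoise` must be >= 0", call. = FALSE)
  if (s == 0) return(with_data(volume, volume$data, paste0(volume$name, ":I_d")))
  w <- max(1L, as.integer(ceiling(3 * s)))
  out <- gaussian_smooth3d(volume$data, s, w, params$padding)
  with_data(volume, out, paste0(volume$name, ":I_d"))
}

#' Full restoration chain: raw I to I_n and I_d
#'
#' Convenience wrapper running background estimation, division normalization
#' and denoising in sequence.
#'
#' @inheritParams estimate_background
#' @return A list with [volume3d] elements `background`, `normalized`,
#'   `denoised`.
#' @export
restore_volume <- function(volume, params = restoration_params()) {
  bg <- estimate_background(volume, params)
  i_n <- normalize_volume(volume, bg)
  i_d <- denoise_volume(i_n, params)
  list(background = bg, normalized = i_n, denoised = i_d)
}
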