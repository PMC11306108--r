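#' Detection parameters
#'
#' @param alpha LoG threshold: regions with `I_LoG > alpha` become candidate
#'   objects. Dimensionless, `0 < alpha << 1`. Default `1e-3` — well below
#'   the LoG peak of a unit-contrast blob, above the float-level response of
#'   flat fields.
#' @param i_d_min Minimum per-object maximum denoised intensity for a
#'   candidate to be kept (default 1.1; background sits at 1 after division
#'   normalization, true cells sit much higher).
#' @param connectivity Neighborhood rule for connected components: 6, 18 or
#'   26 (default 26; the least fragmenting choice for convex blob interiors).
#' @param min_voxels Minimum object size in voxels (default 2; single voxels
#'   carry an all-zero gyration tensor, hence undefined shape).
#' @param spacing_mode `"voxel"` (default): finite differences use `h = 1`
#'   per axis; `"physical"`: `h` = per-axis voxel spacing in um.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(alpha = 1e-3, i_d_min = 1.1, connectivity = 26,
                             min_voxels = 2, spacing_mode = c("voxel", "physical")) {
  spacing_mode <- match.arg(spacing_mode)
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is.numeric(i_d_min) || i_d_min < 0) stop("`i_d_min` must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  if (!is.numeric(min_voxels) || min_voxels < 1) stop("`min_voxels` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, i_d_min = i_d_min,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 spacing_mode = spacing_mode),
            class = "detection_params")
}

#' Negative-Laplacian (LoG) response of the denoised image
#'
#' `I_LoG = -(d2I/dx2 + d2I/dy2 + d2I/dz2)` approximated by central finite
#' differences. The response is positive inside compact local intensity
#' maxima (cell interiors), negative just outside them, and zero along the
#' edge separating interior from exterior — for a Gaussian blob of scale `s`
#' the zero crossing sits at radius `s * sqrt(3)`. Boundary voxels replicate
#' the nearest interior value so faces cannot produce spurious threshold
#' crossings.
#'
#' @param volume Denoised [volume3d] (`I_d`); every axis must have length >= 3.
#' @param params A [detection_params]; `spacing_mode` selects voxel-unit
#'   (`h = 1`) or physical-spacing finite differences.
#' @return A [volume3d] holding `I_LoG`.
#' @export
log_response <- function(volume, params = detection_params()) {
  stopifnot(inherits(volume, "volume3d"), inherits(params, "detection_params"))
  d <- dim(volume$data)
  if (any(d < 3L)) stop("every axis must have length >= 3 for central differences",
                        call. = FALSE)
  h <- if (params$spacing_mode == "physical") volume$spacing else c(1, 1, 1)
  a <- volume$data
  out <- array(0, d)
  for (axis in 1:3) {
    out <- out + (shift3d(a, axis, 1L) - 2 * a + shift3d(a, axis, -1L)) / h[axis]^2
  }
  out <- -out
  # replicate nearest interior value onto each face (z, then y, then x)
  for (axis in 1:3) {
    n <- d[axis]
    idx_first <- as.list(rep(TRUE, 3L)); idx_first[[axis]] <- 1L
    src_first <- idx_first; src_first[[axis]] <- 2L
    out <- assign_slab(out, idx_first, extract_slab(out, src_first))
    idx_last <- as.list(rep(TRUE, 3L)); idx_last[[axis]] <- n
    src_last <- idx_last; src_last[[axis]] <- n - 1L
    out <- assign_slab(out, idx_last, extract_slab(out, src_last))
  }
  with_data(volume, out, paste0(volume$name, ":I_LoG"))
}

extract_slab <- function(a, idx) a[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
assign_slab <- function(a, idx, value) {
  a[idx[[1L]], idx[[2L]], idx[[3L]]] <- value
  a
}

#' Extract candidate objects from the LoG response
#'
#' Thresholds `I_LoG > alpha` and labels the resulting foreground into
#' connected components; every component of at least `min_voxels` voxels
#' becomes a candidate object, annotated with intensity summaries taken from
#' the denoised image. Object ids are assigned deterministically in
#' lexicographic order of each component's minimum `(z, y, x)` voxel.
#'
#' @param log_volume `I_LoG` [volume3d] from [log_response()].
#' @param denoised `I_d` [volume3d], congruent with `log_volume`.
#' @param params A [detection_params].
#' @return A tibble of candidates with columns `id`, `z`, `y`, `x` (centroid,
#'   voxel coordinates), `volume_vox`, `volume_um3`, `max_Id`, `mean_Id` and a
#'   list-column `voxels` (an `n x 3` integer matrix of `(z, y, x)` indices
#'   per object). Empty tibble when nothing crosses the threshold.
#' @export
extract_candidates <- function(log_volume, denoised, params = detection_params()) {
  stopifnot(inherits(log_volume, "volume3d"), inherits(denoised, "volume3d"),
            inherits(params, "detection_params"))
  if (!identical(dim(log_volume$data), dim(denoised$data))) {
    stop("I_LoG and I_d grids are not congruent", call. = FALSE)
  }
  d <- dim(log_volume$data)
  mask <- log_volume$data > params$alpha
  empty <- candidate_tibble_empty()
  if (!any(mask)) return(empty)

  labels <- cc_label3d(as.logical(mask), as.integer(d), params$connectivity)
  fg <- which(labels > 0L)
  lab <- labels[fg]
  keep_sizes <- tabulate(lab)
  keep_ids <- which(keep_sizes >= params$min_voxels)
  if (!length(keep_ids)) return(empty)
  sel <- lab %in% keep_ids
  fg <- fg[sel]; lab <- lab[sel]

  coords <- arrayInd(fg, d)  # columns z, y, x
  # deterministic ids: rank components by lexicographic minimum (z, y, x)
  ord <- order(coords[, 1L], coords[, 2L], coords[, 3L])
  first <- !duplicated(lab[ord])
  rank_map <- integer(max(keep_ids))
  rank_map[lab[ord][first]] <- seq_len(sum(first))
  new_id <- rank_map[lab]

  vals <- denoised$data[fg]
  n_obj <- max(new_id)
  size <- tabulate(new_id, n_obj)
  cz <- rowsum(coords[, 1L], new_id)[, 1L] / size
  cy <- rowsum(coords[, 2L], new_id)[, 1L] / size
  cx <- rowsum(coords[, 3L], new_id)[, 1L] / size
  sum_id <- rowsum(vals, new_id)[, 1L]
  max_id <- vapply(split(vals, new_id), max, numeric(1))

  o <- order(new_id, coords[, 1L], coords[, 2L], coords[, 3L])
  vox_split <- split.data.frame(coords[o, , drop = FALSE], new_id[o])
  vox_list <- lapply(vox_split, function(m) {
    colnames(m) <- c("z", "y", "x")
    m
  })

  tibble::tibble(
    id = seq_len(n_obj),
    z = cz, y = cy, x = cx,
    volume_vox = as.integer(size),
    volume_um3 = size * voxel_volume(denoised),
    max_Id = unname(max_id),
    mean_Id = unname(sum_id / size),
    voxels = unname(vox_list)
  )
}

candidate_tibble_empty <- function() {
  tibble::tibble(
    id = integer(), z = numeric(), y = numeric(), x = numeric(),
    volume_vox = integer(), volume_um3 = numeric(),
    max_Id = numeric(), mean_Id = numeric(), voxels = list()
  )
}

#' Intensity filter on candidate objects
#'
#' Keeps candidates whose maximum denoised intensity reaches `i_d_min`
#' (default 1.1): true cells are expected to sit well above the background
#' level of 1 after division normalization, so dim LoG artefacts are dropped
#' here. Input order is preserved; a filter ledger with in/out counts is
#' attached as attribute `"ledger"`.
#'
#' @param candidates Candidate tibble from [extract_candidates()].
#' @param params A [detection_params].
#' @return The kept candidates, with a `ledger` attribute
#'   `c(n_in = ..., n_kept = ...)`.
#' @export
filter_by_intensity <- function(candidates, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  if (!"max_Id" %in% names(candidates)) {
    stop("candidates must carry a `max_Id` column", call. = FALSE)
  }
  kept <- dplyr::filter(candidates, .data$max_Id >= params$i_d_min)
  attr(kept, "ledger") <- c(n_in = nrow(candidates), n_kept = nrow(kept))
  kept
}

#' Run detection on a denoised volume
#'
#' Convenience wrapper: LoG response, candidate extraction, intensity filter.
#'
#' @param denoised `I_d` [volume3d].
#' @param params A [detection_params].
#' @return Filtered candidate tibble (see [extract_candidates()]).
#' @export
detect_cells <- function(denoised, params = detection_params()) {
  i_log <- log_response(denoised, params)
  cand <- extract_candidates(i_log, denoised, params)
  filter_by_intensity(cand, params)
}
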