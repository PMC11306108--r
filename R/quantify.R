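# Regional quantification: classified cell voxels -> coarse density map of
# detected-cell volume (default 25 um, the Allen Brain Atlas resolution) ->
# per-super-region totals -> group mean +/- SD.

#' Coarse density map of detected-cell volume
#'
#' Each cell voxel contributes its physical volume (product of the fine
#' spacings) to the coarse voxel containing its center — whole-voxel
#' assignment, so the total is conserved exactly. Internally the map is an
#' integer count grid scaled once by the voxel volume, which keeps the
#' conservation identities exact in floating point.
#'
#' @param cells Candidate tibble of objects classified as cells (needs the
#'   `voxels` list-column).
#' @param fine_shape Fine-grid dimensions `(z, y, x)` in voxels.
#' @param fine_spacing Fine voxel size in um `(z, y, x)`.
#' @param coarse_spacing Coarse cubic voxel side in um (default 25).
#' @return Object of class `density_map`: `grid` (um^3 of cell volume per
#'   coarse voxel), `counts` (fine-voxel counts), `spacing`, `fine_spacing`,
#'   `fine_shape`.
#' @export
density_map <- function(cells, fine_shape, fine_spacing,
                        coarse_spacing = 25) {
  if (any(fine_spacing <= 0) || coarse_spacing <= 0) {
    stop("spacings must be positive", call. = FALSE)
  }
  fine_shape <- as.integer(fine_shape)
  dims <- pmax(1L, as.integer(ceiling(fine_shape * fine_spacing / coarse_spacing)))
  counts <- array(0L, dims)
  if (nrow(cells)) {
    vox <- do.call(rbind, cells$voxels)
    if (any(vox < 1L) || any(sweep(vox, 2L, fine_shape, `>`))) {
      stop("cell voxel coordinates fall outside the fine grid", call. = FALSE)
    }
    ci <- sapply(1:3, function(a) {
      pmin(dims[a], floor((vox[, a] - 0.5) * fine_spacing[a] / coarse_spacing) + 1L)
    })
    lin <- ci[, 1L] + dims[1L] * ((ci[, 2L] - 1L) + dims[2L] * (ci[, 3L] - 1L))
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(as.integer(tab), dims)
  }
  structure(
    list(grid = counts * prod(fine_spacing), counts = counts,
         spacing = rep(coarse_spacing, 3L),
         fine_spacing = as.numeric(fine_spacing), fine_shape = fine_shape),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density_map> %d x %d x %d coarse voxels at %.3g um; total cell volume %.4g um^3\n",
    d[1], d[2], d[3], x$spacing[1], sum(x$grid)
  ))
  invisible(x)
}

#' Assign detected cell volume to atlas super-regions
#'
#' Per-voxel mode (default) adds each coarse voxel's cell volume to the
#' super-region of its atlas label — conserving total volume exactly; label 0
#' (and labels missing from the region table) go to `"unassigned"`. Centroid
#' mode assigns each object's whole volume to the region containing its
#' centroid, for comparison.
#'
#' @param dmap A [density_map()].
#' @param atlas An [atlas_volume] congruent with the coarse grid.
#' @param method `"voxel"` (default) or `"centroid"`.
#' @param cells Candidate tibble (required for centroid mode).
#' @return Tibble `region`, `volume_um3`, one row per super-region present
#'   plus `"unassigned"`.
#' @export
assign_regions <- function(dmap, atlas, method = c("voxel", "centroid"),
                           cells = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dmap, "density_map"), inherits(atlas, "atlas_volume"))
  if (!identical(dim(dmap$grid), dim(atlas$labels))) {
    stop("atlas grid is not congruent with the density-map grid ",
         "(no transform supplied)", call. = FALSE)
  }
  lut <- stats::setNames(atlas$region_table$super_region,
                         as.character(atlas$region_table$label))
  if (method == "voxel") {
    lab <- as.vector(atlas$labels)
    region <- ifelse(lab == 0L, "unassigned",
                     unname(lut[as.character(lab)]))
    region[is.na(region)] <- "unassigned"
    counts <- rowsum(as.vector(dmap$counts), region)
    tot <- counts[, 1L] * prod(dmap$fine_spacing)
  } else {
    if (is.null(cells)) stop("centroid mode needs `cells`", call. = FALSE)
    if (nrow(cells) == 0L) {
      return(tibble::tibble(region = "unassigned", volume_um3 = 0))
    }
    ci <- sapply(1:3, function(a) {
      pmin(dim(atlas$labels)[a],
           pmax(1L, floor((cells[[c("z", "y", "x")[a]]] - 0.5) *
                            dmap$fine_spacing[a] / dmap$spacing[a]) + 1L))
    })
    lab <- atlas$labels[ci]
    region <- ifelse(lab == 0L, "unassigned", unname(lut[as.character(lab)]))
    region[is.na(region)] <- "unassigned"
    counts <- rowsum(cells$volume_vox, region)
    tot <- counts[, 1L] * prod(dmap$fine_spacing)
  }
  out <- tibble::tibble(region = rownames(counts), volume_um3 = unname(tot))
  dplyr::arrange(out, .data$region)
}

#' Build a multi-sample region report
#'
#' Stacks per-sample region totals (from [assign_regions()]) with sample and
#' group identifiers into the long table that group statistics and plots
#' consume.
#'
#' @param ... Named arguments: each name is a sample id, each value the
#'   tibble returned by [assign_regions()].
#' @param groups Named character vector mapping sample id to group.
#' @return Tibble of class `region_report`: `sample`, `group`, `region`,
#'   `volume_um3`, with an `excluded_regions` attribute.
#' @export
region_report <- function(..., groups) {
  samples <- list(...)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("per-sample tables must be named by sample id", call. = FALSE)
  }
  rows <- purrr::imap_dfr(samples, function(tbl, id) {
    dplyr::mutate(tbl, sample = id,
                  group = unname(groups[id]) %||% NA_character_,
                  .before = 1L)
  })
  structure(rows, class = c("region_report", class(rows)),
            excluded_regions = character())
}

#' Exclude a region from the report
#'
#' Drops a region (e.g. the cerebellum, whose Purkinje-cell autofluorescence
#' contaminates detection) from the per-region tables and downstream group
#' statistics, recording the exclusion. Idempotent; excluding an absent
#' region is a warning, not an error. The `"unassigned"` bucket is kept.
#'
#' @param report A [region_report()].
#' @param region_name Super-region name to drop.
#' @return The report without that region; attribute `excluded_regions`
#'   accumulates every exclusion.
#' @export
exclude_region <- function(report, region_name) {
  stopifnot(inherits(report, "region_report"))
  excluded <- attr(report, "excluded_regions")
  if (!region_name %in% report$region && !region_name %in% excluded) {
    warning("region not present: ", region_name)
  }
  out <- report[report$region != region_name, ]
  attr(out, "excluded_regions") <- union(excluded, region_name)
  class(out) <- class(report)
  if (nrow(out) == 0L || all(out$region == "unassigned")) {
    warning("all labeled regions excluded; only the unassigned bucket remains")
  }
  out
}

#' Group mean and SD of regional cell volume
#'
#' Per region and group: mean and sample standard deviation (N - 1
#' denominator, appropriate for the small group sizes typical of whole-brain
#' studies) across samples, with group sizes recorded. Single-sample groups
#' are flagged and get `sd = NA` rather than a fabricated 0.
#'
#' @param report A [region_report()].
#' @return Tibble `group`, `region`, `n_samples`, `mean_volume_um3`,
#'   `sd_volume_um3`, `single_sample`.
#' @export
group_stats <- function(report) {
  stopifnot(inherits(report, "region_report"))
  if (nrow(report) == 0L) stop("empty report", call. = FALSE)
  report |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$group, .data$region) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_volume_um3 = mean(.data$volume_um3),
      sd_volume_um3 = if (dplyr::n() > 1) sd(.data$volume_um3) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(single_sample = .data$n_samples == 1L)
}
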