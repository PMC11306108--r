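#' 3D intensity volume with physical voxel spacing
#'
#' The carrier for raw and derived intensity fields throughout the pipeline
#' (raw `I`, background `I_sigma`, normalized `I_n`, denoised `I_d`, and the
#' Laplacian-of-Gaussian response `I_LoG`). Data are stored as a 3D numeric
#' array in `(z, y, x)` axis order — one z-slice per TIFF page — with the
#' physical voxel size in micrometres per axis, also in `(z, y, x)` order.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`; all values finite.
#' @param spacing Numeric length-3, voxel size in um per axis `(z, y, x)`;
#'   strictly positive. The mesoSPIM acquisitions this models use
#'   `c(3, 3.26, 3.26)`.
#' @param name Free-text provenance label.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), name = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  if (any(dim(data) == 0L)) stop("`data` must have positive extent on every axis", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("`data` must be finite everywhere", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (z, y, x) in um", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, name = as.character(name)[1L]),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume3d> %s: %d x %d x %d voxels (z, y, x), spacing %.3g x %.3g x %.3g um\n",
    x$name, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Physical volume of one voxel in um^3
#' @param volume A [volume3d] or [atlas_volume].
#' @return Scalar, product of the per-axis spacings.
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

# Replace the data array, keeping spacing, with a new provenance label.
with_data <- function(volume, data, name) {
  volume3d(data, spacing = volume$spacing, name = name)
}

#' Read a grayscale multi-page TIFF as a volume
#'
#' Each TIFF page becomes one z-slice. Integer samples are returned as
#' floating-point values *without rescaling* (a 16-bit value of 1234 reads as
#' 1234); float samples are read as stored. Division normalization is
#' scale-invariant, so no intensity normalization is applied on input.
#'
#' @param path Path to a grayscale multi-page TIFF (8/16-bit integer or
#'   32-bit float), one page per z-slice.
#' @param spacing Voxel size in um, `(z, y, x)`. If `NULL`, spacing embedded in
#'   the image description by [write_volume()] is used when present, else
#'   `c(1, 1, 1)` with a warning.
#' @param name Provenance label; defaults to the file name.
#' @return A [volume3d] of shape `(n_pages, height, width)`.
#' @export
read_volume <- function(path, spacing = NULL, name = NULL) {
  if (!file.exists(path)) stop("TIFF file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) {
      if (grepl("as.is", conditionMessage(e), fixed = TRUE)) {
        tiff::readTIFF(path, all = TRUE, info = TRUE)
      } else {
        stop("failed to read TIFF ", path, ": ", conditionMessage(e), call. = FALSE)
      }
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  for (k in seq_along(pages)) {
    if (length(dim(pages[[k]])) > 2L && dim(pages[[k]])[3L] > 1L) {
      stop("page ", k, " of ", path, " is multi-channel/RGB; expected grayscale",
           call. = FALSE)
    }
    if (length(dim(pages[[k]])) > 2L) dim(pages[[k]]) <- dim(pages[[k]])[1:2]
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent page shapes in ", path, ": ",
         paste(unique(shapes), collapse = ", "), call. = FALSE)
  }
  d2 <- dim(pages[[1L]])
  data <- array(0, c(length(pages), d2[1L], d2[2L]))
  for (k in seq_along(pages)) data[k, , ] <- pages[[k]]
  if (is.null(spacing)) {
    spacing <- spacing_from_description(attr(pages[[1L]], "description"))
    if (is.null(spacing)) {
      warning("no voxel spacing supplied or embedded; assuming 1 x 1 x 1 um")
      spacing <- c(1, 1, 1)
    }
  }
  volume3d(data, spacing = spacing, name = name %||% basename(path))
}

spacing_from_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  parsed <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  if (is.list(parsed) && !is.null(parsed$spacing_um) &&
      length(parsed$spacing_um) == 3L) {
    return(as.numeric(parsed$spacing_um))
  }
  NULL
}

#' Write a volume as a float32 multi-page TIFF
#'
#' Writes an uncompressed baseline TIFF, one page per z-slice, 32-bit IEEE
#' float samples, with the voxel spacing recorded as JSON in the
#' ImageDescription tag. Round-trips bitwise for float32 data. (Disk files are
#' float32; in-memory computation is double precision throughout, since the
#' division normalization amplifies quantization error.)
#'
#' @param volume A [volume3d].
#' @param path Output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  d <- dim(volume$data)
  if (any(d == 0L)) stop("cannot write an empty volume", call. = FALSE)
  desc <- jsonlite::toJSON(
    list(spacing_um = volume$spacing, name = volume$name),
    auto_unbox = TRUE, digits = NA
  )
  write_tiff_f32(volume$data, path, as.character(desc))
  invisible(path)
}

# Minimal baseline TIFF writer: little-endian, uncompressed, grayscale,
# 32-bit IEEE-float samples, one strip per page, ImageDescription on page 1.
write_tiff_f32 <- function(data, path, description = "") {
  d <- dim(data)
  nz <- d[1L]; h <- d[2L]; w <- d[3L]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  strip_bytes <- h * w * 4L
  desc_raw <- c(charToRaw(description), as.raw(0L))
  desc_count <- length(desc_raw)  # includes the single terminating NUL
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  header_bytes <- 8L
  strip_offsets <- header_bytes + (seq_len(nz) - 1L) * strip_bytes
  desc_offset <- header_bytes + nz * strip_bytes
  ifd0_offset <- desc_offset + length(desc_raw)
  # entry counts: page 1 carries ImageDescription, later pages do not
  n_entries <- c(11L, rep(10L, max(nz - 1L, 0L)))
  ifd_sizes <- 2L + 12L * n_entries + 4L
  ifd_offsets <- ifd0_offset + cumsum(c(0L, head(ifd_sizes, -1L)))

  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0_offset, con, size = 4, endian = "little")
  for (k in seq_len(nz)) {
    writeBin(as.vector(t(data[k, , ])), con, size = 4, endian = "little")
  }
  writeBin(desc_raw, con)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT packed into the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(nz)) {
    writeBin(n_entries[k], con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)                 # ImageWidth
    entry(257L, 4L, 1L, h)                 # ImageLength
    entry(258L, 3L, 1L, 32L)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    if (k == 1L) entry(270L, 2L, desc_count, desc_offset)  # ImageDescription
    entry(273L, 4L, 1L, strip_offsets[k])  # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, h)                 # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)       # StripByteCounts
    entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
    next_ifd <- if (k < nz) ifd_offsets[k + 1L] else 0L
    writeBin(next_ifd, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a region lookup table
#'
#' Maps integer atlas labels to region and super-region names. Super-regions
#' drive the aggregation in [assign_regions()]; the five used for the
#' whole-brain totals in the study design are brainstem, hippocampus,
#' hypothalamus, cortex and thalamus, but any scheme is accepted.
#'
#' @param path TSV (or CSV) file with columns `label`, `region`,
#'   `super_region` and a header row.
#' @return A tibble with integer `label` (unique), `region`, `super_region`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  region_table(tbl)
}

# Validate a region table (possibly empty).
region_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0L) {
    return(tibble::tibble(label = integer(), region = character(),
                          super_region = character()))
  }
  need <- c("label", "region", "super_region")
  if (!all(need %in% names(tbl))) {
    stop("region table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lab <- tbl$label
  if (any(is.na(suppressWarnings(as.numeric(lab)))) ||
      any(as.numeric(lab) != round(as.numeric(lab)))) {
    stop("region table labels must be integers", call. = FALSE)
  }
  tbl$label <- as.integer(round(as.numeric(lab)))
  if (anyDuplicated(tbl$label)) {
    stop("duplicated labels in region table: ",
         paste(unique(tbl$label[duplicated(tbl$label)]), collapse = ", "),
         call. = FALSE)
  }
  tbl[c("label", "region", "super_region")]
}

#' Atlas label volume with region lookup
#'
#' An integer-labeled 3D grid (0 = unassigned) on a coarse grid — typically
#' the 25 um resolution of the Allen Brain Atlas — plus the region table
#' mapping each nonzero label to a region and super-region. Registration is
#' consumed, not computed: the labels are assumed co-registered with the
#' density-map grid.
#'
#' @param labels 3D integer array, `(z, y, x)`; 0 means unassigned.
#' @param spacing Voxel size in um `(z, y, x)`; default 25 um isotropic.
#' @param region_table Tibble with columns `label`, `region`, `super_region`
#'   covering every nonzero label.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, spacing = c(25, 25, 25), region_table) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (any(labels != round(labels)) || any(labels < 0)) {
    stop("`labels` must be nonnegative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive values", call. = FALSE)
  }
  rt <- region_table(region_table)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, rt$label)
  if (length(missing)) {
    stop("labels missing from region table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(labels = labels, spacing = spacing, region_table = rt),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas_volume> %d x %d x %d voxels at %.3g um, %d labeled regions\n",
              d[1], d[2], d[3], x$spacing[1], nrow(x$region_table)))
  invisible(x)
}

#' Read an atlas label TIFF plus region table
#'
#' @param label_path Multi-page TIFF of integer labels (any grayscale depth).
#' @param region_path TSV with `label`, `region`, `super_region` columns.
#' @param spacing Atlas voxel size in um, default 25 isotropic.
#' @return An [atlas_volume].
#' @export
read_atlas <- function(label_path, region_path, spacing = c(25, 25, 25)) {
  vol <- read_volume(label_path, spacing = spacing)
  labs <- round(vol$data)
  atlas_volume(labs, spacing = spacing,
               region_table = read_region_table(region_path))
}
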