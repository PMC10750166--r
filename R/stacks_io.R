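#' Read an intensity z-stack from a multi-page TIFF
#'
#' Pages become z slices, in file order, giving a `(z, y, x)` array. Voxel
#' sizes are resolved in order of precedence: TIFF resolution tags (when
#' present and plausibly in 0.01–10 µm/pixel), then the `metadata` argument,
#' then a YAML sidecar file (`<stem>.yml`/`.yaml` next to the TIFF) with keys
#' `pixel_size_xy_um`, `z_step_um` and optional `channel`.
#'
#' Intensities written by [write_stack()] round-trip bit-exactly for
#' integer-valued data; floating-point data round-trips to 32-bit float
#' precision (the sidecar records the normalisation constant).
#'
#' @param path Path to a single-channel multi-page grayscale TIFF.
#' @param metadata Optional [image_metadata()] (or list with the same fields).
#' @param channel_index For multi-channel pages, which channel to extract;
#'   multi-channel input without a selector is an error.
#' @return A [voxel_grid()].
#' @seealso [write_stack()], [read_labels()]
#' @export
read_stack <- function(path, metadata = NULL, channel_index = NULL) {
  pages <- read_tiff_pages(path, channel_index)
  meta <- resolve_metadata(path, metadata)
  arr <- stack_pages(pages$pages)
  if (!is.null(meta$intensity_max) && is.double(arr))
    arr <- arr * meta$intensity_max
  if (is.integer(arr)) arr <- arr + 0  # grids carry doubles; values stay exact
  voxel_grid(arr, meta$pixel_size_xy_um, meta$z_step_um)
}

#' Write an intensity z-stack to a multi-page TIFF with a metadata sidecar
#'
#' Integer-valued data (up to 65535) is stored as 16-bit pages and
#' round-trips exactly; other data is stored as 32-bit float, normalised to
#' `[0, 1]` with the scale recorded in the sidecar. A YAML sidecar
#' `<stem>.yml` always records `pixel_size_xy_um`, `z_step_um` and `channel`.
#'
#' @param grid A [voxel_grid()].
#' @param path Output TIFF path.
#' @param channel Channel name recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, channel = "DAPI") {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- grid$data
  integerish <- all(arr == round(arr)) && max(arr) <= 65535
  sidecar <- list(pixel_size_xy_um = grid$pixel_size_xy_um,
                  z_step_um = grid$z_step_um,
                  channel = channel)
  if (integerish) {
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    mx <- max(arr)
    if (mx <= 0) mx <- 1
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    sidecar$intensity_max <- mx
  }
  yaml::write_yaml(sidecar, sidecar_path(path))
  invisible(path)
}

#' Read / write instance label volumes as integer TIFFs
#'
#' Labels are stored as 16-bit pages (ids up to 65535) and round-trip
#' losslessly, preserving non-consecutive ids. A float-valued TIFF is accepted
#' only when its content is exactly integer; negative values are rejected.
#'
#' @param path TIFF path.
#' @return `read_labels()` returns a [label_volume()]; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path) {
  pages <- read_tiff_pages(path, channel_index = NULL)$pages
  arr <- stack_pages(pages)
  if (is.double(arr)) {
    # float TIFF: tiff stores [0,1]; undo the 16-bit style scaling if present
    scaled <- arr * 65535
    if (max(abs(scaled - round(scaled))) < 1e-6) arr <- round(scaled)
    else if (all(arr == round(arr))) arr <- arr
    else stop("label TIFF has non-integer content", call. = FALSE)
  }
  label_volume(arr)
}

#' @rdname read_labels
#' @param lv A [label_volume()].
#' @export
write_labels <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  arr <- lv$labels
  if (max(arr) > 65535)
    stop("label ids above 65535 cannot be stored as 16-bit TIFF", call. = FALSE)
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yml")

# list of (y, x) page matrices -> (z, y, x) array; robust to a single page
stack_pages <- function(pages) {
  d <- dim(pages[[1]])
  arr <- array(if (is.integer(pages[[1]])) NA_integer_ else NA_real_,
               c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

read_tiff_pages <- function(path, channel_index) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample
  pages2 <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (is.null(channel_index))
        stop("multi-channel TIFF pages require `channel_index`", call. = FALSE)
      p <- p[, , channel_index]
    }
    # readTIFF scales integer samples to [0, 1]; undo exactly for 8/16-bit
    if (!is.null(bits) && bits <= 16L) {
      q <- round(p * (2^bits - 1))
      storage.mode(q) <- "integer"
      q
    } else p
  })
  list(pages = pages2, info = info)
}

# Precedence: plausible TIFF resolution tags > explicit metadata > sidecar.
resolve_metadata <- function(path, metadata) {
  side <- NULL
  for (cand in c(sidecar_path(path), paste0(tools::file_path_sans_ext(path), ".yaml"))) {
    if (file.exists(cand)) { side <- yaml::read_yaml(cand); break }
  }
  tag <- tiff_tag_pixel_size(path)
  meta <- if (!is.null(metadata)) {
    list(pixel_size_xy_um = metadata$pixel_size_xy_um,
         z_step_um = metadata$z_step_um,
         channel = if (!is.null(metadata$channel)) metadata$channel else "unknown")
  } else side
  if (is.null(meta))
    stop("no voxel-size metadata: pass `metadata` or provide a sidecar .yml", call. = FALSE)
  if (!is.null(tag)) meta$pixel_size_xy_um <- tag
  if (is.null(meta$pixel_size_xy_um) || is.null(meta$z_step_um) ||
      !is.numeric(meta$pixel_size_xy_um) || !is.numeric(meta$z_step_um) ||
      meta$pixel_size_xy_um <= 0 || meta$z_step_um <= 0)
    stop("metadata must provide positive pixel_size_xy_um and z_step_um", call. = FALSE)
  if (!is.null(side) && !is.null(side$intensity_max))
    meta$intensity_max <- side$intensity_max
  meta
}

tiff_tag_pixel_size <- function(path) {
  info <- attributes(suppressWarnings(tiff::readTIFF(path, info = TRUE, as.is = TRUE)))
  xr <- info$x.resolution
  yr <- info$y.resolution
  if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
  if (!is.null(yr) && is.finite(yr) && abs(yr - xr) > 1e-6 * xr)
    stop("non-square xy pixels in TIFF resolution tags are not supported", call. = FALSE)
  unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
  um_per_px <- switch(unit,
                      cm = 1e4 / xr,
                      inch = 25400 / xr,
                      1 / xr)  # unitless: assume pixels per micrometre
  if (um_per_px >= 0.01 && um_per_px <= 10) um_per_px else NULL
}
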