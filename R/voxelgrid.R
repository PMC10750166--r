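#' Intensity z-stack with physical voxel sizes
#'
#' A `voxel_grid` is the pipeline's carrier: a 3D intensity array in `(z, y, x)`
#' axis order together with the physical sampling of the microscope — the
#' lateral pixel size (assumed square in x and y) and the z-step between focal
#' planes, both in micrometres.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`. Values must be finite
#'   and nonnegative. A 2D matrix is promoted to a single-slice stack.
#' @param pixel_size_xy_um Lateral pixel size in µm/pixel (x and y equal).
#' @param z_step_um Distance between consecutive z slices in µm.
#'
#' @return An object of class `voxel_grid` with elements `data`,
#'   `pixel_size_xy_um`, `z_step_um`.
#' @examples
#' g <- voxel_grid(array(0, c(5, 32, 32)), pixel_size_xy_um = 0.117, z_step_um = 0.3)
#' dim(g)
#' @export
voxel_grid <- function(data, pixel_size_xy_um, z_step_um) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  if (any(data < 0)) stop("intensities must be nonnegative", call. = FALSE)
  check_positive_scalar(pixel_size_xy_um, "pixel_size_xy_um")
  check_positive_scalar(z_step_um, "z_step_um")
  structure(
    list(data = data,
         pixel_size_xy_um = as.numeric(pixel_size_xy_um),
         z_step_um = as.numeric(z_step_um)),
    class = "voxel_grid"
  )
}

#' Instance label volume
#'
#' Nonnegative-integer labels aligned voxel-for-voxel with a companion
#' [voxel_grid()]: 0 is background, each positive id `k` marks the voxels of
#' nucleus instance `k`. Ids need not be consecutive, but each id names a
#' single instance.
#'
#' @param labels 3D integer array in `(z, y, x)` order (a matrix is promoted
#'   to one slice). Negative or non-integer values are rejected.
#' @return An object of class `label_volume` wrapping the integer array.
#' @examples
#' lv <- label_volume(array(0L, c(3, 8, 8)))
#' n_instances(lv)
#' @export
label_volume <- function(labels) {
  if (is.matrix(labels)) labels <- array(labels, c(1L, nrow(labels), ncol(labels)))
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array in (z, y, x) order", call. = FALSE)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("labels must be integer-valued", call. = FALSE)
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("labels must be integer", call. = FALSE)
  if (any(labels < 0L)) stop("labels must be nonnegative", call. = FALSE)
  structure(list(labels = labels), class = "label_volume")
}

#' Image acquisition metadata
#'
#' @param pixel_size_xy_um Lateral pixel size in µm/pixel.
#' @param z_step_um Z-step in µm.
#' @param channel Free-text channel name, e.g. `"DAPI"`.
#' @return An object of class `image_metadata`.
#' @export
image_metadata <- function(pixel_size_xy_um, z_step_um, channel = "DAPI") {
  check_positive_scalar(pixel_size_xy_um, "pixel_size_xy_um")
  check_positive_scalar(z_step_um, "z_step_um")
  structure(
    list(pixel_size_xy_um = as.numeric(pixel_size_xy_um),
         z_step_um = as.numeric(z_step_um),
         channel = as.character(channel)),
    class = "image_metadata"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Instance ids present in a label volume
#' @param lv A [label_volume()].
#' @return Sorted integer vector of positive instance ids.
#' @export
instance_ids <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  ids <- sort(unique(as.vector(lv$labels)))
  ids[ids > 0L]
}

#' Number of instances in a label volume
#' @param lv A [label_volume()].
#' @return Integer count of distinct positive labels.
#' @export
n_instances <- function(lv) length(instance_ids(lv))

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), %.4g um/px xy, %.4g um z-step\n",
              d[1], d[2], d[3], x$pixel_size_xy_um, x$z_step_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), %d instance(s)\n",
              d[1], d[2], d[3], n_instances(x)))
  invisible(x)
}

#' @export
print.image_metadata <- function(x, ...) {
  cat(sprintf("<image_metadata> %.4g um/px xy, %.4g um z-step, channel '%s'\n",
              x$pixel_size_xy_um, x$z_step_um, x$channel))
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  invisible(TRUE)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes must have identical (z, y, x) shapes", call. = FALSE)
  invisible(TRUE)
}
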