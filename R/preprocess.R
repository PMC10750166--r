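#' Lateral scale factor converting a nucleus to a 30-pixel diameter
#'
#' Cellpose-style models expect objects of about 30 px diameter, so stacks are
#' rescaled laterally such that a nucleus of `diameter_um` spans 30 pixels:
#' `s = 30 * pixel_size_xy_um / diameter_um`. After rescaling the pixel size is
#' `diameter_um / 30` (0.1167 µm for the default 3.5 µm nucleus).
#'
#' @param pixel_size_xy_um Lateral pixel size of the input, µm/pixel.
#' @param diameter_um Expected nucleus diameter in µm (default 3.5).
#' @return Scale factor `s > 0`; multiply lateral dimensions by `s`.
#' @examples
#' compute_scale_factor(0.117, 3.5)  # ~1.003: AiryScan data is nearly at target
#' @export
compute_scale_factor <- function(pixel_size_xy_um, diameter_um = 3.5) {
  check_positive_scalar(pixel_size_xy_um, "pixel_size_xy_um")
  check_positive_scalar(diameter_um, "diameter_um")
  TARGET_DIAMETER_PX * pixel_size_xy_um / diameter_um
}

TARGET_DIAMETER_PX <- 30

#' Resample a stack laterally by a scale factor
#'
#' Each z slice is resampled by `s` in y and x with bilinear interpolation
#' (labels are never passed through this path); z is untouched and the pixel
#' size is divided by `s`, so the lateral physical extent is preserved to
#' within one output pixel.
#'
#' @param grid A [voxel_grid()].
#' @param s Positive lateral scale factor, e.g. from [compute_scale_factor()].
#' @return A [voxel_grid()] with dimensions `(z, round(y*s), round(x*s))`.
#' @export
rescale_xy <- function(grid, s) {
  stopifnot(inherits(grid, "voxel_grid"))
  check_positive_scalar(s, "s")
  d <- dim(grid$data)
  if (s == 1) return(grid)
  ny <- as.integer(round(d[2] * s)); nx <- as.integer(round(d[3] * s))
  if (ny < 4L || nx < 4L)
    stop("rescaled lateral dimension would be below 4 px", call. = FALSE)
  out <- array(0, c(d[1], ny, nx))
  for (z in seq_len(d[1]))
    out[z, , ] <- resample2d(grid$data[z, , ], ny, nx, method = "linear")
  voxel_grid(pmax(out, 0), grid$pixel_size_xy_um / s, grid$z_step_um)
}

#' Axial anisotropy of a (rescaled) stack
#'
#' The ratio of the z sampling interval to the lateral pixel size; > 1 means
#' z is coarser than xy. Forwarded to 3D segmentation backends.
#'
#' @param z_step_um Z-step in µm.
#' @param rescaled_pixel_size_um Lateral pixel size after rescaling, µm/pixel.
#' @return `z_step_um / rescaled_pixel_size_um`.
#' @export
compute_anisotropy <- function(z_step_um, rescaled_pixel_size_um) {
  check_positive_scalar(z_step_um, "z_step_um")
  check_positive_scalar(rescaled_pixel_size_um, "rescaled_pixel_size_um")
  z_step_um / rescaled_pixel_size_um
}

#' Physically isotropic Gaussian blur of a stack
#'
#' Smooths with standard deviation `blurfactor` pixels laterally and
#' `blurfactor / anisotropy` slices axially, so the blur is (approximately)
#' isotropic in physical units. Reflective boundaries; `blurfactor = 0` is the
#' identity. The default 2.5 suits chromatin (DAPI) staining; 3.5 is
#' recommended for deconvolved or synaptonemal-complex images.
#'
#' @param grid A [voxel_grid()].
#' @param blurfactor Gaussian standard deviation in (rescaled) pixels, >= 0.
#' @param anisotropy Axial/lateral sampling ratio, from [compute_anisotropy()].
#' @return Blurred [voxel_grid()] with unchanged geometry.
#' @export
gaussian_blur <- function(grid, blurfactor = 2.5, anisotropy = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(blurfactor) || blurfactor < 0)
    stop("`blurfactor` must be >= 0", call. = FALSE)
  check_positive_scalar(anisotropy, "anisotropy")
  if (blurfactor == 0) return(grid)
  out <- blur_volume(grid$data, sigma_z = blurfactor / anisotropy,
                     sigma_y = blurfactor, sigma_x = blurfactor)
  voxel_grid(pmax(out, 0), grid$pixel_size_xy_um, grid$z_step_um)
}

# ---- internals -------------------------------------------------------------

# Reflective-boundary normalised Gaussian convolution matrix (n x n).
# Row i holds the kernel centred at i with out-of-range taps folded back
# (reflect-101), so constants are preserved exactly.
gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    j <- reflect_index(j, n)
    for (t in seq_along(j)) W[i, j[t]] <- W[i, j[t]] + k[t]
  }
  W
}

reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  period <- 2L * (n - 1L)
  j0 <- (j - 1L) %% period
  j0 <- ifelse(j0 >= n, period - j0, j0)
  j0 + 1L
}

# Separable 3D Gaussian on a (z, y, x) array; any sigma below ~1e-8 skips
# that axis. Implemented as banded-matrix multiplications per axis.
blur_volume <- function(arr, sigma_z, sigma_y, sigma_x) {
  d <- dim(arr)
  if (sigma_z > 1e-8 && d[1] > 1L) {
    W <- gauss_conv_matrix(d[1], sigma_z)
    arr <- array(W %*% matrix(arr, d[1], d[2] * d[3]), d)
  }
  if (sigma_y > 1e-8 && d[2] > 1L) {
    a <- aperm(arr, c(2L, 1L, 3L))
    W <- gauss_conv_matrix(d[2], sigma_y)
    a <- array(W %*% matrix(a, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2L, 1L, 3L))
  }
  if (sigma_x > 1e-8 && d[3] > 1L) {
    a <- aperm(arr, c(3L, 1L, 2L))
    W <- gauss_conv_matrix(d[3], sigma_x)
    a <- array(W %*% matrix(a, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    arr <- aperm(a, c(2L, 3L, 1L))
  }
  arr
}

# 2D resampling with pixel-centre alignment: output index i maps to source
# coordinate (i + 0.5) * n_src / n_out - 0.5, clamped. Linear for
# intensities, nearest for labels.
resample2d <- function(img, ny, nx, method = c("linear", "nearest")) {
  method <- match.arg(method)
  ys <- axis_map(ny, nrow(img))
  xs <- axis_map(nx, ncol(img))
  if (method == "nearest") {
    img[pmin(pmax(round(ys) + 1, 1), nrow(img)),
        pmin(pmax(round(xs) + 1, 1), ncol(img)), drop = FALSE]
  } else {
    tmp <- interp_axis_rows(img, ys)        # rows -> ny x ncol
    t(interp_axis_rows(t(tmp), xs))         # cols -> ny x nx
  }
}

axis_map <- function(n_out, n_src) (seq_len(n_out) - 0.5) * n_src / n_out - 0.5

# Linear interpolation of matrix rows at fractional 0-based coordinates.
interp_axis_rows <- function(img, coords) {
  n <- nrow(img)
  if (n == 1L) return(img[rep(1L, length(coords)), , drop = FALSE])
  c0 <- pmin(pmax(coords, 0), n - 1)
  lo <- pmin(floor(c0), n - 2); lo <- pmax(lo, 0)
  w <- c0 - lo
  img[lo + 1, , drop = FALSE] * (1 - w) + img[lo + 2, , drop = FALSE] * w
}

# 1D resampling of the z axis of a 2D (z, lateral) view.
resample_rows_1d <- function(mat, n_out, method = c("linear", "nearest")) {
  method <- match.arg(method)
  coords <- axis_map(n_out, nrow(mat))
  if (method == "nearest") {
    mat[pmin(pmax(round(coords) + 1, 1), nrow(mat)), , drop = FALSE]
  } else if (nrow(mat) == 1L) {
    mat[rep(1L, n_out), , drop = FALSE]
  } else {
    interp_axis_rows(mat, coords)
  }
}
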