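#' Extract a 2D orthogonal view (image + mask) from a stack
#'
#' Annotating 2D orthogonal views (xy, xz, yz) instead of whole stacks is how
#' the ground truth for germline nuclei is produced. An `xy` view is the z
#' slice passed through unchanged. `xz`/`yz` views are resampled along z by
#' the anisotropy factor (`z_step / pixel_size_xy`; linear for intensity,
#' nearest-neighbour for labels) so the view is isotropic at the lateral
#' pixel size.
#'
#' @param grid A [voxel_grid()].
#' @param labels Optional companion [label_volume()].
#' @param orientation One of `"xy"`, `"xz"`, `"yz"`.
#' @param index 1-based slice index along the complementary axis (z for xy,
#'   y for xz, x for yz).
#' @param source_id Provenance string recorded on the view.
#' @return An object of class `ortho_view`: `image` (2D matrix), `mask`
#'   (2D integer matrix or NULL), `orientation`, `source_id`,
#'   `pixel_size_um`.
#' @export
extract_ortho_view <- function(grid, labels = NULL,
                               orientation = c("xy", "xz", "yz"),
                               index = 1L, source_id = "") {
  stopifnot(inherits(grid, "voxel_grid"))
  orientation <- match.arg(orientation)
  d <- dim(grid$data)
  axis_len <- switch(orientation, xy = d[1], xz = d[2], yz = d[3])
  if (index < 1L || index > axis_len)
    stop(sprintf("index %d out of range for %s view (axis length %d)",
                 index, orientation, axis_len), call. = FALSE)
  lab_arr <- if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_volume"))
    check_same_shape(labels$labels, grid$data)
    labels$labels
  } else NULL

  if (orientation == "xy") {
    img <- grid$data[index, , ]
    msk <- if (!is.null(lab_arr)) lab_arr[index, , ] else NULL
  } else {
    sl <- if (orientation == "xz") grid$data[, index, ] else grid$data[, , index]
    msl <- if (!is.null(lab_arr)) {
      if (orientation == "xz") lab_arr[, index, ] else lab_arr[, , index]
    } else NULL
    a <- compute_anisotropy(grid$z_step_um, grid$pixel_size_xy_um)
    nz <- as.integer(round((d[1] - 1L) * a)) + 1L
    img <- resample_rows_1d(sl, nz, "linear")
    msk <- if (!is.null(msl)) resample_rows_1d(msl, nz, "nearest") else NULL
  }
  structure(list(image = img, mask = msk, orientation = orientation,
                 source_id = source_id,
                 pixel_size_um = grid$pixel_size_xy_um),
            class = "ortho_view")
}

#' Random train/test split
#'
#' Reproducible partition of items into a training and a test set, the way a
#' 120-view ground-truth collection is split 108/12 at `test_fraction = 0.1`.
#'
#' @param items Vector or list to split (length >= 2).
#' @param test_fraction Fraction assigned to the test set, in (0, 1); the
#'   test size is `round(test_fraction * N)`.
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return List with `train` and `test`, a disjoint exhaustive partition.
#' @export
split_train_test <- function(items, test_fraction = 0.1, seed = 1L) {
  n <- length(items)
  if (n < 2L) stop("need at least 2 items to split", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  n_test <- max(1L, as.integer(round(test_fraction * n)))
  withr_seed(seed, {
    test_idx <- sort(sample.int(n, n_test))
    list(train = items[setdiff(seq_len(n), test_idx)],
         test = items[test_idx])
  })
}

#' Augmentation protocol specification
#'
#' The stochastic transforms applied to paired (image, mask) training views:
#' random mirroring (horizontal and/or vertical), random rotations in
#' 0–90 degrees, additive noise, intensity rescaling, and blurring with a
#' blur factor in 0–3.5. Geometric transforms are applied identically to
#' image and mask; photometric ones to the image only.
#'
#' @param p_flip_h,p_flip_v Flip probabilities in `[0, 1]`.
#' @param rotation_range_deg Rotation range, within `[0, 90]` degrees.
#' @param noise_sigma_range Additive Gaussian noise sigma range, relative to
#'   the image's standard deviation.
#' @param intensity_rescale_range Multiplicative intensity factor range.
#' @param blur_range Gaussian blur-factor range, within `[0, 3.5]`.
#' @param n_augment_per_image Augmented variants emitted per original view.
#' @param seed Base RNG seed for the whole augmentation run.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(p_flip_h = 0.5, p_flip_v = 0.5,
                              rotation_range_deg = c(0, 90),
                              noise_sigma_range = c(0, 0.1),
                              intensity_rescale_range = c(0.8, 1.2),
                              blur_range = c(0, 3.5),
                              n_augment_per_image = 2L,
                              seed = 1L) {
  stopifnot(p_flip_h >= 0, p_flip_h <= 1, p_flip_v >= 0, p_flip_v <= 1,
            length(rotation_range_deg) == 2L,
            rotation_range_deg[1] >= 0, rotation_range_deg[2] <= 90,
            rotation_range_deg[1] <= rotation_range_deg[2],
            length(noise_sigma_range) == 2L, all(noise_sigma_range >= 0),
            length(intensity_rescale_range) == 2L,
            all(intensity_rescale_range > 0),
            length(blur_range) == 2L, blur_range[1] >= 0, blur_range[2] <= 3.5,
            blur_range[1] <= blur_range[2],
            n_augment_per_image >= 0)
  structure(as.list(environment()), class = "augmentation_spec")
}

#' Apply one random augmentation to a paired view
#'
#' Samples transform parameters from `spec` and applies them: flips and
#' rotation identically to image and mask (image bilinear, mask
#' nearest-neighbour, reflective fill, shape preserved), then noise,
#' intensity rescaling (with min-max renormalisation) and blur to the image
#' only. Mask ids never change; tiny mask fragments created at rotated edges
#' (< 9 px) are dropped.
#'
#' @param view An [extract_ortho_view()] result (mask may be NULL).
#' @param spec An [augmentation_spec()].
#' @param seed RNG seed for this draw.
#' @return An `ortho_view` with attribute `"params"` recording every sampled
#'   transform parameter.
#' @export
augment_pair <- function(view, spec, seed = 1L) {
  stopifnot(inherits(view, "ortho_view"), inherits(spec, "augmentation_spec"))
  withr_seed(seed, {
    params <- list(
      flip_h = stats::runif(1) < spec$p_flip_h,
      flip_v = stats::runif(1) < spec$p_flip_v,
      rotation_deg = stats::runif(1, spec$rotation_range_deg[1],
                                  spec$rotation_range_deg[2]),
      noise_sigma = stats::runif(1, spec$noise_sigma_range[1],
                                 spec$noise_sigma_range[2]),
      intensity_factor = stats::runif(1, spec$intensity_rescale_range[1],
                                      spec$intensity_rescale_range[2]),
      blurfactor = stats::runif(1, spec$blur_range[1], spec$blur_range[2]))
    img <- view$image
    msk <- view$mask
    if (params$flip_h) { img <- img[, rev(seq_len(ncol(img)))]
                         if (!is.null(msk)) msk <- msk[, rev(seq_len(ncol(msk)))] }
    if (params$flip_v) { img <- img[rev(seq_len(nrow(img))), ]
                         if (!is.null(msk)) msk <- msk[rev(seq_len(nrow(msk))), ] }
    if (params$rotation_deg > 0) {
      img <- rotate2d(img, params$rotation_deg, "linear")
      if (!is.null(msk)) {
        msk <- rotate2d(msk, params$rotation_deg, "nearest")
        msk <- drop_tiny_fragments(msk, min_px = 9L)
      }
    }
    if (params$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, params$noise_sigma * stats::sd(img))
    if (params$intensity_factor != 1) {
      img <- img * params$intensity_factor
      rng <- range(img)
      if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
    }
    if (params$blurfactor > 0) {
      img <- blur_volume(array(img, c(1L, nrow(img), ncol(img))),
                         0, params$blurfactor, params$blurfactor)[1, , ]
    }
    img <- pmax(img, 0)
    out <- view
    out$image <- img
    out$mask <- if (!is.null(msk)) msk else NULL
    attr(out, "params") <- params
    out
  })
}

#' Build an augmented training set with a reproducible manifest
#'
#' Emits each view plus `spec$n_augment_per_image` augmented variants as
#' paired TIFFs following the Cellpose training-folder convention
#' (`<id>_img.tif` / `<id>_masks.tif`) and writes `manifest.csv` recording
#' every sampled transform parameter, plus `training_config.yml` with the
#' frozen network-training hyperparameters ([training_config_record()]) for
#' provenance. Per-view RNG substreams are derived from `(seed, view index)`,
#' so the output is reproducible and independent of processing order.
#'
#' @param views Nonempty list of `ortho_view` objects (with masks).
#' @param spec An [augmentation_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (columns: file stem,
#'   orientation, source, variant, and all transform parameters).
#' @export
build_training_set <- function(views, spec, out_dir) {
  stopifnot(length(views) > 0, inherits(spec, "augmentation_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(views)) {
    v <- views[[i]]
    stopifnot(inherits(v, "ortho_view"))
    for (k in 0:spec$n_augment_per_image) {
      sub_seed <- (as.integer(spec$seed) * 10007L + i * 101L + k) %% .Machine$integer.max
      out <- if (k == 0L) v else augment_pair(v, spec, seed = sub_seed)
      stem <- sprintf("view%03d_aug%02d", i, k)
      write_view_pair(out, file.path(out_dir, stem))
      p <- attr(out, "params")
      rows[[length(rows) + 1L]] <- data.frame(
        stem = stem, orientation = v$orientation,
        source_id = v$source_id, variant = k, seed = if (k == 0L) NA else sub_seed,
        flip_h = if (k == 0L) FALSE else p$flip_h,
        flip_v = if (k == 0L) FALSE else p$flip_v,
        rotation_deg = if (k == 0L) 0 else p$rotation_deg,
        noise_sigma = if (k == 0L) 0 else p$noise_sigma,
        intensity_factor = if (k == 0L) 1 else p$intensity_factor,
        blurfactor = if (k == 0L) 0 else p$blurfactor)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(training_config_record(),
                   file.path(out_dir, "training_config.yml"))
  invisible(manifest)
}

#' Frozen network-training hyperparameters (provenance record)
#'
#' The hyperparameters used to retrain the nucleus model, recorded for
#' provenance only — this package prepares training data but never executes
#' network training.
#'
#' @return Named list: `n_epochs = 500`, `momentum = 0.9`,
#'   `weight_decay = 1e-5`, `learning_rate = 0.05`, `min_train_masks = 2`,
#'   `normalize = TRUE`, `rescale = TRUE`.
#' @export
training_config_record <- function() {
  list(n_epochs = 500L, momentum = 0.9, weight_decay = 1e-05,
       learning_rate = 0.05, min_train_masks = 2L,
       normalize = TRUE, rescale = TRUE)
}

# ---- internals -------------------------------------------------------------

# Shape-preserving rotation about the image centre with reflective fill.
rotate2d <- function(img, angle_deg, method = c("linear", "nearest")) {
  method <- match.arg(method)
  th <- angle_deg * pi / 180
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  gy <- rep(seq_len(ny), times = nx) - cy
  gx <- rep(seq_len(nx), each = ny) - cx
  # inverse map: rotate output coordinates by -angle
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  if (method == "nearest") {
    iy <- reflect_index(as.integer(round(sy)), ny)
    ix <- reflect_index(as.integer(round(sx)), nx)
    matrix(img[cbind(iy, ix)], ny, nx)
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    wy <- sy - y0; wx <- sx - x0
    iy0 <- reflect_index(as.integer(y0), ny); iy1 <- reflect_index(as.integer(y0) + 1L, ny)
    ix0 <- reflect_index(as.integer(x0), nx); ix1 <- reflect_index(as.integer(x0) + 1L, nx)
    v <- img[cbind(iy0, ix0)] * (1 - wy) * (1 - wx) +
         img[cbind(iy1, ix0)] * wy * (1 - wx) +
         img[cbind(iy0, ix1)] * (1 - wy) * wx +
         img[cbind(iy1, ix1)] * wy * wx
    matrix(v, ny, nx)
  }
}

drop_tiny_fragments <- function(msk, min_px = 9L) {
  counts <- table(msk[msk > 0])
  tiny <- as.integer(names(counts)[counts < min_px])
  if (length(tiny)) msk[msk %in% tiny] <- 0L
  msk
}

write_view_pair <- function(view, stem) {
  img <- view$image
  mx <- max(img)
  tiff::writeTIFF(if (mx > 0) img / mx else img, paste0(stem, "_img.tif"),
                  bits.per.sample = 32L, compression = "none")
  if (!is.null(view$mask)) {
    tiff::writeTIFF(view$mask / 65535, paste0(stem, "_masks.tif"),
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(stem)
}
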