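#' Specification of a synthetic germline-like scene
#'
#' Describes a ground-truthed synthetic z-stack emulating the distal
#' C. elegans germline: densely packed round nuclei of about 3.5 µm whose
#' chromatin staining is discontinuous (partially condensed, paired
#' chromosomes), sampled on an anisotropic voxel grid with PSF-like blur and
#' shot/read noise.
#'
#' Defaults reflect the acquisition regime of the real data: 0.117 µm lateral
#' pixels, 0.3 µm z-step (anisotropy ~2.6), 3.5 µm mean nucleus diameter.
#'
#' @param volume_shape_vox Integer `(Z, Y, X)` volume shape.
#' @param pixel_size_xy_um,z_step_um Voxel sizes in µm.
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param diameter_mean_um,diameter_sd_um Nucleus diameter distribution, µm.
#' @param min_gap_um Minimum surface-to-surface gap between nuclei, µm.
#' @param chromatin_n_blobs Number of bright chromatin blobs per nucleus.
#' @param chromatin_blob_diameter_um Diameter of each chromatin blob, µm.
#' @param interior_intensity Diffuse nucleoplasm level inside a nucleus
#'   (chromatin blobs reach 1.0).
#' @param psf_sigma_um Isotropic Gaussian PSF sigma in µm (0 disables).
#' @param noise_gaussian_sd Additive read-noise sd (intensity units).
#' @param noise_poisson_scale Photon scale for shot noise (0 disables);
#'   larger means less noise.
#' @param background_level Constant background intensity.
#' @param seed RNG seed making the scene fully reproducible.
#' @return An object of class `synthetic_scene_spec`.
#' @export
synthetic_scene_spec <- function(volume_shape_vox = c(64L, 256L, 256L),
                                 pixel_size_xy_um = 0.117,
                                 z_step_um = 0.3,
                                 n_nuclei = 20L,
                                 diameter_mean_um = 3.5,
                                 diameter_sd_um = 0.25,
                                 min_gap_um = 0.25,
                                 chromatin_n_blobs = 25L,
                                 chromatin_blob_diameter_um = 0.9,
                                 interior_intensity = 0.45,
                                 psf_sigma_um = 0.15,
                                 noise_gaussian_sd = 0.02,
                                 noise_poisson_scale = 400,
                                 background_level = 0.08,
                                 seed = 1L) {
  stopifnot(length(volume_shape_vox) == 3L, all(volume_shape_vox >= 1))
  check_positive_scalar(pixel_size_xy_um, "pixel_size_xy_um")
  check_positive_scalar(z_step_um, "z_step_um")
  stopifnot(n_nuclei >= 0, diameter_mean_um > 0, diameter_sd_um >= 0,
            min_gap_um >= 0, chromatin_n_blobs >= 1,
            chromatin_blob_diameter_um > 0, psf_sigma_um >= 0,
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0,
            background_level >= 0)
  structure(as.list(environment()), class = "synthetic_scene_spec")
}

#' Generate a ground-truthed synthetic germline scene
#'
#' Places `n_nuclei` spheres by dart-throwing with a hard-core exclusion rule
#' (surface gap >= `min_gap_um`), fully inside the volume. Ground-truth labels
#' are the full spheres rasterised on the anisotropic voxel grid — the way an
#' annotator outlines whole nuclei, not the sparse chromatin texture. The
#' intensity image is the union of random chromatin blobs inside each sphere
#' over a diffuse nucleoplasm level, convolved with an anisotropic Gaussian
#' PSF, plus background, Poisson shot noise and Gaussian read noise.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [synthetic_scene_spec()].
#' @return List with elements `grid` ([voxel_grid()]), `labels`
#'   ([label_volume()]), `metadata` ([image_metadata()]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_scene_spec"))
  d <- as.integer(spec$volume_shape_vox)
  withr_seed(spec$seed, {
    ext <- c(d[1] * spec$z_step_um, d[2] * spec$pixel_size_xy_um,
             d[3] * spec$pixel_size_xy_um)
    nuclei <- place_nuclei(spec, ext)
    labels <- array(0L, d)
    clean <- array(0, d)
    zc <- (seq_len(d[1]) - 0.5) * spec$z_step_um
    yc <- (seq_len(d[2]) - 0.5) * spec$pixel_size_xy_um
    xc <- (seq_len(d[3]) - 0.5) * spec$pixel_size_xy_um
    for (k in seq_len(nrow(nuclei))) {
      ctr <- nuclei[k, 1:3]
      r <- nuclei[k, 4]
      zi <- which(abs(zc - ctr[1]) <= r)
      yi <- which(abs(yc - ctr[2]) <= r)
      xi <- which(abs(xc - ctr[3]) <= r)
      if (!length(zi) || !length(yi) || !length(xi)) next
      dz2 <- (zc[zi] - ctr[1])^2
      dy2 <- (yc[yi] - ctr[2])^2
      dx2 <- (xc[xi] - ctr[3])^2
      D2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
      inside <- D2 <= r^2
      sub <- labels[zi, yi, xi, drop = FALSE]
      sub[inside] <- k
      labels[zi, yi, xi] <- sub
      csub <- clean[zi, yi, xi, drop = FALSE]
      csub[inside] <- pmax(csub[inside], spec$interior_intensity)
      # discontinuous chromatin: bright blobs at random positions in the sphere
      rb <- spec$chromatin_blob_diameter_um / 2
      for (b in seq_len(spec$chromatin_n_blobs)) {
        bc <- random_point_in_sphere(ctr, max(r - rb, r * 0.3))
        bz <- abs(zc[zi] - bc[1]); by <- abs(yc[yi] - bc[2]); bx <- abs(xc[xi] - bc[3])
        B2 <- outer(outer(bz^2, by^2, `+`), bx^2, `+`)
        csub[B2 <= rb^2 & inside] <- 1
      }
      clean[zi, yi, xi] <- csub
    }
    if (spec$psf_sigma_um > 0) {
      clean <- blur_volume(clean,
                           sigma_z = spec$psf_sigma_um / spec$z_step_um,
                           sigma_y = spec$psf_sigma_um / spec$pixel_size_xy_um,
                           sigma_x = spec$psf_sigma_um / spec$pixel_size_xy_um)
    }
    img <- clean + spec$background_level
    if (spec$noise_poisson_scale > 0)
      img <- stats::rpois(length(img), img * spec$noise_poisson_scale) /
        spec$noise_poisson_scale
    if (spec$noise_gaussian_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_gaussian_sd)
    img <- array(pmax(img, 0), d)
    list(grid = voxel_grid(img, spec$pixel_size_xy_um, spec$z_step_um),
         labels = label_volume(labels),
         metadata = image_metadata(spec$pixel_size_xy_um, spec$z_step_um,
                                   channel = "synthetic-DAPI"))
  })
}

#' Corrupt a label volume with known, countable errors
#'
#' Produces a "prediction" whose match statistics against the original are
#' exactly computable: `drop_k` instances are deleted (false negatives) and
#' `split_k` instances are bisected through their centroid into two new ids,
#' emulating the fragmentation failure mode of generic segmentation models on
#' germline nuclei. Each fragment covers at most half of the parent, so at
#' IoU threshold 0.5 a split yields one FN and two FPs (for an odd voxel
#' count the single rank-median voxel is removed so neither fragment can
#' exceed half).
#'
#' @param lv A [label_volume()].
#' @param drop_k,split_k Numbers of instances to drop / split; their sum must
#'   not exceed the instance count.
#' @param seed RNG seed selecting which instances are affected.
#' @return A corrupted [label_volume()].
#' @export
corrupt_labels <- function(lv, drop_k = 0, split_k = 0, seed = 1L) {
  stopifnot(inherits(lv, "label_volume"))
  ids <- instance_ids(lv)
  if (drop_k + split_k > length(ids))
    stop("drop_k + split_k exceeds the number of instances", call. = FALSE)
  arr <- lv$labels
  withr_seed(seed, {
    pick <- if (length(ids)) sample(ids, drop_k + split_k) else integer()
    drop_ids <- utils::head(pick, drop_k)
    split_ids <- utils::tail(pick, split_k)
    if (length(drop_ids)) arr[arr %in% drop_ids] <- 0L
    next_id <- max(arr) + 1L
    for (id in split_ids) {
      idx <- which(arr == id)
      cc <- arrayInd(idx, dim(arr))
      ax <- which.max(apply(cc, 2, function(v) diff(range(v))))
      o <- order(cc[, ax], cc[, 1], cc[, 2], cc[, 3])
      n <- length(idx)
      half <- n %/% 2L
      arr[idx] <- 0L
      arr[idx[o[seq_len(half)]]] <- next_id
      # odd count: skip the median voxel so both fragments are <= n/2
      arr[idx[o[(n - half + 1L):n]]] <- next_id + 1L
      next_id <- next_id + 2L
    }
  })
  label_volume(arr)
}

# ---- internals -------------------------------------------------------------

place_nuclei <- function(spec, ext) {
  n <- spec$n_nuclei
  out <- matrix(numeric(0), 0, 4)
  if (n == 0) return(out)
  cap <- 2000L * n
  tries <- 0L
  while (nrow(out) < n && tries < cap) {
    tries <- tries + 1L
    r <- stats::rnorm(1, spec$diameter_mean_um / 2, spec$diameter_sd_um / 2)
    r <- min(max(r, 0.6 * spec$diameter_mean_um / 2), 1.4 * spec$diameter_mean_um / 2)
    if (any(2 * r >= ext)) next
    ctr <- stats::runif(3, min = r, max = ext - r)
    ok <- TRUE
    if (nrow(out)) {
      dd <- sqrt(colSums((t(out[, 1:3, drop = FALSE]) - ctr)^2))
      ok <- all(dd >= out[, 4] + r + spec$min_gap_um)
    }
    if (ok) out <- rbind(out, c(ctr, r))
  }
  if (nrow(out) < n)
    stop(sprintf(paste0("could not place %d nuclei of ~%.2g um in a %.3g x %.3g x ",
                        "%.3g um volume (packing too dense)"),
                 n, spec$diameter_mean_um, ext[1], ext[2], ext[3]), call. = FALSE)
  out
}

random_point_in_sphere <- function(center, radius) {
  repeat {
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) <= 1) return(center + p * radius)
  }
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
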