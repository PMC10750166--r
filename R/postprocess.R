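#' Remove instances touching the stack borders
#'
#' Deletes every instance that has a voxel on the first or last z slice, or
#' within 2 pixels of the lateral edges of the stack (0-based index `< 2` or
#' `>= dim - 2` in x or y). Incomplete nuclei cut by the imaging volume are
#' removed this way before quantification. Surviving instances keep their ids
#' and voxels untouched; the operation is idempotent.
#'
#' @param lv A [label_volume()].
#' @return A [label_volume()] containing only interior instances.
#' @export
clean_borders <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  arr <- lv$labels
  d <- dim(arr)
  border <- array(FALSE, d)
  border[c(1L, d[1]), , ] <- TRUE
  if (d[2] >= 1L) border[, unique(pmin(pmax(c(1:2, d[2] - 1L, d[2]), 1L), d[2])), ] <- TRUE
  if (d[3] >= 1L) border[, , unique(pmin(pmax(c(1:2, d[3] - 1L, d[3]), 1L), d[3]))] <- TRUE
  bad <- unique(arr[border])
  bad <- bad[bad > 0L]
  if (length(bad)) arr[arr %in% bad] <- 0L
  label_volume(arr)
}

#' Shape/size filter criteria for segmented instances
#'
#' All criteria are optional (`NULL` disables one). An instance is kept only
#' if it satisfies every active criterion. Measurements are defined in
#' [measure_instances()].
#'
#' @param min_size_vox,max_size_vox Bounds on voxel count.
#' @param min_solidity Lower bound on voxel count / convex-hull voxel count.
#' @param max_elongation Upper bound on the major/minor principal-axis ratio
#'   (computed in physical units, so anisotropy does not read as shape).
#' @param min_z_thickness Lower bound on the number of distinct z slices the
#'   instance occupies.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_size_vox = NULL, max_size_vox = NULL,
                            min_solidity = NULL, max_elongation = NULL,
                            min_z_thickness = NULL) {
  crit <- list(min_size_vox = min_size_vox, max_size_vox = max_size_vox,
               min_solidity = min_solidity, max_elongation = max_elongation,
               min_z_thickness = min_z_thickness)
  for (nm in names(crit)) {
    v <- crit[[nm]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v < 0))
      stop(sprintf("`%s` must be NULL or a single nonnegative number", nm), call. = FALSE)
  }
  if (!is.null(crit$min_size_vox) && !is.null(crit$max_size_vox) &&
      crit$min_size_vox > crit$max_size_vox)
    stop("min_size_vox must not exceed max_size_vox", call. = FALSE)
  structure(crit, class = "filter_criteria")
}

#' Per-instance 3D shape measurements
#'
#' For each instance: `size_vox` (voxel count); `solidity` (voxel count
#' divided by the number of lattice voxels inside the instance's 3D convex
#' hull); `elongation` (ratio of largest to smallest principal-axis length
#' from the voxel covariance in physical µm, with the voxel's own second
#' moment added so flat instances stay finite); `z_thickness` (distinct z
#' slices occupied). A single-voxel instance has solidity 1 and elongation 1
#' by convention.
#'
#' @param lv A [label_volume()].
#' @param pixel_size_xy_um,z_step_um Physical voxel sizes used for elongation;
#'   defaults of 1 measure in voxel units.
#' @return A data.frame with one row per instance: `label`, `size_vox`,
#'   `solidity`, `elongation`, `z_thickness`.
#' @export
measure_instances <- function(lv, pixel_size_xy_um = 1, z_step_um = 1) {
  stopifnot(inherits(lv, "label_volume"))
  ids <- instance_ids(lv)
  if (!length(ids))
    return(data.frame(label = integer(), size_vox = integer(), solidity = numeric(),
                      elongation = numeric(), z_thickness = integer()))
  coords <- instance_coords(lv)
  res <- lapply(ids, function(id) {
    cc <- coords[[as.character(id)]]
    n <- nrow(cc)
    zt <- length(unique(cc[, 1]))
    if (n == 1L) {
      return(data.frame(label = id, size_vox = 1L, solidity = 1,
                        elongation = 1, z_thickness = 1L))
    }
    sol <- n / convex_hull_voxel_count(cc)
    el <- elongation_physical(cc, pixel_size_xy_um, z_step_um)
    data.frame(label = id, size_vox = n, solidity = sol,
               elongation = el, z_thickness = zt)
  })
  do.call(rbind, res)
}

#' Filter instances by size and shape
#'
#' Applies a [filter_criteria()] to a label volume: instances failing any
#' active criterion are deleted; survivors keep their ids and voxels exactly.
#' Empty criteria return the input unchanged.
#'
#' @param lv A [label_volume()].
#' @param criteria A [filter_criteria()].
#' @param pixel_size_xy_um,z_step_um Physical voxel sizes (elongation only).
#' @return Filtered [label_volume()].
#' @export
filter_masks <- function(lv, criteria = filter_criteria(),
                         pixel_size_xy_um = 1, z_step_um = 1) {
  stopifnot(inherits(lv, "label_volume"), inherits(criteria, "filter_criteria"))
  if (all(vapply(criteria, is.null, logical(1)))) return(lv)
  m <- measure_instances(lv, pixel_size_xy_um, z_step_um)
  if (!nrow(m)) return(lv)
  keep <- rep(TRUE, nrow(m))
  if (!is.null(criteria$min_size_vox))   keep <- keep & m$size_vox >= criteria$min_size_vox
  if (!is.null(criteria$max_size_vox))   keep <- keep & m$size_vox <= criteria$max_size_vox
  if (!is.null(criteria$min_solidity))   keep <- keep & m$solidity >= criteria$min_solidity
  if (!is.null(criteria$max_elongation)) keep <- keep & m$elongation <= criteria$max_elongation
  if (!is.null(criteria$min_z_thickness)) keep <- keep & m$z_thickness >= criteria$min_z_thickness
  bad <- m$label[!keep]
  arr <- lv$labels
  if (length(bad)) arr[arr %in% bad] <- 0L
  label_volume(arr)
}

# ---- internals -------------------------------------------------------------

# list of per-instance coordinate matrices (z, y, x), 1-based, named by id
instance_coords <- function(lv) {
  arr <- lv$labels
  idx <- which(arr > 0L)
  if (!length(idx)) return(list())
  d <- dim(arr)
  z <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  y <- rest %% d[2] + 1L
  x <- rest %/% d[2] + 1L
  split.data.frame(cbind(z = z, y = y, x = x), arr[idx])
}

elongation_physical <- function(cc, px, zs) {
  P <- cbind(cc[, 1] * zs, cc[, 2] * px, cc[, 3] * px)
  S <- stats::cov(P) * (nrow(P) - 1) / nrow(P)
  # add the second moment of a single voxel so degenerate instances are finite
  S <- S + diag(c(zs^2, px^2, px^2)) / 12
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), .Machine$double.eps))
}

# Exact count of lattice voxels inside the 3D convex hull of integer points.
# Plane sweep over z: the hull's cross-section at integer z = t is the 2D
# convex hull of all segment interpolations between candidate hull vertices
# below and above t. Candidate vertices are the per-slice 2D hull vertices,
# a superset of the true 3D hull vertices.
convex_hull_voxel_count <- function(cc) {
  n <- nrow(cc)
  if (n <= 2L) return(n)
  zs <- sort(unique(cc[, 1]))
  verts <- do.call(rbind, lapply(zs, function(t) {
    P <- cc[cc[, 1] == t, 2:3, drop = FALSE]
    P <- unique(P)
    if (nrow(P) >= 3L) {
      h <- grDevices::chull(P[, 1], P[, 2])
      if (length(h) >= 3L) P <- P[h, , drop = FALSE]
    }
    cbind(t, P)
  }))
  total <- 0L
  for (t in min(zs):max(zs)) {
    A <- verts[verts[, 1] <= t, , drop = FALSE]
    B <- verts[verts[, 1] >= t, , drop = FALSE]
    # all A-B segment intersections with plane z = t
    ia <- rep(seq_len(nrow(A)), times = nrow(B))
    ib <- rep(seq_len(nrow(B)), each = nrow(A))
    za <- A[ia, 1]; zb <- B[ib, 1]
    lam <- ifelse(zb == za, 0, (t - za) / (zb - za))
    py <- A[ia, 2] + lam * (B[ib, 2] - A[ia, 2])
    px <- A[ia, 3] + lam * (B[ib, 3] - A[ia, 3])
    total <- total + count_lattice_in_polygon(py, px)
  }
  total
}

# Count integer (y, x) lattice points inside the convex hull of a point set.
count_lattice_in_polygon <- function(py, px, eps = 1e-9) {
  P <- unique(cbind(py, px))
  if (nrow(P) == 1L) {
    return(as.integer(abs(P[1, 1] - round(P[1, 1])) < eps &&
                      abs(P[1, 2] - round(P[1, 2])) < eps))
  }
  if (nrow(P) == 2L || length(grDevices::chull(P[, 1], P[, 2])) < 3L) {
    # collinear: count lattice points on the segment's bounding trace
    return(count_lattice_on_segments(P, eps))
  }
  h <- grDevices::chull(P[, 1], P[, 2])
  H <- P[h, , drop = FALSE]
  m <- nrow(H)
  # orientation from the signed area, so the half-plane test is sign-correct
  jn <- c(2:m, 1L)
  area2 <- sum(H[, 1] * H[jn, 2] - H[jn, 1] * H[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  ys <- seq.int(ceiling(min(H[, 1]) - eps), floor(max(H[, 1]) + eps))
  xs <- seq.int(ceiling(min(H[, 2]) - eps), floor(max(H[, 2]) + eps))
  if (!length(ys) || !length(xs)) return(0L)
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  inside <- rep(TRUE, length(gy))
  for (i in seq_len(m)) {
    j <- jn[i]
    cr <- sgn * ((H[j, 1] - H[i, 1]) * (gx - H[i, 2]) -
                 (H[j, 2] - H[i, 2]) * (gy - H[i, 1]))
    inside <- inside & (cr >= -eps)
    if (!any(inside)) return(0L)
  }
  sum(inside)
}

count_lattice_on_segments <- function(P, eps) {
  # degenerate (collinear) cross-section: count integer points on the hullline
  o <- order(P[, 1], P[, 2])
  a <- P[o[1], ]; b <- P[o[nrow(P)], ]
  d <- b - a
  len2 <- sum(d^2)
  ys <- seq.int(ceiling(min(P[, 1]) - eps), floor(max(P[, 1]) + eps))
  xs <- seq.int(ceiling(min(P[, 2]) - eps), floor(max(P[, 2]) + eps))
  if (!length(ys) || !length(xs)) return(0L)
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  if (len2 < eps) {
    return(sum(abs(gy - a[1]) < eps & abs(gx - a[2]) < eps))
  }
  tpar <- ((gy - a[1]) * d[1] + (gx - a[2]) * d[2]) / len2
  projy <- a[1] + tpar * d[1]
  projx <- a[2] + tpar * d[2]
  on_line <- abs(projy - gy) < 1e-6 & abs(projx - gx) < 1e-6 &
    tpar >= -eps & tpar <= 1 + eps
  sum(on_line)
}
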