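# Fixtures are built in code; nothing is stored on disk.

# Digital ball: voxels whose centre lies within `radius` (voxel units,
# optionally anisotropic in z) of `center` (z, y, x), labelled `id`.
make_ball <- function(dims, center, radius, id = 1L, z_scale = 1) {
  arr <- array(0L, dims)
  z <- slice.index(arr, 1); y <- slice.index(arr, 2); x <- slice.index(arr, 3)
  d2 <- ((z - center[1]) * z_scale)^2 + (y - center[2])^2 + (x - center[3])^2
  arr[d2 <= radius^2] <- as.integer(id)
  arr
}

# Axis-aligned box instance [z1:z2, y1:y2, x1:x2]
make_box <- function(dims, z, y, x, id = 1L) {
  arr <- array(0L, dims)
  arr[z[1]:z[2], y[1]:y[2], x[1]:x[2]] <- as.integer(id)
  arr
}

# Exhaustive maximum-cardinality matching oracle: enumerate every one-to-one
# assignment of gt rows to pred cols over the admissible pairs (IoU strictly
# above threshold) and return the best cardinality. Independent of the
# package's augmenting-path implementation.
oracle_max_matching <- function(iou, threshold) {
  admissible <- iou > threshold
  n_gt <- nrow(iou); n_pred <- ncol(iou)
  best <- 0L
  recurse <- function(row, used_cols, count) {
    if (count + (n_gt - row + 1L) <= best) return()  # bound
    if (row > n_gt) { best <<- max(best, count); return() }
    recurse(row + 1L, used_cols, count)  # leave this gt unmatched
    for (col in seq_len(n_pred)) {
      if (!used_cols[col] && admissible[row, col]) {
        used_cols[col] <- TRUE
        recurse(row + 1L, used_cols, count + 1L)
        used_cols[col] <- FALSE
      }
    }
  }
  if (n_gt > 0L && n_pred > 0L) recurse(1L, rep(FALSE, n_pred), 0L)
  best
}

# Random small label volume with n instances (disjoint random boxes)
random_label_volume <- function(dims, n, seed) {
  set.seed(seed)
  arr <- array(0L, dims)
  for (id in seq_len(n)) {
    sz <- pmin(sample(2:4, 3, replace = TRUE), dims)
    lo <- mapply(function(d, s) sample.int(d - s + 1L, 1L), dims, sz)
    arr[lo[1]:(lo[1] + sz[1] - 1L),
        lo[2]:(lo[2] + sz[2] - 1L),
        lo[3]:(lo[3] + sz[3] - 1L)] <- id
  }
  label_volume(arr)
}

# Relabel a volume's ids by a random permutation (bijection on positive ids)
permute_labels <- function(lv, seed) {
  ids <- instance_ids(lv)
  set.seed(seed)
  new_ids <- sample(ids)
  arr <- lv$labels
  out <- arr
  for (i in seq_along(ids)) out[arr == ids[i]] <- new_ids[i]
  label_volume(out)
}

# python + scipy oracle for lattice points inside a 3D convex hull; returns
# NA if the interpreter is unavailable (tests then fall back to analytics)
scipy_hull_voxel_count <- function(cc) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NA_integer_)
  f <- tempfile(fileext = ".csv")
  utils::write.table(cc, f, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- paste(
    "import sys, numpy as np",
    "from scipy.spatial import Delaunay",
    "pts = np.loadtxt(sys.argv[1], delimiter=',')",
    "lo = pts.min(0).astype(int); hi = pts.max(0).astype(int)",
    "gz, gy, gx = np.mgrid[lo[0]:hi[0]+1, lo[1]:hi[1]+1, lo[2]:hi[2]+1]",
    "grid = np.stack([gz.ravel(), gy.ravel(), gx.ravel()], 1)",
    "tri = Delaunay(pts)",
    "print(int((tri.find_simplex(grid) >= 0).sum()))",
    sep = "\n")
  out <- tryCatch(system2(py, c("-c", shQuote(script), f), stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NA_character_, warning = function(w) NA_character_)
  if (length(out) != 1L || is.na(out)) return(NA_integer_)
  as.integer(out)
}
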