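#' Request object for a 3D segmentation backend
#'
#' Bundles a preprocessed stack (rescaled so nuclei span about 30 px,
#' optionally blurred) with the parameters every backend receives: the axial
#' anisotropy and the cell-probability threshold.
#'
#' @param grid Preprocessed [voxel_grid()].
#' @param anisotropy Axial/lateral sampling ratio ([compute_anisotropy()]).
#' @param cellprob_threshold Scalar threshold on the backend's object
#'   likelihood; default 0.0, the operating point used for germline nuclei.
#' @return An object of class `backend_request`.
#' @export
backend_request <- function(grid, anisotropy, cellprob_threshold = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  check_positive_scalar(anisotropy, "anisotropy")
  if (!is.numeric(cellprob_threshold) || length(cellprob_threshold) != 1L)
    stop("`cellprob_threshold` must be a single number", call. = FALSE)
  structure(list(grid = grid, anisotropy = anisotropy,
                 cellprob_threshold = cellprob_threshold),
            class = "backend_request")
}

#' Run a 3D instance-segmentation backend
#'
#' Dispatches a [backend_request()] to a named backend. `"baseline"` is the
#' built-in classical detector ([baseline_segment()]); `"cellpose_germlineNuclei"`
#' forwards to the retrained Cellpose model through [cellpose_adapter()] and
#' requires the optional Python dependency. A function may be passed directly
#' for custom backends (it receives the request and must return a
#' [label_volume()] of the same shape).
#'
#' @param request A [backend_request()].
#' @param backend `"baseline"`, `"cellpose_germlineNuclei"`, or a function.
#' @param ... Passed to the backend (e.g. `model_path` for the adapter).
#' @return A [label_volume()] with the same `(z, y, x)` shape as the input;
#'   instances are 6-connected and non-empty.
#' @export
segment <- function(request, backend = "baseline", ...) {
  stopifnot(inherits(request, "backend_request"))
  out <- if (is.function(backend)) {
    backend(request, ...)
  } else {
    switch(match.arg(backend, c("baseline", "cellpose_germlineNuclei")),
           baseline = baseline_segment(request, ...),
           cellpose_germlineNuclei = cellpose_adapter(request, ...))
  }
  stopifnot(inherits(out, "label_volume"))
  check_same_shape(out$labels, request$grid$data)
  out
}

#' Classical 3D baseline segmenter (blob seeds + marker-controlled watershed)
#'
#' A deterministic, dependency-free detector for roughly spherical nuclei of
#' about `diameter_px` pixels: (1) smooth the volume with a physically
#' isotropic Gaussian and take an Otsu foreground mask; (2) compute an
#' anisotropy-aware difference-of-Gaussians blob response at scale
#' `diameter_px / (2 * sqrt(3))` laterally; (3) keep response maxima above a
#' percentile cut tied to `cellprob_threshold` as seeds; (4) grow seeds by a
#' marker-controlled watershed on the inverted smoothed intensity, restricted
#' to the foreground mask.
#'
#' `cellprob_threshold` is mapped to the response percentile
#' `stats::plogis(cellprob_threshold)` within the foreground, so the default
#' 0.0 keeps seeds above the median foreground blob response and larger
#' values are stricter, mirroring how the threshold behaves in flow-based
#' backends.
#'
#' @param request A [backend_request()].
#' @param diameter_px Expected object diameter in pixels after preprocessing
#'   (30 for this pipeline).
#' @param smooth_sigma_px Lateral sigma of the relief/mask smoothing.
#' @return A [label_volume()].
#' @export
baseline_segment <- function(request, diameter_px = 30, smooth_sigma_px = 2) {
  stopifnot(inherits(request, "backend_request"))
  arr <- request$grid$data
  d <- dim(arr)
  aniso <- request$anisotropy
  if (max(arr) == min(arr)) return(label_volume(array(0L, d)))

  smooth <- blur_volume(arr, smooth_sigma_px / aniso, smooth_sigma_px, smooth_sigma_px)
  mask <- smooth > otsu_threshold(smooth)
  if (!any(mask)) return(label_volume(array(0L, d)))

  sigma <- diameter_px / (2 * sqrt(3))
  resp <- blur_volume(arr, sigma / aniso, sigma, sigma) -
    blur_volume(arr, 1.6 * sigma / aniso, 1.6 * sigma, 1.6 * sigma)

  q <- stats::plogis(request$cellprob_threshold)
  cut <- stats::quantile(resp[mask], probs = q, names = FALSE)
  cut <- max(cut, 0)
  r_lat <- max(2L, as.integer(round(sigma * 0.8)))
  r_ax <- max(1L, as.integer(round(sigma * 0.8 / aniso)))
  peaks <- .local_maxima3d(resp, dim(resp), r_ax, r_lat, r_lat, cut) & mask
  if (!any(peaks)) return(label_volume(array(0L, d)))

  markers <- .cc_label6(peaks, dim(peaks))
  relief <- max(smooth) - smooth
  lab <- .watershed_flood(relief, markers, mask, dim(markers))
  label_volume(lab)
}

#' Adapter for the retrained germline-nuclei Cellpose model
#'
#' Builds the exact call that the external Cellpose backend would receive —
#' `anisotropy` and `cellprob_threshold` are forwarded verbatim, along with
#' `diameter = 30` and the model path — and executes it when the optional
#' Python `cellpose` dependency is installed. Without the dependency the
#' adapter raises a capability error (condition class
#' `germseg_capability_error`) with an install hint; it never falls back
#' silently to another backend.
#'
#' @param request A [backend_request()].
#' @param model_path Path to the retrained model weights file.
#' @param do_3D Use true-3D inference rather than per-plane stitching; the
#'   stitching mode is exposed but no default mode is claimed for the
#'   published pipeline.
#' @return A [label_volume()] (only when the external backend is available).
#' @seealso [cellpose_call()] for the serialised call without execution.
#' @export
cellpose_adapter <- function(request, model_path = NULL, do_3D = TRUE) {
  call <- cellpose_call(request, model_path = model_path, do_3D = do_3D)
  if (!cellpose_available()) {
    stop(structure(
      class = c("germseg_capability_error", "error", "condition"),
      list(message = paste0(
             "the 'cellpose' Python package (with the germlineNuclei model) is ",
             "not available; install it with `pip install cellpose` and pass ",
             "`model_path`, or use backend = \"baseline\""),
           call = sys.call(-1))))
  }
  stop("cellpose execution bridge not implemented in this build", call. = FALSE)
}

#' @rdname cellpose_adapter
#' @export
cellpose_call <- function(request, model_path = NULL, do_3D = TRUE) {
  stopifnot(inherits(request, "backend_request"))
  list(model = "cellpose_germlineNuclei",
       model_path = model_path,
       diameter = TARGET_DIAMETER_PX,
       anisotropy = request$anisotropy,
       cellprob_threshold = request$cellprob_threshold,
       do_3D = isTRUE(do_3D))
}

cellpose_available <- function() FALSE

# Otsu's threshold on a 256-bin histogram of the volume's intensity range.
otsu_threshold <- function(x) {
  v <- as.vector(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  h <- tabulate(pmin(as.integer((v - lo) / (hi - lo) * nb) + 1L, nb), nbins = nb)
  p <- h / sum(h)
  mids <- lo + (seq_len(nb) - 0.5) / nb * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}
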