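#' User-facing segmentation parameters
#'
#' The knobs of the germline-nucleus segmentation pipeline, with the plugin's
#' defaults: nuclei of 3.5 µm, blur factor 2.5 (3.5 recommended for
#' deconvolved or synaptonemal-complex images), cell-probability threshold
#' 0.0, border cleaning off unless requested.
#'
#' @param diameter_um Expected nucleus diameter in µm.
#' @param blurfactor Gaussian blur applied before segmentation, in rescaled
#'   pixels (0 disables).
#' @param cellprob_threshold Backend object-likelihood threshold.
#' @param clean_borders Remove instances touching the stack borders
#'   ([clean_borders()]).
#' @param filter_criteria A [filter_criteria()] (empty = no shape filtering).
#' @param backend Backend selection: `"baseline"`,
#'   `"cellpose_germlineNuclei"`, or a function (see [segment()]).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(diameter_um = 3.5, blurfactor = 2.5,
                                cellprob_threshold = 0,
                                clean_borders = FALSE,
                                filter_criteria = germseg::filter_criteria(),
                                backend = "baseline") {
  check_positive_scalar(diameter_um, "diameter_um")
  if (!is.numeric(blurfactor) || blurfactor < 0)
    stop("`blurfactor` must be >= 0", call. = FALSE)
  stopifnot(is.logical(clean_borders), inherits(filter_criteria, "filter_criteria"))
  structure(list(diameter_um = diameter_um, blurfactor = blurfactor,
                 cellprob_threshold = cellprob_threshold,
                 clean_borders = isTRUE(clean_borders),
                 filter_criteria = filter_criteria,
                 backend = backend),
            class = "segmentation_params")
}

#' Run the full segmentation pipeline on a stack
#'
#' Executes, in order: lateral rescale so a `diameter_um` nucleus spans 30 px
#' ([compute_scale_factor()], [rescale_xy()]); Gaussian blur by `blurfactor`
#' ([gaussian_blur()]); 3D instance segmentation with the anisotropy computed
#' from the metadata ([compute_anisotropy()], [segment()]); nearest-neighbour
#' mapping of the labels back onto the original voxel grid; then optional
#' [clean_borders()] and [filter_masks()]. The result therefore lives in the
#' acquisition coordinate frame, ready for downstream quantification.
#'
#' @param grid A [voxel_grid()] (raw intensity stack).
#' @param params A [segmentation_params()].
#' @param metadata Optional [image_metadata()] overriding the grid's voxel
#'   sizes.
#' @param verbose Emit a message per stage with the resolved parameters.
#' @return A [label_volume()] with the same shape as `grid`, with attribute
#'   `"log"`: the resolved scale factor, anisotropy and all parameters.
#' @export
run_pipeline <- function(grid, params = segmentation_params(),
                         metadata = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "segmentation_params"))
  if (!is.null(metadata))
    grid <- voxel_grid(grid$data, metadata$pixel_size_xy_um, metadata$z_step_um)
  say <- function(fmt, ...) if (verbose) message(sprintf(paste0("[germseg] ", fmt), ...))

  s <- compute_scale_factor(grid$pixel_size_xy_um, params$diameter_um)
  say("rescale: s = %.4f (pixel %.4g -> %.4g um)", s,
      grid$pixel_size_xy_um, grid$pixel_size_xy_um / s)
  rescaled <- with_stage("rescale_xy", rescale_xy(grid, s))

  aniso <- compute_anisotropy(rescaled$z_step_um, rescaled$pixel_size_xy_um)
  say("anisotropy = %.4f; blurfactor = %.3g", aniso, params$blurfactor)
  blurred <- with_stage("gaussian_blur",
                        gaussian_blur(rescaled, params$blurfactor, aniso))

  say("segmenting with backend '%s' (cellprob_threshold %.3g)",
      if (is.function(params$backend)) "<function>" else params$backend,
      params$cellprob_threshold)
  req <- backend_request(blurred, aniso, params$cellprob_threshold)
  lab <- with_stage("segment", segment(req, backend = params$backend))

  lab0 <- with_stage("map_to_original",
                     map_labels_to_grid(lab, dim(grid$data)))
  if (params$clean_borders) {
    say("clean_borders: removing instances touching stack borders")
    lab0 <- with_stage("clean_borders", clean_borders(lab0))
  }
  lab0 <- with_stage("filter_masks",
                     filter_masks(lab0, params$filter_criteria,
                                  grid$pixel_size_xy_um, grid$z_step_um))
  say("done: %d instance(s)", n_instances(lab0))
  attr(lab0, "log") <- list(scale_factor = s, anisotropy = aniso,
                            diameter_um = params$diameter_um,
                            blurfactor = params$blurfactor,
                            cellprob_threshold = params$cellprob_threshold,
                            clean_borders = params$clean_borders,
                            backend = if (is.function(params$backend))
                              "custom_function" else params$backend)
  lab0
}

# nearest-neighbour resampling of a label volume onto a target (z, y, x) shape
map_labels_to_grid <- function(lv, target_dim) {
  stopifnot(inherits(lv, "label_volume"))
  arr <- lv$labels
  d <- dim(arr)
  if (identical(d, as.integer(target_dim))) return(lv)
  zi <- nearest_axis_index(target_dim[1], d[1])
  yi <- nearest_axis_index(target_dim[2], d[2])
  xi <- nearest_axis_index(target_dim[3], d[3])
  label_volume(arr[zi, yi, xi, drop = FALSE])
}

nearest_axis_index <- function(n_out, n_src) {
  pmin(pmax(as.integer(round(axis_map(n_out, n_src))) + 1L, 1L), n_src)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}
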