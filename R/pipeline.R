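#' Pipeline configuration
#'
#' Collects the parameters of every stage in one nested list, optionally
#' overridden from a YAML file with keys `enhancement.*`, `prediction.*`,
#' `chanvese.*`, `outlier.*`, `keypoints.*`, `measurement.*`.
#'
#' @param file optional YAML file of overrides.
#' @return nested configuration list.
#' @export
pipeline_config <- function(file = NULL) {
  cfg <- list(
    enhancement = unclass(enhancement_params()),
    prediction = unclass(prediction_params()),
    chanvese = unclass(chan_vese_params()),
    outlier = list(area_jump = 0.5, centroid_jump_px = 20),
    keypoints = unclass(keypoint_params()),
    measurement = list(max_slope = 10)
  )
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    for (sec in names(user)) {
      if (!sec %in% names(cfg)) stop("unknown config section: ", sec, call. = FALSE)
      for (key in names(user[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          stop("unknown config key: ", sec, ".", key, call. = FALSE)
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  cfg
}

#' Run the full measurement pipeline on a slice stack
#'
#' Enhancement, inter-slice bone-region prediction, Chan-Vese segmentation,
#' key-point extraction, central-plane fitting, PTA/PLS measurement and
#' diagnosis.
#'
#' @param stack a [slice_stack].
#' @param config a [pipeline_config()] list.
#' @param use_prediction disable the inter-slice prediction for ablation.
#' @return list with `masks` (a [bone_masks]) and `report`
#'   (a `measurement_report`).
#' @export
run_pipeline <- function(stack, config = pipeline_config(),
                         use_prediction = TRUE) {
  masks <- segment_stack(
    stack,
    enh_params = do.call(enhancement_params, config$enhancement),
    pred_params = do.call(prediction_params, config$prediction),
    cv_params = do.call(chan_vese_params, config$chanvese),
    use_prediction = use_prediction,
    outlier_area_jump = config$outlier$area_jump,
    outlier_centroid_jump_px = config$outlier$centroid_jump_px)
  report <- measure_stack(
    masks,
    pixel_pitch_mm = stack$pixel_pitch_mm,
    slice_spacing_mm = stack$slice_spacing_mm,
    kp_params = do.call(keypoint_params, config$keypoints),
    max_slope = config$measurement$max_slope)
  list(masks = masks, report = report)
}
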