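#' Default pipeline configuration
#'
#' Nested list mirroring the YAML/JSON configuration file: `camera`
#' (`dfov_deg`, `aspect`), `frame` (`width`, `height`), `lanes` (`count`,
#' `trigger_fraction`), `detection` (HSV range, kernels, threshold), and
#' `scene` (egg count, grade mix, illumination mode, noise, flow speed) for
#' the simulator.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    camera = list(dfov_deg = 78, aspect = c(16, 9)),
    frame = list(width = 1280, height = 720),
    lanes = list(count = 4, trigger_fraction = 0.5),
    detection = list(
      hsv_lo = c(5, 0.15, 0.40), hsv_hi = c(60, 1, 1),
      box_kernel_px = 5, gauss_kernel_px = 5, gauss_sigma = 1.5,
      threshold_mode = "otsu", fixed_threshold = 50,
      min_contour_area_px2 = 500
    ),
    scene = list(
      n_eggs = 20, grade_mix = c(0.25, 0.25, 0.25, 0.25),
      illumination = "multi", noise_sd = 4,
      flow_speed_px_per_frame = 400 / 30,
      entry_spacing_frames = 12, dirt_rate = 1.0
    )
  )
}

#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`, requires the `yaml` package) or JSON. Missing keys
#' fall back to [default_config()].
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(cfg, user)
}

#' Build the lane layout and detection config from a configuration
#'
#' @param cfg Configuration list from [read_config()].
#' @return List with `layout` ([build_lane_layout()]), `detection`
#'   ([detection_config()]) and `camera` ([camera_model()]).
#' @export
config_objects <- function(cfg = default_config()) {
  layout <- build_lane_layout(cfg$frame$width, cfg$frame$height,
                              cfg$lanes$count, cfg$lanes$trigger_fraction)
  det <- detection_config(
    hsv_lo = cfg$detection$hsv_lo, hsv_hi = cfg$detection$hsv_hi,
    box_kernel_px = cfg$detection$box_kernel_px,
    gauss_kernel_px = cfg$detection$gauss_kernel_px,
    gauss_sigma = cfg$detection$gauss_sigma,
    threshold_mode = cfg$detection$threshold_mode,
    fixed_threshold = cfg$detection$fixed_threshold,
    min_contour_area_px2 = cfg$detection$min_contour_area_px2)
  cam <- camera_model(cfg$camera$dfov_deg, cfg$camera$aspect)
  list(layout = layout, detection = det, camera = cam)
}

#' Build a synthetic scene from a configuration
#'
#' @param cfg Configuration list.
#' @param seed Integer seed for the population and the frame noise.
#' @return A [scene_spec()].
#' @export
config_scene <- function(cfg = default_config(), seed = 1L) {
  obj <- config_objects(cfg)
  eggs <- sample_population(
    cfg$scene$n_eggs, cfg$scene$grade_mix, seed = seed,
    layout = obj$layout,
    entry_spacing_frames = cfg$scene$entry_spacing_frames,
    dirt_rate = cfg$scene$dirt_rate)
  illum <- if (identical(cfg$scene$illumination, "single"))
    single_source_illumination(obj$layout,
                               match_power_of = per_lane_illumination(obj$layout))
  else per_lane_illumination(obj$layout)
  scene_spec(obj$layout, eggs, illum,
             flow_speed_px_per_frame = cfg$scene$flow_speed_px_per_frame,
             noise_sd = cfg$scene$noise_sd, seed = seed)
}
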