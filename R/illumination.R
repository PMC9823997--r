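#' Illumination specification for the synthetic cabinet
#'
#' Two lighting arrangements are modelled. `"single"` places one high-power
#' source over the middle of the conveyor: the center lanes are lit well and
#' the outer lanes fall off. `"multi"` places one source per flow lane, which
#' lights every lane near-equally. Each source contributes a flat-top
#' super-Gaussian lobe \eqn{I \exp(-((x - x_0)/s)^4)} across the frame width
#' (constant along the flow direction); lobes are summed and clipped at
#' `saturation_cap`.
#'
#' @param mode `"single"` or `"multi"`.
#' @param sources Data frame with columns `x_px` (lobe center), `intensity`
#'   (peak multiplier), `spread_px` (lobe scale `s`). Built automatically by
#'   [single_source_illumination()] / [per_lane_illumination()].
#' @param saturation_cap Maximum field value (sensor saturation), default 1.
#' @return An object of class `illumination_spec`.
#' @export
illumination_spec <- function(mode = c("multi", "single"),
                              sources, saturation_cap = 1) {
  mode <- match.arg(mode)
  stopifnot(all(c("x_px", "intensity", "spread_px") %in% names(sources)))
  if (any(sources$intensity < 0)) stop("intensities must be >= 0")
  structure(list(mode = mode, sources = sources,
                 saturation_cap = saturation_cap),
            class = "illumination_spec")
}

#' @rdname illumination_spec
#' @param layout A [build_lane_layout()]; `per_lane_illumination()` places
#'   one source at each lane center.
#' @param intensity Peak intensity per source.
#' @param spread_px Lobe scale; defaults: 0.51x the frame width for the
#'   single source, 0.41x the lane width for per-lane sources (neighbour
#'   spill then leaves the per-lane means equal within 1%).
#' @export
per_lane_illumination <- function(layout, intensity = 1, spread_px = NULL) {
  centers <- rowMeans(layout$lane_bounds)
  if (is.null(spread_px))
    spread_px <- 0.41 * mean(diff(t(layout$lane_bounds)))
  illumination_spec("multi", data.frame(
    x_px = centers, intensity = intensity, spread_px = spread_px
  ))
}

#' @rdname illumination_spec
#' @param match_power_of Optional `illumination_spec`; the single source is
#'   scaled so both fields deliver the same total power over the frame.
#' @export
single_source_illumination <- function(layout, intensity = 1,
                                       spread_px = NULL,
                                       match_power_of = NULL) {
  if (is.null(spread_px)) spread_px <- 0.51 * layout$frame_width_px
  spec <- illumination_spec("single", data.frame(
    x_px = layout$frame_width_px / 2,
    intensity = intensity, spread_px = spread_px
  ))
  if (!is.null(match_power_of)) {
    x <- seq(0, layout$frame_width_px - 1)
    target <- sum(.field_profile(match_power_of, x))
    got <- sum(.field_profile(spec, x))
    spec$sources$intensity <- spec$sources$intensity * target / got
  }
  spec
}

# uncapped 1-D profile over x pixel coordinates
.field_profile <- function(spec, x) {
  f <- numeric(length(x))
  for (i in seq_len(nrow(spec$sources))) {
    s <- spec$sources[i, ]
    f <- f + s$intensity * exp(-((x - s$x_px) / s$spread_px)^4)
  }
  f
}

#' Illumination field over the frame
#'
#' Evaluates the illumination multiplier at every pixel. Lobes vary across
#' the frame width only (the cabinet's LED bars run along the flow), so the
#' map is constant down each column.
#'
#' @param spec An [illumination_spec()].
#' @param layout A [build_lane_layout()] giving the frame size.
#' @return Numeric `frame_height_px x frame_width_px` matrix in
#'   `[0, saturation_cap]`.
#' @export
illumination_field <- function(spec, layout) {
  x <- seq(0, layout$frame_width_px - 1)
  f <- pmin(.field_profile(spec, x), spec$saturation_cap)
  matrix(f, nrow = layout$frame_height_px, ncol = layout$frame_width_px,
         byrow = TRUE)
}

#' Mean illumination per flow lane
#'
#' @param field Matrix from [illumination_field()].
#' @param layout The matching lane layout.
#' @return Numeric vector of per-lane mean intensities.
#' @export
lane_mean_intensity <- function(field, layout) {
  vapply(seq_len(layout$n_lanes), function(i) {
    cols <- (layout$lane_bounds[i, 1] + 1):layout$lane_bounds[i, 2]
    mean(field[, cols])
  }, numeric(1))
}

#' Flat (uniform) illumination
#'
#' Convenience for tests: a constant field of the given level.
#' @param level Field value everywhere.
#' @inheritParams illumination_field
#' @export
flat_illumination <- function(layout, level = 1) {
  spec <- illumination_spec("multi", data.frame(
    x_px = layout$frame_width_px / 2, intensity = level,
    spread_px = 1e9
  ), saturation_cap = level)
  spec
}
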