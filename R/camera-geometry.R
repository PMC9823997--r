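#' Angular field of view from an image-plane dimension
#'
#' Pinhole half-angle relation: a plane dimension \eqn{w} imaged through a
#' lens of focal length \eqn{f} subtends an angle
#' \eqn{\alpha = 2\,\mathrm{atan}(w / 2f)}. The same relation holds for the
#' sensor width, height or diagonal, giving the horizontal, vertical or
#' diagonal field of view respectively.
#'
#' @param plane_dim Image-plane dimension (any length unit), `> 0`.
#' @param focal_length Focal length in the same unit, `> 0`.
#' @return Field of view in degrees, in (0, 180).
#' @seealso [focal_from_fov()] for the inverse, [hv_fov_from_diagonal()].
#' @export
#' @examples
#' fov_from_plane(2, 1) # 90 degrees
fov_from_plane <- function(plane_dim, focal_length) {
  if (!is.numeric(plane_dim) || any(plane_dim <= 0))
    stop("`plane_dim` must be positive")
  if (!is.numeric(focal_length) || any(focal_length <= 0))
    stop("`focal_length` must be positive")
  2 * atan(plane_dim / (2 * focal_length)) * 180 / pi
}

#' Focal length from a known field of view
#'
#' Inverse of [fov_from_plane()]: \eqn{f = (w/2)\cot(\alpha/2)}.
#'
#' @param plane_dim Image-plane dimension, `> 0`.
#' @param fov_deg Field of view in degrees, strictly inside (0, 180).
#' @return Focal length in the unit of `plane_dim`.
#' @export
focal_from_fov <- function(plane_dim, fov_deg) {
  if (!is.numeric(plane_dim) || any(plane_dim <= 0))
    stop("`plane_dim` must be positive")
  if (!is.numeric(fov_deg) || any(fov_deg <= 0) || any(fov_deg >= 180))
    stop("`fov_deg` must be strictly between 0 and 180 degrees")
  (plane_dim / 2) / tan(fov_deg / 2 * pi / 180)
}

#' Horizontal and vertical FoV from the diagonal FoV and aspect ratio
#'
#' Camera vendors quote the diagonal field of view. For a sensor with aspect
#' ratio `aspect_w:aspect_h`, the diagonal in aspect units is
#' \eqn{d = \sqrt{w^2 + h^2}}; recovering the focal length from the diagonal
#' angle and re-applying the half-angle relation to the width and height
#' gives the horizontal and vertical angles.
#'
#' @param dfov_deg Diagonal field of view in degrees, in (0, 180).
#' @param aspect_w,aspect_h Positive aspect-ratio terms (e.g. 16 and 9).
#' @return Named numeric vector `c(hfov_deg =, vfov_deg =)`.
#' @export
#' @examples
#' hv_fov_from_diagonal(78, 16, 9) # c(70.42, 43.30) for a 78-degree 16:9 lens
hv_fov_from_diagonal <- function(dfov_deg, aspect_w, aspect_h) {
  if (any(c(aspect_w, aspect_h) <= 0)) stop("aspect terms must be positive")
  d <- sqrt(aspect_w^2 + aspect_h^2)
  f <- focal_from_fov(d, dfov_deg)
  c(hfov_deg = fov_from_plane(aspect_w, f),
    vfov_deg = fov_from_plane(aspect_h, f))
}

#' Camera model from diagonal FoV and aspect ratio
#'
#' Builds a `camera_model` object holding the sensor dimensions (in aspect
#' units), the focal length consistent with the quoted diagonal FoV, and the
#' three angular fields of view.
#'
#' @param dfov_deg Diagonal field of view in degrees.
#' @param aspect Length-2 numeric, width:height aspect (default 16:9).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(dfov_deg, aspect = c(16, 9)) {
  stopifnot(length(aspect) == 2)
  w <- aspect[1]; h <- aspect[2]
  d <- sqrt(w^2 + h^2)
  f <- focal_from_fov(d, dfov_deg)
  structure(list(
    focal_length = f,
    sensor_width = w,
    sensor_height = h,
    sensor_diagonal = d,
    dfov_deg = dfov_deg,
    hfov_deg = fov_from_plane(w, f),
    vfov_deg = fov_from_plane(h, f),
    aspect_ratio = w / h
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>\n")
  cat(sprintf("  aspect %g:%g  focal length %.4f (aspect units)\n",
              x$sensor_width, x$sensor_height, x$focal_length))
  cat(sprintf("  DFoV %.2f deg  HFoV %.2f deg  VFoV %.2f deg\n",
              x$dfov_deg, x$hfov_deg, x$vfov_deg))
  invisible(x)
}

#' Partition the camera frame into flow-lane regions of interest
#'
#' Divides the frame width into `n_lanes` contiguous half-open pixel
#' intervals `[x_lo, x_hi)` — one per conveyor flow lane — and places the
#' measurement trigger line at `round(trigger_fraction * frame_height_px)`.
#' Pixel coordinates are 0-based with the origin at the top-left corner;
#' eggs flow in the +y direction.
#'
#' @param frame_width_px,frame_height_px Frame size in pixels.
#' @param n_lanes Number of flow lanes (>= 1).
#' @param trigger_fraction Vertical position of the trigger line as a
#'   fraction of the frame height, strictly in (0, 1). Default 0.5.
#' @param roi Optional measurement region, a list with `x = c(x_lo, x_hi)`
#'   and `y = c(y_lo, y_hi)` half-open pixel intervals. Defaults to the full
#'   frame. The trigger line must lie inside the ROI.
#' @return An object of class `lane_layout` with elements `frame_width_px`,
#'   `frame_height_px`, `n_lanes`, `lane_bounds` (n x 2 matrix of half-open
#'   intervals), `trigger_y_px` and `roi`.
#' @export
#' @examples
#' build_lane_layout(1280, 720, 4, 0.5)
build_lane_layout <- function(frame_width_px, frame_height_px, n_lanes = 4,
                              trigger_fraction = 0.5, roi = NULL) {
  if (n_lanes < 1) stop("`n_lanes` must be >= 1")
  if (n_lanes > frame_width_px)
    stop("`n_lanes` exceeds the frame width in pixels")
  if (trigger_fraction <= 0 || trigger_fraction >= 1)
    stop("`trigger_fraction` must be strictly inside (0, 1)")
  cuts <- round((0:n_lanes) * frame_width_px / n_lanes)
  bounds <- cbind(x_lo = cuts[-(n_lanes + 1)], x_hi = cuts[-1])
  trigger <- round(trigger_fraction * frame_height_px)
  if (is.null(roi))
    roi <- list(x = c(0, frame_width_px), y = c(0, frame_height_px))
  if (trigger < roi$y[1] || trigger >= roi$y[2])
    stop("trigger line falls outside the measurement ROI")
  structure(list(
    frame_width_px = frame_width_px,
    frame_height_px = frame_height_px,
    n_lanes = n_lanes,
    lane_bounds = bounds,
    trigger_y_px = trigger,
    roi = roi
  ), class = "lane_layout")
}

#' @export
print.lane_layout <- function(x, ...) {
  cat(sprintf("<lane_layout> %d x %d px, %d lane(s), trigger row %d\n",
              x$frame_width_px, x$frame_height_px, x$n_lanes, x$trigger_y_px))
  for (i in seq_len(x$n_lanes))
    cat(sprintf("  lane %d: [%d, %d)\n", i,
                x$lane_bounds[i, 1], x$lane_bounds[i, 2]))
  invisible(x)
}

#' Flow lane containing an x pixel coordinate
#'
#' @param layout A [build_lane_layout()] object.
#' @param x 0-based x pixel coordinate(s).
#' @return Integer lane index (1-based), `NA` outside the frame.
#' @export
lane_of <- function(layout, x) {
  idx <- findInterval(x, layout$lane_bounds[, 1])
  idx[x < 0 | x >= layout$frame_width_px] <- NA_integer_
  as.integer(idx)
}
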