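#' Detection-chain configuration
#'
#' Parameters of the image-processing chain: the HSV range that keeps egg
#' pixels and removes the dark matte background, the smoothing kernels, the
#' thresholding mode and the minimum contour size.
#'
#' The published pipeline names no HSV range (it is scene-specific); the
#' defaults target the brown-shell palette of the synthetic scenes. Hue is
#' in degrees `[0, 360)`, saturation and value in `[0, 1]`. A hue range with
#' `hsv_lo[1] > hsv_hi[1]` wraps through 0 degrees (red/brown shells
#' straddle the hue origin).
#'
#' @param hsv_lo,hsv_hi HSV triples bounding the foreground (egg) range.
#' @param box_kernel_px Odd size of the normalized box filter, default 5.
#' @param gauss_kernel_px Odd size of the Gaussian filter, default 5.
#' @param gauss_sigma Gaussian standard deviation in px, default 1.5.
#' @param threshold_mode `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold on the masked grayscale (0..255 scale)
#'   when `threshold_mode = "fixed"`.
#' @param min_contour_area_px2 Components smaller than this many pixels are
#'   discarded, default 500.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(hsv_lo = c(5, 0.15, 0.40),
                             hsv_hi = c(60, 1, 1),
                             box_kernel_px = 5, gauss_kernel_px = 5,
                             gauss_sigma = 1.5,
                             threshold_mode = c("otsu", "fixed"),
                             fixed_threshold = 50,
                             min_contour_area_px2 = 500) {
  threshold_mode <- match.arg(threshold_mode)
  for (k in c(box_kernel_px, gauss_kernel_px))
    if (k < 1 || k %% 2 == 0) stop("smoothing kernels must be odd and >= 1")
  if (length(hsv_lo) != 3 || length(hsv_hi) != 3)
    stop("`hsv_lo` and `hsv_hi` must be HSV triples")
  if (any(hsv_lo[2:3] > hsv_hi[2:3]))
    stop("saturation/value bounds must satisfy lo <= hi")
  structure(list(
    hsv_lo = hsv_lo, hsv_hi = hsv_hi,
    box_kernel_px = as.integer(box_kernel_px),
    gauss_kernel_px = as.integer(gauss_kernel_px),
    gauss_sigma = gauss_sigma,
    threshold_mode = threshold_mode,
    fixed_threshold = fixed_threshold,
    min_contour_area_px2 = min_contour_area_px2
  ), class = "detection_config")
}

#' RGB to HSV conversion
#'
#' Converts an `h x w x 3` RGB frame (0..255) to HSV with hue in degrees
#' `[0, 360)`, saturation in `[0, 1]` and value in `[0, 1]`. Gray pixels map
#' to saturation 0 (and hue 0 by convention).
#'
#' @param frame `h x w x 3` numeric array, values 0..255.
#' @return `h x w x 3` array with channels `h`, `s`, `v`.
#' @export
to_hsv <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3)
    stop("`frame` must be an h x w x 3 RGB array")
  ch <- cpp_rgb2hsv(frame)
  out <- array(c(ch$h, ch$s, ch$v), dim = d)
  dimnames(out) <- list(NULL, NULL, c("h", "s", "v"))
  out
}

#' Smooth an image with the box-then-Gaussian cascade
#'
#' Applies the normalized box filter followed by the Gaussian filter (in
#' that order), channel by channel, with replicated borders. A kernel size
#' of 1 is the identity.
#'
#' @param image Numeric matrix or `h x w x c` array.
#' @param config A [detection_config()] supplying kernel sizes and sigma.
#' @return Smoothed image of the same shape.
#' @export
smooth_image <- function(image, config = detection_config()) {
  one <- function(m) {
    m <- cpp_box_filter(m, config$box_kernel_px)
    cpp_gauss_filter(m, config$gauss_kernel_px, config$gauss_sigma)
  }
  if (is.matrix(image)) return(one(image))
  d <- dim(image)
  if (length(d) != 3) stop("`image` must be a matrix or 3-d array")
  out <- image
  for (k in seq_len(d[3])) out[, , k] <- one(image[, , k])
  out
}

#' Foreground mask from an HSV range
#'
#' Marks pixels whose HSV values fall inside `[hsv_lo, hsv_hi]` as
#' foreground (1); everything else — the background — becomes 0. Applying
#' the mask to the original frame leaves "the actual image but background".
#'
#' @param hsv_image Array from [to_hsv()] (optionally smoothed).
#' @param config A [detection_config()].
#' @return Integer `h x w` matrix of 0/1.
#' @export
background_mask <- function(hsv_image, config = detection_config()) {
  d <- dim(hsv_image)
  if (length(d) != 3 || d[3] != 3) stop("`hsv_image` must be h x w x 3")
  cpp_hsv_mask(hsv_image[, , 1], hsv_image[, , 2], hsv_image[, , 3],
               config$hsv_lo, config$hsv_hi)
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' 0..255 intensity range.
#'
#' @param x Numeric vector or matrix of intensities in 0..255.
#' @return Threshold value (bin upper edge); pixels `> threshold` are
#'   foreground.
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  bins <- pmin(255L, pmax(0L, as.integer(floor(x))))
  otsu_from_hist(as.numeric(tabulate(bins + 1L, nbins = 256L)))
}

# Otsu on a precomputed 256-bin histogram (bin i holds intensity i - 1)
otsu_from_hist <- function(h) {
  n <- sum(h)
  if (n == 0) return(0)
  lv <- 0:255
  w1 <- cumsum(h)
  m1 <- cumsum(h * lv)
  mt <- m1[256]
  w2 <- n - w1
  between <- (mt * w1 - m1 * n)^2 / (w1 * w2 * n^2)
  between[w1 == 0 | w2 == 0] <- 0
  lv[which.max(between)]
}

#' Extract object contours from a mask or grayscale image
#'
#' Binary input is used as-is; grayscale input is first thresholded (Otsu by
#' default, or the configured fixed threshold). Connected foreground
#' components (8-connectivity) with at least `min_contour_area_px2` pixels
#' are traced with Moore boundary following; contours are returned sorted by
#' decreasing area.
#'
#' @param image Integer 0/1 mask or numeric grayscale matrix (0..255).
#' @param config A [detection_config()].
#' @return List of contours; each has `points` (n x 2 matrix of ordered
#'   boundary pixel coordinates, 0-based), `area` (polygonal, by the
#'   shoelace formula), `n_pixels` (component pixel count), `centroid`
#'   (component mass center), `label`, and the label image is attached as
#'   the `labels` attribute of the list.
#' @export
extract_contours <- function(image, config = detection_config()) {
  rng <- range(image)
  binary <- rng[1] >= 0 && rng[2] <= 1 &&
    (is.integer(image) || all(image == floor(image)))
  if (!binary) {
    thr <- if (config$threshold_mode == "otsu") otsu_threshold(image)
           else config$fixed_threshold
    image <- (image > thr) * 1L
  }
  mask <- if (is.integer(image)) image
          else matrix(as.integer(image != 0), nrow(image), ncol(image))
  lab <- cpp_label(mask)
  stats <- lab$stats
  keep <- which(stats[, "size"] >= config$min_contour_area_px2)
  out <- lapply(keep, function(id) {
    pts <- cpp_trace_boundary(lab$labels, id)
    sz <- unname(stats[id, "size"])
    list(points = pts,
         area = polygon_area(pts),
         perimeter = polygon_perimeter(pts),
         n_pixels = sz,
         centroid = c(x = unname(stats[id, "sum_x"]) / sz,
                      y = unname(stats[id, "sum_y"]) / sz),
         label = id)
  })
  out <- out[order(vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)]
  attr(out, "labels") <- lab$labels
  out
}

# shoelace area of a closed polygon given ordered vertices
polygon_area <- function(points) {
  n <- nrow(points)
  if (n < 3) return(0)
  x <- points[, 1]; y <- points[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# length of the closed polyline through ordered vertices
polygon_perimeter <- function(points) {
  n <- nrow(points)
  if (n < 2) return(0)
  j <- c(seq_len(n)[-1], 1)
  sum(sqrt((points[j, 1] - points[, 1])^2 + (points[j, 2] - points[, 2])^2))
}

#' Minimum enclosing circle of a point set
#'
#' Smallest circle containing every point (all points lie inside or on the
#' boundary). Welzl's move-to-front algorithm, expected linear time after an
#' internal deterministic shuffle.
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 1.
#' @return List with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(points) {
  points <- rbind(points)
  if (nrow(points) == 0) stop("`points` must contain at least one point")
  points <- unique(points)
  res <- cpp_min_enclosing_circle(points)
  list(center = res[1:2], radius = res[3])
}

#' Measure one detected egg
#'
#' Computes the full per-egg feature record: the component mass center, the
#' polygonal contour area and perimeter, the minimum enclosing circle, the
#' zero / non-zero pixel counts of the mask restricted to the circle's disk,
#' the foreground ratio `bw_ratio = nonzero / (zero + nonzero)`, and the
#' dirt-corrected area. The correction restores convexity: inside the disk,
#' background pixels falling within the convex hull of the foreground are
#' counted as egg (egg silhouettes are convex, so interior dirt holes and
#' boundary dirt bites are both concavities).
#'
#' @param mask Integer 0/1 mask the contour was extracted from.
#' @param contour One element of [extract_contours()].
#' @param config A [detection_config()].
#' @return An object of class `egg_detection`, or `NULL` (with a message)
#'   for a degenerate contour. Fields: `contour`, `centroid_px`,
#'   `contour_area_px2`, `perimeter_px`, `circle_center_px`,
#'   `circle_radius_px`, `circle_area_px2`, `zero_px`, `nonzero_px`,
#'   `bw_ratio`, `corrected_area_px2`, `lane` (`NA` until assigned).
#' @export
measure_egg <- function(mask, contour, config = detection_config()) {
  if (contour$area <= 0 || nrow(contour$points) < 3) {
    message("egg rejected: degenerate contour (zero area)")
    return(NULL)
  }
  mec <- min_enclosing_circle(contour$points)
  hull_idx <- grDevices::chull(contour$points[, 1], contour$points[, 2])
  hull <- contour$points[hull_idx, , drop = FALSE]
  mask_int <- if (is.integer(mask)) mask
              else matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  cnt <- cpp_disk_counts(mask_int, mec$center[1], mec$center[2],
                         mec$radius, hull)
  total <- cnt[["total"]]
  structure(list(
    contour = contour$points,
    centroid_px = contour$centroid,
    contour_area_px2 = contour$area,
    perimeter_px = contour$perimeter,
    n_pixels = contour$n_pixels,
    circle_center_px = mec$center,
    circle_radius_px = mec$radius,
    circle_area_px2 = pi * mec$radius^2,
    zero_px = cnt[["zero"]],
    nonzero_px = cnt[["nonzero"]],
    bw_ratio = if (total > 0) cnt[["nonzero"]] / total else NA_real_,
    corrected_area_px2 = cnt[["filled"]],
    lane = NA_integer_
  ), class = "egg_detection")
}

#' Detect eggs in one frame
#'
#' Runs the full chain — HSV conversion, box + Gaussian smoothing, HSV
#' background masking, thresholding of the masked grayscale, contour
#' extraction, and per-egg measurement — inside the layout's measurement
#' ROI, then assigns each detection to the flow lane containing its mass
#' center.
#'
#' @param frame `h x w x 3` RGB array (0..255) matching the layout.
#' @param layout A [build_lane_layout()].
#' @param config A [detection_config()].
#' @return List of `egg_detection` objects (possibly empty), coordinates in
#'   full-frame pixels.
#' @export
detect_eggs <- function(frame, layout, config = detection_config()) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3)
    stop("`frame` must be an h x w x 3 RGB array")
  if (d[1] != layout$frame_height_px || d[2] != layout$frame_width_px)
    stop("frame dimensions do not match the lane layout")
  rx <- layout$roi$x; ry <- layout$roi$y
  sub <- frame[(ry[1] + 1):ry[2], (rx[1] + 1):rx[2], , drop = FALSE]
  .detect_core(sub, layout, config)
}

# detection chain on an already-cropped ROI image; coordinates are shifted
# back to full-frame pixels using the layout's ROI origin
.detect_core <- function(sub, layout, config) {
  rx <- layout$roi$x; ry <- layout$roi$y
  # fused fast path: identical to to_hsv() |> smooth_image() |>
  # background_mask() but without intermediate copies (asserted in tests)
  chain <- cpp_chain_mask(sub, config$hsv_lo, config$hsv_hi,
                          config$box_kernel_px, config$gauss_kernel_px,
                          config$gauss_sigma)
  # threshold the masked grayscale; its binary is the final pixel-count image
  thr <- if (config$threshold_mode == "otsu") otsu_from_hist(chain$gray_hist)
         else config$fixed_threshold
  binary <- cpp_apply_threshold(chain$mask, chain$v_smooth, thr)
  contours <- extract_contours(binary, config)
  dets <- list()
  for (ct in contours) {
    det <- measure_egg(binary, ct, config)
    if (is.null(det)) next
    det$centroid_px <- det$centroid_px + c(rx[1], ry[1])
    det$circle_center_px <- det$circle_center_px + c(rx[1], ry[1])
    det$contour <- sweep(det$contour, 2, c(rx[1], ry[1]), "+")
    det$lane <- lane_of(layout, det$centroid_px[1])
    dets[[length(dets) + 1]] <- det
  }
  dets
}

#' Detections as a data frame
#'
#' @param detections List of `egg_detection` objects.
#' @param frame_index Optional frame index column.
#' @return Data frame, one row per detection.
#' @export
detections_df <- function(detections, frame_index = NA_integer_) {
  if (!length(detections))
    return(data.frame(frame_index = integer(0), lane = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      contour_area = numeric(0), perimeter = numeric(0),
                      circle_area = numeric(0), bw_ratio = numeric(0),
                      corrected_area = numeric(0)))
  do.call(rbind, lapply(detections, function(d) data.frame(
    frame_index = frame_index, lane = d$lane,
    centroid_x = d$centroid_px[1], centroid_y = d$centroid_px[2],
    contour_area = d$contour_area_px2, perimeter = d$perimeter_px,
    circle_area = d$circle_area_px2, bw_ratio = d$bw_ratio,
    corrected_area = d$corrected_area_px2
  )))
}
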