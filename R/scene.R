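#' Synthetic conveyor scene
#'
#' Bundles everything needed to render a labelled frame sequence: the lane
#' layout, the egg population, the illumination, the flow speed, the sensor
#' noise level and a seed. The same spec and seed always render bit-identical
#' frames.
#'
#' Default flow speed: a 0.2 m/s conveyor imaged at 30 fps and 2 px/mm moves
#' eggs 400/30 = 13.33 px per frame.
#'
#' @param layout A [build_lane_layout()].
#' @param eggs List of [egg_spec()] objects (e.g. [sample_population()]).
#' @param illumination An [illumination_spec()]; default per-lane sources.
#' @param n_frames Number of frames; `NULL` runs until the last egg has left
#'   the frame.
#' @param flow_speed_px_per_frame Egg advance along +y per frame.
#' @param noise_sd Achromatic Gaussian sensor noise sd (intensity units on
#'   the 0..255 scale), default 4.
#' @param background_rgb Matte background colour, default dark
#'   `c(26, 26, 26)` ("opaque black ground").
#' @param seed Integer seed controlling the per-frame noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(layout, eggs,
                       illumination = per_lane_illumination(layout),
                       n_frames = NULL,
                       flow_speed_px_per_frame = 400 / 30,
                       noise_sd = 4,
                       background_rgb = c(26, 26, 26),
                       seed = 1L) {
  if (flow_speed_px_per_frame <= 0) stop("flow speed must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(n_frames)) {
    n_frames <- if (length(eggs) == 0) 1L else {
      exit <- vapply(eggs, function(e) {
        e$entry_frame +
          ceiling((layout$frame_height_px + 2 * e$semi_axes_px[2]) /
                    flow_speed_px_per_frame)
      }, numeric(1))
      as.integer(max(exit) + 1)
    }
  }
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  structure(list(
    layout = layout, eggs = eggs, illumination = illumination,
    n_frames = as.integer(n_frames),
    flow_speed_px_per_frame = flow_speed_px_per_frame,
    noise_sd = noise_sd, background_rgb = background_rgb,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# center of egg e at frame t (0-based); x fixed at lane center + offset,
# y advances from just above the frame at constant speed
egg_center <- function(spec, egg, frame_index) {
  lane_c <- mean(spec$layout$lane_bounds[egg$lane, ])
  c(x = lane_c + egg$x_offset_px,
    y = -egg$semi_axes_px[2] +
      (frame_index - egg$entry_frame) * spec$flow_speed_px_per_frame)
}

# eggs whose ellipse intersects the frame at the given frame index
visible_eggs <- function(spec, frame_index) {
  keep <- vapply(seq_along(spec$eggs), function(i) {
    e <- spec$eggs[[i]]
    if (frame_index < e$entry_frame) return(FALSE)
    y <- egg_center(spec, e, frame_index)["y"]
    y + e$semi_axes_px[2] >= 0 & y - e$semi_axes_px[2] <= spec$layout$frame_height_px - 1
  }, logical(1))
  which(keep)
}

# error if two same-lane eggs overlap at the given frame (the conveyor feeds
# eggs singly per lane; overlap would invalidate per-egg measurement)
check_no_overlap <- function(spec, frame_index, ids) {
  if (length(ids) < 2) return(invisible(TRUE))
  lanes <- vapply(ids, function(i) spec$eggs[[i]]$lane, integer(1))
  for (ln in unique(lanes)) {
    in_lane <- ids[lanes == ln]
    if (length(in_lane) < 2) next
    ys <- vapply(in_lane, function(i)
      egg_center(spec, spec$eggs[[i]], frame_index)["y"], numeric(1))
    bs <- vapply(in_lane, function(i) spec$eggs[[i]]$semi_axes_px[2], numeric(1))
    o <- order(ys)
    ys <- ys[o]; bs <- bs[o]
    gap <- diff(ys) - (bs[-length(bs)] + bs[-1])
    if (any(gap < 0))
      stop(sprintf("eggs overlap in lane %d at frame %d", ln, frame_index))
  }
  invisible(TRUE)
}

#' Render one frame of a synthetic scene
#'
#' Eggs are drawn as filled ellipses in their lanes, dirt spots as darker
#' disks, all modulated by the illumination field; achromatic Gaussian noise
#' is added and values are clipped to `[0, 255]`. Rendering is deterministic:
#' the per-frame noise stream is seeded from `spec$seed` and `frame_index`.
#'
#' @param spec A [scene_spec()].
#' @param frame_index 0-based frame index.
#' @param field Optional precomputed [illumination_field()] (saves time in
#'   frame loops).
#' @param region Optional sub-region to render, a list with half-open pixel
#'   intervals `x = c(x_lo, x_hi)` and `y = c(y_lo, y_hi)` (e.g. the layout
#'   ROI). Only that part of the frame is rasterized and returned; its noise
#'   is drawn from a region-sized stream, so region pixels are *not*
#'   bit-identical to the same pixels of a full-frame render (both are
#'   equally valid realizations of the scene).
#' @return `h x w x 3` numeric array, values in 0..255 (region-sized when
#'   `region` is given).
#' @export
render_frame <- function(spec, frame_index, field = NULL, region = NULL) {
  if (frame_index < 0 || frame_index >= spec$n_frames)
    stop("`frame_index` out of range")
  if (is.null(field)) field <- illumination_field(spec$illumination, spec$layout)
  ids <- visible_eggs(spec, frame_index)
  check_no_overlap(spec, frame_index, ids)
  eggm <- matrix(numeric(0), ncol = 7)
  dirtm <- matrix(numeric(0), ncol = 5)
  if (length(ids)) {
    rows <- lapply(seq_along(ids), function(k) {
      e <- spec$eggs[[ids[k]]]
      ctr <- egg_center(spec, e, frame_index)
      list(egg = c(ctr["x"], ctr["y"], e$semi_axes_px, e$shell_color),
           dirt = if (nrow(e$dirt_spots))
             cbind(k, ctr["x"] + e$dirt_spots$dx, ctr["y"] + e$dirt_spots$dy,
                   e$dirt_spots$radius_px, e$dirt_spots$darkness)
           else matrix(numeric(0), ncol = 5))
    })
    eggm <- do.call(rbind, lapply(rows, `[[`, "egg"))
    dirtm <- do.call(rbind, lapply(rows, `[[`, "dirt"))
    if (is.null(dirtm)) dirtm <- matrix(numeric(0), ncol = 5)
  }
  h <- spec$layout$frame_height_px
  w <- spec$layout$frame_width_px
  if (!is.null(region)) {
    h <- region$y[2] - region$y[1]
    w <- region$x[2] - region$x[1]
    field <- field[(region$y[1] + 1):region$y[2],
                   (region$x[1] + 1):region$x[2], drop = FALSE]
    if (nrow(eggm)) {
      eggm[, 1] <- eggm[, 1] - region$x[1]
      eggm[, 2] <- eggm[, 2] - region$y[1]
    }
    if (nrow(dirtm)) {
      dirtm[, 2] <- dirtm[, 2] - region$x[1]
      dirtm[, 3] <- dirtm[, 3] - region$y[1]
    }
  }
  cpp_render_frame(h, w, spec$background_rgb, field, eggm, dirtm,
                   spec$noise_sd,
                   seed = (spec$seed * 1e6 + frame_index) %% 2^48)
}

#' Rasterized area of an ellipse on the pixel lattice
#'
#' Counts lattice points (pixel centers) inside the ellipse with center
#' `(cx, cy)` and semi-axes `(a, b)`. This is exactly the number of pixels
#' the renderer paints for a clean egg, and serves as the per-frame true
#' projected area in the ground-truth channel.
#'
#' @param a,b Semi-axes in px (`a` along x, `b` along y).
#' @param cx,cy Center coordinates (possibly fractional).
#' @return Integer pixel count.
#' @export
raster_ellipse_area <- function(a, b, cx = 0, cy = 0) {
  ys <- seq(ceiling(cy - b), floor(cy + b))
  if (!length(ys)) return(0L)
  t2 <- 1 - ((ys - cy) / b)^2
  t2[t2 < 0] <- 0
  half <- a * sqrt(t2)
  sum(pmax(0, floor(cx + half) - ceiling(cx - half) + 1))
}

#' Ground-truth table for a scene
#'
#' One record per visible egg per frame: frame index, egg id, lane, center,
#' the rasterized true projected area at that frame's subpixel position, the
#' true weight and the true grade. Computed analytically — no rendering.
#'
#' @param spec A [scene_spec()].
#' @param frames Frame indices to cover (default all).
#' @return Data frame with columns `frame_index`, `egg_id`, `lane`,
#'   `centroid_x`, `centroid_y`, `true_area_px2`, `true_weight_g`,
#'   `true_grade`.
#' @export
truth_table <- function(spec, frames = seq_len(spec$n_frames) - 1L) {
  grades <- if (length(spec$eggs))
    assign_grade(vapply(spec$eggs, `[[`, numeric(1), "true_weight_g"))$grade
  else integer(0)
  recs <- list()
  for (t in frames) {
    ids <- visible_eggs(spec, t)
    for (i in ids) {
      e <- spec$eggs[[i]]
      ctr <- egg_center(spec, e, t)
      recs[[length(recs) + 1]] <- data.frame(
        frame_index = t, egg_id = i, lane = e$lane,
        centroid_x = unname(ctr["x"]), centroid_y = unname(ctr["y"]),
        true_area_px2 = raster_ellipse_area(e$semi_axes_px[1],
                                            e$semi_axes_px[2],
                                            ctr["x"], ctr["y"]),
        true_weight_g = e$true_weight_g,
        true_grade = grades[i]
      )
    }
  }
  if (!length(recs))
    return(data.frame(frame_index = integer(0), egg_id = integer(0),
                      lane = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), true_area_px2 = numeric(0),
                      true_weight_g = numeric(0), true_grade = integer(0)))
  do.call(rbind, recs)
}

#' Render a frame sequence with its ground truth
#'
#' Materializes all frames in memory; intended for short sequences (tests,
#' examples). Long runs should stream frames with [render_frame()] or
#' [run_scene_pipeline()].
#'
#' @param spec A [scene_spec()].
#' @param frames Frame indices (default all).
#' @return List with `frames` (list of `h x w x 3` arrays) and `truth`
#'   (data frame, see [truth_table()]).
#' @export
render_sequence <- function(spec, frames = seq_len(spec$n_frames) - 1L) {
  field <- illumination_field(spec$illumination, spec$layout)
  list(frames = lapply(frames, function(t) render_frame(spec, t, field)),
       truth = truth_table(spec, frames))
}

#' Write frames and ground truth to a directory
#'
#' Frames are written as zero-padded PNG files `frame_000000.png` (requires
#' the `png` package); the truth table as both a JSON-lines manifest
#' `truth.jsonl` (one record per line) and a summary CSV `truth.csv`.
#'
#' @param spec A [scene_spec()].
#' @param dir Output directory (created if needed).
#' @param frames Frame indices (default all).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(spec, dir, frames = seq_len(spec$n_frames) - 1L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG frames requires the `png` package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  field <- illumination_field(spec$illumination, spec$layout)
  for (t in frames) {
    fr <- render_frame(spec, t, field)
    png::writePNG(fr / 255, file.path(dir, sprintf("frame_%06d.png", t)))
  }
  truth <- truth_table(spec, frames)
  con <- file(file.path(dir, "truth.jsonl"), "w")
  for (i in seq_len(nrow(truth)))
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  close(con)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read frames back from a directory
#'
#' Reads `frame_*.png` files ordered by filename index into 0..255 arrays.
#'
#' @param dir Directory written by [write_scene()] (or any directory of
#'   same-sized PNG frames).
#' @return List of `h x w x 3` arrays.
#' @export
read_frames <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG frames requires the `png` package")
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE] * 255
  })
}
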