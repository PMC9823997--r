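#' Per-egg track on the moving line
#'
#' A track accumulates the per-frame detections of one egg travelling down
#' its lane, and records the single measurement captured when the egg's mass
#' center crosses the trigger line.
#'
#' Tracks are plain lists with fields `track_id`, `lane`, `history` (data
#' frame: `frame_index`, `centroid_x`, `centroid_y`), `detections` (list of
#' `egg_detection`, parallel to `history`), `measured` (flag),
#' `measurement` (the `egg_detection` at trigger time), `trigger_frame`,
#' `last_frame`, `open`.
#'
#' @name egg_track
NULL

new_track <- function(track_id, lane, frame_index, detection) {
  list(track_id = track_id, lane = lane,
       history = data.frame(frame_index = frame_index,
                            centroid_x = detection$centroid_px[1],
                            centroid_y = detection$centroid_px[2]),
       detections = list(detection),
       measured = FALSE, measurement = NULL, trigger_frame = NA_integer_,
       last_frame = frame_index, open = TRUE)
}

#' Associate one frame of detections with existing tracks
#'
#' Greedy nearest-neighbour association, gated by lane and by `max_jump_px`:
#' each detection joins the open same-lane track whose last centroid is
#' nearest (and within `max_jump_px`); otherwise it starts a new track. When
#' two detections claim one track the nearer one wins (ties broken by lower
#' x) and the other starts a new track. Tracks not updated for more than 2
#' frames whose last centroid lies beyond the ROI exit are closed.
#' Unmatched detections first seen within one association gate of the ROI
#' exit are discarded rather than started as tracks: the flow enters from
#' the top, so such detections are clipping fragments of exiting eggs.
#'
#' @param state Tracking state from [new_track_state()].
#' @param detections List of `egg_detection` from [detect_eggs()].
#' @param frame_index Current (0-based) frame index.
#' @param layout The [build_lane_layout()].
#' @param max_jump_px Association gate; default 2x the expected per-frame
#'   flow displacement stored in the state.
#' @return Updated state.
#' @export
update_tracks <- function(state, detections, frame_index, layout,
                          max_jump_px = state$max_jump_px) {
  # age out tracks: unseen for > 2 frames and already past the ROI exit
  for (i in seq_along(state$tracks)) {
    tr <- state$tracks[[i]]
    if (!tr$open) next
    stale <- frame_index - tr$last_frame > 2
    past_exit <- tr$history$centroid_y[nrow(tr$history)] >=
      layout$roi$y[2] - max_jump_px
    if (stale && past_exit) state$tracks[[i]]$open <- FALSE
    else if (frame_index - tr$last_frame > 10)
      state$tracks[[i]]$open <- FALSE  # lost track safety net
  }
  if (!length(detections)) return(state)
  # order detections by lower x first so that ties resolve deterministically
  ord <- order(vapply(detections, function(d) d$centroid_px[1], numeric(1)))
  claimed <- integer(0)
  for (di in ord) {
    det <- detections[[di]]
    best <- NA_integer_; best_d <- Inf
    for (i in seq_along(state$tracks)) {
      tr <- state$tracks[[i]]
      if (!tr$open || tr$lane != det$lane || i %in% claimed) next
      last <- tr$history[nrow(tr$history), ]
      dist <- sqrt((last$centroid_x - det$centroid_px[1])^2 +
                     (last$centroid_y - det$centroid_px[2])^2)
      # flow is one-way: never associate backwards beyond jitter
      if (det$centroid_px[2] < last$centroid_y - 2) next
      if (dist < best_d && dist <= max_jump_px) { best <- i; best_d <- dist }
    }
    if (is.na(best)) {
      # eggs enter the ROI from the top: an unmatched detection first seen
      # within one association gate of the ROI exit can only be a clipping
      # fragment of an egg leaving the band, never a new egg
      if (det$centroid_px[2] >= layout$roi$y[2] - 2 * max_jump_px) next
      state$next_id <- state$next_id + 1L
      state$tracks[[length(state$tracks) + 1]] <-
        new_track(state$next_id, det$lane, frame_index, det)
      claimed <- c(claimed, length(state$tracks))
    } else {
      tr <- state$tracks[[best]]
      tr$history <- rbind(tr$history, data.frame(
        frame_index = frame_index,
        centroid_x = det$centroid_px[1], centroid_y = det$centroid_px[2]))
      tr$detections[[length(tr$detections) + 1]] <- det
      tr$last_frame <- frame_index
      state$tracks[[best]] <- tr
      claimed <- c(claimed, best)
    }
  }
  state
}

#' Fresh tracking state
#'
#' @param max_jump_px Association gate passed to [update_tracks()]; default
#'   twice the expected per-frame flow displacement.
#' @param flow_speed_px_per_frame Expected flow speed, used only for the
#'   default gate.
#' @return A tracking state (list with `tracks`, `next_id`, `max_jump_px`).
#' @export
new_track_state <- function(flow_speed_px_per_frame = 400 / 30,
                            max_jump_px = 2 * flow_speed_px_per_frame) {
  list(tracks = list(), next_id = 0L, max_jump_px = max_jump_px)
}

#' Should this track fire its measurement now?
#'
#' `TRUE` exactly when the track is unmeasured and its latest mass center
#' has reached the trigger line: either the center crossed the line between
#' the two most recent frames, or the track was first seen already past the
#' line (first-sight fallback).
#'
#' @param track An egg track.
#' @param layout The [build_lane_layout()] with the trigger row.
#' @return Logical flag.
#' @export
check_trigger <- function(track, layout) {
  if (track$measured) return(FALSE)
  n <- nrow(track$history)
  y_now <- track$history$centroid_y[n]
  if (y_now < layout$trigger_y_px) return(FALSE)
  if (n == 1) return(TRUE)  # first sight already past the line
  y_prev <- track$history$centroid_y[n - 1]
  y_prev < layout$trigger_y_px
}

# fire triggers after an update; returns state and the measurements fired
fire_triggers <- function(state, layout, frame_index) {
  fired <- list()
  for (i in seq_along(state$tracks)) {
    tr <- state$tracks[[i]]
    if (!tr$open || tr$last_frame != frame_index) next
    if (check_trigger(tr, layout)) {
      tr$measured <- TRUE
      tr$measurement <- tr$detections[[length(tr$detections)]]
      tr$trigger_frame <- frame_index
      state$tracks[[i]] <- tr
      fired[[length(fired) + 1]] <- tr
    }
  }
  list(state = state, fired = fired)
}

#' Measurements table from a tracking state
#'
#' One row per measured egg, in trigger order.
#'
#' @param state Tracking state after a run.
#' @return Data frame with `track_id`, `lane`, `trigger_frame`, centroid and
#'   the geometric features of the triggering detection.
#' @export
measurements_df <- function(state) {
  ms <- Filter(function(tr) tr$measured, state$tracks)
  if (!length(ms))
    return(data.frame(track_id = integer(0), lane = integer(0),
                      trigger_frame = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), contour_area = numeric(0),
                      perimeter = numeric(0), circle_area = numeric(0),
                      bw_ratio = numeric(0), corrected_area = numeric(0)))
  out <- do.call(rbind, lapply(ms, function(tr) {
    d <- tr$measurement
    data.frame(track_id = tr$track_id, lane = tr$lane,
               trigger_frame = tr$trigger_frame,
               centroid_x = d$centroid_px[1], centroid_y = d$centroid_px[2],
               contour_area = d$contour_area_px2, perimeter = d$perimeter_px,
               circle_area = d$circle_area_px2, bw_ratio = d$bw_ratio,
               corrected_area = d$corrected_area_px2)
  }))
  out[order(out$trigger_frame, out$lane), ]
}

#' Run detection and tracking over a synthetic scene
#'
#' Streams the scene frame by frame (constant memory): render, detect inside
#' the ROI, associate with tracks, fire the trigger-line measurement.
#'
#' @param spec A [scene_spec()].
#' @param config A [detection_config()].
#' @param frames Frame indices to process (default: the whole scene).
#' @param render_roi_only If `TRUE` (default) only the layout ROI — the
#'   part of the frame the detector observes — is rasterized each frame,
#'   which is substantially faster; see the `region` argument of
#'   [render_frame()].
#' @return List with `measurements` (data frame, one row per measured egg)
#'   and `state` (final tracking state).
#' @export
run_scene_pipeline <- function(spec, config = detection_config(),
                               frames = seq_len(spec$n_frames) - 1L,
                               render_roi_only = TRUE) {
  field <- illumination_field(spec$illumination, spec$layout)
  state <- new_track_state(spec$flow_speed_px_per_frame)
  region <- if (render_roi_only) spec$layout$roi else NULL
  for (t in frames) {
    if (render_roi_only) {
      sub <- render_frame(spec, t, field, region = region)
      dets <- .detect_core(sub, spec$layout, config)
    } else {
      fr <- render_frame(spec, t, field)
      dets <- detect_eggs(fr, spec$layout, config)
    }
    state <- update_tracks(state, dets, t, spec$layout)
    state <- fire_triggers(state, spec$layout, t)$state
  }
  list(measurements = measurements_df(state), state = state)
}

#' Run detection and tracking over frames on disk
#'
#' @param frames List of `h x w x 3` arrays or a directory of
#'   `frame_*.png` files (see [read_frames()]).
#' @param layout A [build_lane_layout()].
#' @param config A [detection_config()].
#' @param flow_speed_px_per_frame Expected flow speed (association gate).
#' @return As [run_scene_pipeline()].
#' @export
run_frames_pipeline <- function(frames, layout, config = detection_config(),
                                flow_speed_px_per_frame = 400 / 30) {
  if (is.character(frames)) frames <- read_frames(frames)
  state <- new_track_state(flow_speed_px_per_frame)
  for (t in seq_along(frames) - 1L) {
    dets <- detect_eggs(frames[[t + 1]], layout, config)
    state <- update_tracks(state, dets, t, layout)
    state <- fire_triggers(state, layout, t)$state
  }
  list(measurements = measurements_df(state), state = state)
}

#' Match measurements to the eggs of a synthetic scene
#'
#' Joins each measured track to the simulated egg in the same lane whose
#' trigger-crossing frame is nearest, giving per-egg (measured, true) pairs
#' for calibration and evaluation.
#'
#' @param measurements Data frame from [run_scene_pipeline()].
#' @param spec The [scene_spec()] that produced the frames.
#' @return `measurements` with extra columns `egg_id`, `true_weight_g`,
#'   `true_area_px2`, `true_grade`.
#' @export
match_measurements <- function(measurements, spec) {
  if (!nrow(measurements)) {
    measurements$egg_id <- integer(0)
    measurements$true_weight_g <- numeric(0)
    measurements$true_area_px2 <- numeric(0)
    measurements$true_grade <- integer(0)
    return(measurements)
  }
  cross <- expected_crossings(spec)
  measurements$egg_id <- NA_integer_
  measurements$true_weight_g <- NA_real_
  measurements$true_area_px2 <- NA_real_
  measurements$true_grade <- NA_integer_
  used <- logical(nrow(cross))
  for (i in seq_len(nrow(measurements))) {
    cand <- which(cross$lane == measurements$lane[i] & !used)
    if (!length(cand)) next
    j <- cand[which.min(abs(cross$cross_frame[cand] -
                              measurements$trigger_frame[i]))]
    used[j] <- TRUE
    e <- spec$eggs[[cross$egg_id[j]]]
    measurements$egg_id[i] <- cross$egg_id[j]
    measurements$true_weight_g[i] <- e$true_weight_g
    measurements$true_area_px2[i] <- raster_ellipse_area(
      e$semi_axes_px[1], e$semi_axes_px[2])
    measurements$true_grade[i] <- assign_grade(e$true_weight_g)$grade
  }
  measurements
}

#' Eggs expected to cross the trigger line
#'
#' For each simulated egg, the first frame at which its center is at or past
#' the trigger row (and still inside the frame). The count of rows is the
#' exact number of measurements a correct tracker must fire.
#'
#' @param spec A [scene_spec()].
#' @return Data frame with `egg_id`, `lane`, `cross_frame`.
#' @export
expected_crossings <- function(spec) {
  recs <- lapply(seq_along(spec$eggs), function(i) {
    e <- spec$eggs[[i]]
    # center y at frame t: -b + (t - entry) * v ; first t with y >= trigger
    t_cross <- e$entry_frame +
      ceiling((spec$layout$trigger_y_px + e$semi_axes_px[2]) /
                spec$flow_speed_px_per_frame)
    if (t_cross >= spec$n_frames) return(NULL)
    data.frame(egg_id = i, lane = e$lane, cross_frame = t_cross)
  })
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs))
    return(data.frame(egg_id = integer(0), lane = integer(0),
                      cross_frame = numeric(0)))
  do.call(rbind, recs)
}
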