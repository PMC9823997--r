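test_that("population sampling respects the grade mix and is seed-stable", {
  layout <- build_lane_layout(1280, 720, 4)
  # all mass on grade 2 (L): every weight in (63, 73]
  eggs <- sample_population(40, c(0, 1, 0, 0), seed = 3, layout = layout)
  w <- vapply(eggs, `[[`, numeric(1), "true_weight_g")
  expect_true(all(w > 63 & w <= 73))
  expect_equal(assign_grade(w)$grade, rep(2L, 40))

  expect_equal(sample_population(0, seed = 1, layout = layout), list())
  expect_error(sample_population(5, c(0.5, 0.5), seed = 1), "grade_mix")

  a <- sample_population(25, seed = 99, layout = layout)
  b <- sample_population(25, seed = 99, layout = layout)
  expect_identical(a, b)

  # every projected ellipse fits inside its lane
  for (e in a) {
    bounds <- layout$lane_bounds[e$lane, ]
    cx <- mean(bounds) + e$x_offset_px
    expect_gte(cx - e$semi_axes_px[1], bounds[1])
    expect_lte(cx + e$semi_axes_px[1], bounds[2])
    expect_gte(e$semi_axes_px[1], e$semi_axes_px[2])
  }
})

test_that("projected area tracks weight^(2/3) up to the configured jitter", {
  layout <- build_lane_layout(1280, 720, 4)
  eggs <- sample_population(300, seed = 17, layout = layout)
  w <- vapply(eggs, `[[`, numeric(1), "true_weight_g")
  area <- vapply(eggs, function(e)
    pi * e$semi_axes_px[1] * e$semi_axes_px[2], numeric(1))
  ratio <- area / w^(2 / 3)
  # multiplicative jitter has cv ~ 2% around the default coefficient
  expect_equal(mean(ratio), default_area_coef(), tolerance = 0.01)
  expect_lt(sd(ratio) / mean(ratio), 0.035)
  expect_gt(sd(ratio) / mean(ratio), 0.005)
})

test_that("illumination fields have the stated lane structure", {
  layout <- build_lane_layout(1280, 720, 4)
  multi <- per_lane_illumination(layout)
  single <- single_source_illumination(layout, match_power_of = multi)
  fm <- illumination_field(multi, layout)
  fs <- illumination_field(single, layout)
  # equal total power by construction
  expect_equal(sum(fm), sum(fs), tolerance = 1e-6)
  lm <- lane_mean_intensity(fm, layout)
  ls <- lane_mean_intensity(fs, layout)
  # multi: all lane means equal within 1%
  expect_lt((max(lm) - min(lm)) / mean(lm), 0.01)
  # single: outer lanes strictly dimmer than center lanes
  expect_lt(ls[1], ls[2]); expect_lt(ls[4], ls[3])
  # multi has strictly lower across-lane variance of the lane means
  expect_lt(var(lm), var(ls))
  # fields never exceed the saturation cap
  expect_lte(max(fm), multi$saturation_cap)
  expect_lte(max(fs), single$saturation_cap)

  # zero sources: uniform zero field
  zero <- illumination_spec("multi", data.frame(x_px = numeric(0),
                                                intensity = numeric(0),
                                                spread_px = numeric(0)))
  expect_true(all(illumination_field(zero, layout) == 0))
  expect_error(illumination_spec("multi", data.frame(
    x_px = 1, intensity = -1, spread_px = 10)), "intensities")
})

test_that("rendering is bit-identical for a fixed seed", {
  spec <- one_egg_scene(noise_sd = 4, seed = 123)
  f1 <- render_frame(spec, 5)
  f2 <- render_frame(spec, 5)
  expect_identical(f1, f2)
  seq1 <- render_sequence(spec, 0:3)
  seq2 <- render_sequence(spec, 0:3)
  expect_identical(seq1, seq2)
  # a different seed produces different noise
  spec2 <- one_egg_scene(noise_sd = 4, seed = 124)
  expect_false(identical(render_frame(spec2, 5), f1))
})

test_that("egg kinematics: centroids advance arithmetically at the flow speed", {
  spec <- one_egg_scene()
  tr <- truth_table(spec, 0:9)
  expect_equal(nrow(tr), 10)
  expect_equal(diff(tr$centroid_y),
               rep(spec$flow_speed_px_per_frame, 9), tolerance = 1e-12)
  expect_equal(diff(tr$centroid_x), rep(0, 9))
})

test_that("noise-free flat-lit egg pixels equal the shell colour exactly", {
  layout <- small_layout()
  egg <- egg_spec(60, c(26, 20), lane = 1, entry_frame = 0,
                  shell_color = c(190, 140, 95))
  spec <- scene_spec(layout, list(egg), flat_illumination(layout),
                     noise_sd = 0, seed = 1)
  t <- 8
  fr <- render_frame(spec, t)
  ctr <- truth_table(spec, t)
  m <- oracle_ellipse_mask(layout$frame_height_px, layout$frame_width_px,
                           ctr$centroid_x, ctr$centroid_y, 26, 20)
  for (k in 1:3) {
    ch <- fr[, , k]
    expect_true(all(ch[m == 1] == egg$shell_color[k]))
    expect_true(all(ch[m == 0] == spec$background_rgb[k]))
  }
  # the truth area equals the rendered pixel count exactly
  expect_equal(ctr$true_area_px2, sum(m))
})

test_that("rasterized truth area stays within 1.5% of the analytic ellipse area", {
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 45, 66); b <- runif(1, 35, 50)
    cx <- runif(1, 0, 1); cy <- runif(1, 0, 1)
    expect_equal(raster_ellipse_area(a, b, cx, cy), pi * a * b,
                 tolerance = 0.015)
  }
  # oracle agreement at a small size where the loop is affordable
  expect_equal(raster_ellipse_area(26, 20, 40.3, 30.7),
               sum(oracle_ellipse_mask(64, 96, 40.3, 30.7, 26, 20)))
})

test_that("each egg contributes one truth record per visible frame, consecutively", {
  layout <- build_lane_layout(1280, 720, 4)
  eggs <- sample_population(12, seed = 5, layout = layout)
  spec <- scene_spec(layout, eggs, seed = 5)
  tr <- truth_table(spec)
  for (id in unique(tr$egg_id)) {
    frames <- tr$frame_index[tr$egg_id == id]
    expect_equal(frames, seq(min(frames), max(frames)))  # consecutive
    expect_equal(anyDuplicated(frames), 0)
    e <- spec$eggs[[id]]
    # visibility span: from entry until the ellipse has fully left the frame
    expect_equal(min(frames), e$entry_frame)
    n_vis <- ceiling((layout$frame_height_px + 2 * e$semi_axes_px[2]) /
                       spec$flow_speed_px_per_frame)
    expect_lte(abs(length(frames) - n_vis), 1)
  }
})

test_that("same-lane overlap is rejected by the renderer", {
  layout <- small_layout()
  e1 <- egg_spec(60, c(26, 20), lane = 1, entry_frame = 0)
  e2 <- egg_spec(60, c(26, 20), lane = 1, entry_frame = 1)  # 13 px behind
  spec <- scene_spec(layout, list(e1, e2), flat_illumination(layout),
                     noise_sd = 0, seed = 1)
  expect_error(render_frame(spec, 5), "overlap")
  # same spacing in different lanes is fine
  e2b <- egg_spec(60, c(26, 20), lane = 2, entry_frame = 1)
  spec2 <- scene_spec(layout, list(e1, e2b), flat_illumination(layout),
                      noise_sd = 0, seed = 1)
  expect_silent(render_frame(spec2, 5))
})

test_that("scenes round-trip through PNG frames and truth manifests", {
  skip_if_not_installed("png")
  spec <- one_egg_scene(noise_sd = 3, seed = 9)
  dir <- withr::local_tempdir()
  write_scene(spec, dir, frames = 0:2)
  files <- list.files(dir)
  expect_true(all(c("frame_000000.png", "frame_000002.png",
                    "truth.jsonl", "truth.csv") %in% files))
  back <- read_frames(dir)
  expect_length(back, 3)
  # 8-bit quantization: within half an intensity step
  expect_lt(max(abs(back[[1]] - render_frame(spec, 0))), 0.51)
  # JSONL manifest parses line by line into the truth records
  lines <- readLines(file.path(dir, "truth.jsonl"))
  truth <- truth_table(spec, 0:2)
  expect_length(lines, nrow(truth))
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$true_weight_g, truth$true_weight_g[1])
  csv <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(csv), nrow(truth))
})
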