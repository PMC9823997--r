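test_that("RGB to HSV matches the closed form and the grDevices oracle", {
  px <- function(r, g, b) {
    fr <- array(c(r, g, b), c(1, 1, 3))
    to_hsv(fr)[1, 1, ]
  }
  expect_equal(unname(px(255, 0, 0)), c(0, 1, 1))
  expect_equal(unname(px(128, 128, 128)), c(0, 0, 128 / 255))
  expect_equal(unname(px(255, 128, 0))[1], 30.1, tolerance = 0.1)

  set.seed(21)
  rgb <- matrix(sample(0:255, 300, replace = TRUE), nrow = 3)
  fr <- array(t(rgb), c(100, 1, 3))
  got <- to_hsv(fr)
  ref <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  expect_equal(as.numeric(got[, 1, 1]), unname(ref["h", ]) * 360,
               tolerance = 1e-9)
  expect_equal(as.numeric(got[, 1, 2]), unname(ref["s", ]), tolerance = 1e-9)
  expect_equal(as.numeric(got[, 1, 3]), unname(ref["v", ]), tolerance = 1e-9)

  expect_error(to_hsv(matrix(0, 4, 4)), "RGB")
})

test_that("smoothing cascade: identity, impulse response, mean conservation", {
  cfg3 <- detection_config(box_kernel_px = 3, gauss_kernel_px = 1)
  const <- matrix(7, 20, 20)
  expect_equal(smooth_image(const, detection_config()), const)
  # 3x3 box on a centered impulse spreads value/9 over the 9-neighbourhood
  imp <- matrix(0, 11, 11); imp[6, 6] <- 9
  sm <- smooth_image(imp, cfg3)
  expect_equal(sm[5:7, 5:7], matrix(1, 3, 3))
  expect_true(all(sm[-(5:7), ] == 0))
  # kernel 1 is the identity
  id_cfg <- detection_config(box_kernel_px = 1, gauss_kernel_px = 1)
  set.seed(2)
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_identical(smooth_image(img, id_cfg), img)
  # smoothing conserves the interior of a linear ramp exactly, hence the
  # interior mean to well within 0.5 intensity
  ramp <- outer(seq(0, 255, length.out = 40), seq(0, 1, length.out = 40), "*")
  smr <- smooth_image(ramp, detection_config())
  expect_lt(abs(mean(smr[9:32, 9:32]) - mean(ramp[9:32, 9:32])), 0.5)
  expect_equal(smr[9:32, 9:32], ramp[9:32, 9:32], tolerance = 1e-9)
  expect_error(detection_config(box_kernel_px = 4), "odd")
})

test_that("background masking honours the range, including hue wrap", {
  layout <- small_layout()
  # all pixels inside the range -> all ones
  hsv <- array(c(matrix(30, 4, 4), matrix(0.5, 4, 4), matrix(0.8, 4, 4)),
               c(4, 4, 3))
  expect_true(all(background_mask(hsv) == 1))
  # wrap range 350..10 classifies hue 5 as foreground, hue 180 as background
  cfgw <- detection_config(hsv_lo = c(350, 0, 0), hsv_hi = c(10, 1, 1))
  hsv[, , 1] <- 5
  expect_true(all(background_mask(hsv, cfgw) == 1))
  hsv[, , 1] <- 180
  expect_true(all(background_mask(hsv, cfgw) == 0))
})

test_that("masking a clean synthetic egg recovers its pixels (recall >= 0.99)", {
  layout <- small_layout()
  spec <- one_egg_scene(noise_sd = 0)
  t <- 8
  fr <- render_frame(spec, t)
  ctr <- truth_table(spec, t)
  truth <- oracle_ellipse_mask(layout$frame_height_px, layout$frame_width_px,
                               ctr$centroid_x, ctr$centroid_y, 26, 20)
  mask <- background_mask(smooth_image(to_hsv(fr)), detection_config())
  recall <- sum(mask == 1 & truth == 1) / sum(truth == 1)
  expect_gte(recall, 0.99)
})

test_that("the fused detection front end equals the documented composition", {
  spec <- one_egg_scene(noise_sd = 4, seed = 31)
  fr <- render_frame(spec, 8)
  cfg <- detection_config()
  chain <- eggline:::cpp_chain_mask(fr, cfg$hsv_lo, cfg$hsv_hi,
                                    cfg$box_kernel_px, cfg$gauss_kernel_px,
                                    cfg$gauss_sigma)
  hsv_sm <- smooth_image(to_hsv(fr), cfg)
  expect_equal(chain$v_smooth, hsv_sm[, , 3], tolerance = 1e-12)
  expect_equal(matrix(as.integer(background_mask(hsv_sm, cfg)),
                      nrow(chain$mask)),
               matrix(as.integer(chain$mask), nrow(chain$mask)))
})

test_that("Otsu separates a bimodal histogram and respects degenerate input", {
  x <- c(rep(20, 500), rep(200, 300))
  thr <- otsu_threshold(x)
  expect_gte(thr, 20); expect_lt(thr, 200)  # foreground is > threshold
  expect_true(all((x > thr) == (x == 200)))
  expect_equal(otsu_threshold(numeric(0)), 0)
})

test_that("contour extraction: cardinality, areas and the pixel-count oracle", {
  cfg <- detection_config(min_contour_area_px2 = 20)
  expect_length(extract_contours(matrix(0L, 30, 30), cfg), 0)
  # two disjoint filled ellipses -> two contours, sorted by decreasing area
  m <- oracle_ellipse_mask(60, 120, 25, 30, 16, 11) +
    oracle_ellipse_mask(60, 120, 85, 30, 10, 7)
  cts <- extract_contours(m, cfg)
  expect_length(cts, 2)
  expect_gt(cts[[1]]$area, cts[[2]]$area)
  expect_equal(cts[[1]]$n_pixels, sum(oracle_ellipse_mask(60, 120, 25, 30, 16, 11)))
  # filled 10x10 square: tracing follows pixel centers, so the polygon area
  # is bounded by the brute-force pixel count and 9x9; both are asserted
  sq <- matrix(0L, 20, 20); sq[6:15, 4:13] <- 1L
  ct <- extract_contours(sq, cfg)
  expect_length(ct, 1)
  expect_equal(ct[[1]]$n_pixels, 100)
  expect_equal(ct[[1]]$area, 81)  # (10-1)^2: center-to-center polygon
  expect_lte(abs(ct[[1]]$area - 100), 100 - 81 + 1e-9)
  # min-area filter drops small specks
  speck <- matrix(0L, 30, 30); speck[4:5, 4:5] <- 1L
  expect_length(extract_contours(speck, cfg), 0)
})

test_that("minimum enclosing circle: worked examples and defining property", {
  # two points 2r apart
  mec <- min_enclosing_circle(rbind(c(0, 0), c(6, 0)))
  expect_equal(mec$center, c(3, 0))
  expect_equal(mec$radius, 3)
  # unit square corners: circumscribed circle
  mec2 <- min_enclosing_circle(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(mec2$center, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(mec2$radius, sqrt(2) / 2, tolerance = 1e-9)
  expect_error(min_enclosing_circle(matrix(numeric(0), 0, 2)), "at least one")
  # defining property + order invariance on random point clouds
  set.seed(8)
  for (i in 1:20) {
    pts <- matrix(rnorm(40), ncol = 2)
    m <- min_enclosing_circle(pts)
    d <- sqrt((pts[, 1] - m$center[1])^2 + (pts[, 2] - m$center[2])^2)
    expect_lte(max(d), m$radius + 1e-6)
    m2 <- min_enclosing_circle(pts[sample(nrow(pts)), ])
    expect_equal(m2$radius, m$radius, tolerance = 1e-9)
    expect_equal(m2$center, m$center, tolerance = 1e-6)
  }
})

test_that("minimum enclosing circle is minimal (brute force, <= 12 points)", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    pts <- matrix(round(rnorm(2 * n, 0, 10), 2), ncol = 2)
    fast <- min_enclosing_circle(pts)
    slow <- oracle_mec(unique(pts))
    expect_equal(fast$radius, slow$radius, tolerance = 1e-7)
  }
})

test_that("measure_egg satisfies its pixel-count and geometry invariants", {
  cfg <- detection_config(min_contour_area_px2 = 50)
  m <- oracle_ellipse_mask(80, 100, 50.3, 40.6, 30, 22)
  ct <- extract_contours(m, cfg)[[1]]
  det <- measure_egg(m, ct, cfg)
  # all contour vertices inside or on the circle
  d <- sqrt((det$contour[, 1] - det$circle_center_px[1])^2 +
              (det$contour[, 2] - det$circle_center_px[2])^2)
  expect_lte(max(d), det$circle_radius_px + 1e-6)
  expect_lte(det$contour_area_px2, det$circle_area_px2)
  expect_gte(det$bw_ratio, 0); expect_lte(det$bw_ratio, 1)
  # counts agree exactly with the naive per-pixel oracle
  oc <- oracle_disk_counts(m, det$circle_center_px[1],
                           det$circle_center_px[2], det$circle_radius_px)
  expect_equal(det$zero_px + det$nonzero_px, unname(oc["total"]))
  expect_equal(det$nonzero_px, unname(oc["nonzero"]))
  expect_equal(det$zero_px, unname(oc["zero"]))
  # clean convex silhouette: corrected area within 2% of the truth
  expect_equal(det$corrected_area_px2, sum(m), tolerance = 0.02)
  # degenerate contour is rejected with a message
  tiny <- list(points = rbind(c(1, 1)), area = 0, perimeter = 0,
               n_pixels = 1, centroid = c(x = 1, y = 1), label = 1)
  expect_message(res <- measure_egg(m, tiny, cfg), "degenerate")
  expect_null(res)
})

test_that("a full disk yields bw_ratio 1 and corrected area = circle area", {
  cfg <- detection_config(min_contour_area_px2 = 50)
  m <- oracle_ellipse_mask(60, 60, 30, 30, 20, 20)  # a circle
  ct <- extract_contours(m, cfg)[[1]]
  det <- measure_egg(m, ct, cfg)
  expect_equal(det$bw_ratio, 1)
  expect_equal(det$corrected_area_px2, det$zero_px + det$nonzero_px)
  expect_equal(det$corrected_area_px2, det$circle_area_px2, tolerance = 0.02)
})

test_that("interior dirt barely moves the corrected area but drops the raw count", {
  cfg <- detection_config(min_contour_area_px2 = 50)
  clean <- oracle_ellipse_mask(90, 110, 55.2, 45.1, 32, 24)
  dirty <- clean
  # a dirt hole fully inside the silhouette
  hole <- oracle_ellipse_mask(90, 110, 48, 40, 6, 6)
  dirty[hole == 1] <- 0L
  ct_c <- extract_contours(clean, cfg)[[1]]
  ct_d <- extract_contours(dirty, cfg)[[1]]
  det_c <- measure_egg(clean, ct_c, cfg)
  det_d <- measure_egg(dirty, ct_d, cfg)
  expect_lt(det_d$nonzero_px, det_c$nonzero_px)  # raw count drops
  expect_lt(abs(det_d$corrected_area_px2 - det_c$corrected_area_px2) /
              det_c$corrected_area_px2, 0.01)    # corrected area stable
})

test_that("boundary-touching dirt: corrected area beats the raw contour area", {
  cfg <- detection_config(min_contour_area_px2 = 50)
  truth_mask <- oracle_ellipse_mask(90, 110, 55.2, 45.1, 32, 24)
  truth_area <- sum(truth_mask)
  set.seed(33)
  for (i in 1:5) {
    # dirt disk centered on the silhouette boundary
    th <- runif(1, 0, 2 * pi)
    dx <- 32 * cos(th); dy <- 24 * sin(th)
    bite <- oracle_ellipse_mask(90, 110, 55.2 + dx, 45.1 + dy, 7, 7)
    dirty <- truth_mask; dirty[bite == 1] <- 0L
    ct <- extract_contours(dirty, cfg)[[1]]
    det <- measure_egg(dirty, ct, cfg)
    err_contour <- abs(det$contour_area_px2 - truth_area)
    err_corrected <- abs(det$corrected_area_px2 - truth_area)
    expect_lt(err_corrected, err_contour)
  }
})

test_that("corrected area scales as k^2 when the silhouette is scaled by k", {
  cfg <- detection_config(min_contour_area_px2 = 50)
  base <- c(a = 24, b = 18)
  area_at <- function(k) {
    m <- oracle_ellipse_mask(round(130 * k) + 20, round(150 * k) + 20,
                             (150 * k) / 2, (130 * k) / 2,
                             base["a"] * k, base["b"] * k)
    det <- measure_egg(m, extract_contours(m, cfg)[[1]], cfg)
    det$corrected_area_px2
  }
  a1 <- area_at(1)
  for (k in c(0.5, 2)) {
    expect_equal(area_at(k) / a1, k^2, tolerance = 0.02)
  }
})

test_that("detect_eggs runs the whole chain and assigns lanes", {
  layout <- build_lane_layout(1280, 720, 4)
  eggs <- sample_population(4, seed = 7, layout = layout)
  spec <- scene_spec(layout, eggs, seed = 3)
  fr <- render_frame(spec, 30)
  dets <- detect_eggs(fr, layout)
  expect_length(dets, 4)
  expect_setequal(vapply(dets, `[[`, integer(1), "lane"), 1:4)
  truth <- truth_table(spec, 30)
  for (d in dets) {
    tr <- truth[truth$lane == d$lane, ]
    expect_equal(unname(d$centroid_px[1]), tr$centroid_x, tolerance = 0.01)
    expect_equal(unname(d$centroid_px[2]), tr$centroid_y, tolerance = 0.01)
    expect_equal(d$corrected_area_px2, tr$true_area_px2, tolerance = 0.02)
  }
  # background-only frame -> no detections
  bg <- render_frame(spec, spec$n_frames - 1)
  expect_length(detect_eggs(bg, layout), 0)
  expect_error(detect_eggs(fr[1:10, 1:10, , drop = FALSE], layout),
               "dimensions")
})
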