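# Shared fixtures and independent oracles. Everything here is deliberately
# naive (per-pixel loops, exhaustive search) so that it can stand against the
# package's optimized implementations.

# small two-lane layout for cheap rendered tests
small_layout <- function(w = 320, h = 240, n = 2, trigger = 0.5)
  build_lane_layout(w, h, n, trigger)

# brute-force rasterized ellipse mask (pixel centers), independent of the
# renderer: 1 where ((x-cx)/a)^2 + ((y-cy)/b)^2 <= 1
oracle_ellipse_mask <- function(h, w, cx, cy, a, b) {
  m <- matrix(0L, h, w)
  for (y in 0:(h - 1))
    for (x in 0:(w - 1))
      if (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1) m[y + 1, x + 1] <- 1L
  m
}

# exhaustive minimum enclosing circle: best circle over all pairs and triples
oracle_mec <- function(pts) {
  n <- nrow(pts)
  covers <- function(c, r) all(sqrt((pts[, 1] - c[1])^2 +
                                      (pts[, 2] - c[2])^2) <= r + 1e-9)
  best <- list(center = pts[1, ], radius = Inf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    c <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best$radius && covers(c, r)) best <- list(center = c, radius = r)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (k <= j || j <= i) next
    p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
    d <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) +
                s[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(p^2) * (q[2] - s[2]) + sum(q^2) * (s[2] - p[2]) +
             sum(s^2) * (p[2] - q[2])) / d
    uy <- (sum(p^2) * (s[1] - q[1]) + sum(q^2) * (p[1] - s[1]) +
             sum(s^2) * (q[1] - p[1])) / d
    r <- sqrt(sum((p - c(ux, uy))^2))
    if (r < best$radius && covers(c(ux, uy), r))
      best <- list(center = c(ux, uy), radius = r)
  }
  best
}

# naive per-pixel disk counts over the bounding box (the oracle for the
# optimized counting in measure_egg)
oracle_disk_counts <- function(mask, cx, cy, r) {
  h <- nrow(mask); w <- ncol(mask)
  total <- 0L; nonzero <- 0L
  for (y in 0:(h - 1))
    for (x in 0:(w - 1))
      if ((x - cx)^2 + (y - cy)^2 <= r^2 + 1e-9) {
        total <- total + 1L
        if (mask[y + 1, x + 1] != 0) nonzero <- nonzero + 1L
      }
  c(total = total, nonzero = nonzero, zero = total - nonzero)
}

# flat RGB frame with one hard-edged ellipse, no illumination or noise
flat_egg_frame <- function(h, w, cx, cy, a, b,
                           shell = c(190, 140, 95), bg = c(26, 26, 26)) {
  m <- oracle_ellipse_mask(h, w, cx, cy, a, b)
  fr <- array(0, c(h, w, 3))
  for (k in 1:3) fr[, , k] <- ifelse(m == 1, shell[k], bg[k])
  fr
}

# a clean single-egg scene on the small layout
one_egg_scene <- function(weight = 60, axes = c(26, 20), lane = 1,
                          noise_sd = 0, seed = 1,
                          layout = small_layout(), dirt = empty_dirt()) {
  egg <- egg_spec(weight, axes, lane = lane, entry_frame = 0,
                  dirt_spots = dirt)
  scene_spec(layout, list(egg), flat_illumination(layout),
             noise_sd = noise_sd, seed = seed)
}
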