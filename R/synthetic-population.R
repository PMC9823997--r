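#' One synthetic egg
#'
#' Describes a single ellipsoidal egg on the conveyor: its true weight, the
#' semi-axes of its projected ellipse in pixels (`a` across the flow, along
#' the roller axis; `b` along the flow; `a >= b`), the flow lane it travels
#' in, the frame at which its center enters the top of the frame, its shell
#' colour, and any dirt spots (offsets relative to the egg center, in px).
#'
#' @param true_weight_g Positive weight in grams.
#' @param semi_axes_px Length-2 numeric `c(a, b)` with `a >= b > 0`.
#' @param lane Lane index (1-based).
#' @param entry_frame Frame index (0-based) at which the egg center crosses
#'   y = -b (just above the frame).
#' @param shell_color RGB triple in 0..255.
#' @param dirt_spots Data frame with columns `dx`, `dy` (offset from the egg
#'   center, px), `radius_px`, `darkness` (reflectance multiplier in (0, 1)).
#' @param x_offset_px Horizontal offset of the egg from its lane center.
#' @return An object of class `egg_spec`.
#' @export
egg_spec <- function(true_weight_g, semi_axes_px, lane = 1L, entry_frame = 0L,
                     shell_color = c(190, 140, 95),
                     dirt_spots = empty_dirt(), x_offset_px = 0) {
  if (true_weight_g <= 0) stop("`true_weight_g` must be positive")
  if (length(semi_axes_px) != 2 || any(semi_axes_px <= 0) ||
      semi_axes_px[1] < semi_axes_px[2])
    stop("`semi_axes_px` must be c(a, b) with a >= b > 0")
  structure(list(
    true_weight_g = true_weight_g,
    semi_axes_px = as.numeric(semi_axes_px),
    lane = as.integer(lane),
    entry_frame = as.integer(entry_frame),
    shell_color = as.numeric(shell_color),
    dirt_spots = dirt_spots,
    x_offset_px = x_offset_px
  ), class = "egg_spec")
}

#' @rdname egg_spec
#' @export
empty_dirt <- function() {
  data.frame(dx = numeric(0), dy = numeric(0), radius_px = numeric(0),
             darkness = numeric(0))
}

#' Projected ellipse area implied by an egg weight
#'
#' Isometric scaling: projected area scales as weight to the 2/3 power,
#' \eqn{A = c\,m^{2/3}}. The default coefficient corresponds to a 60 g egg
#' of 45 mm minor diameter imaged at 2 px/mm with a 1.3 length-to-width
#' shape ratio (about 8270 px^2).
#'
#' @param weight_g Weight(s) in grams.
#' @param area_coef_px2 Coefficient `c` in px^2 per g^(2/3).
#' @return Projected area in px^2.
#' @export
area_from_weight <- function(weight_g, area_coef_px2 = default_area_coef()) {
  area_coef_px2 * weight_g^(2 / 3)
}

#' @rdname area_from_weight
#' @export
default_area_coef <- function(px_per_mm = 2, ref_weight_g = 60,
                              ref_minor_diameter_mm = 45, shape_ratio = 1.3) {
  b <- ref_minor_diameter_mm / 2 * px_per_mm
  a <- shape_ratio * b
  pi * a * b / ref_weight_g^(2 / 3)
}

#' Sample a synthetic egg population
#'
#' Draws `n_eggs` eggs with grade labels from `grade_mix` (probabilities
#' over grades 1 "XL" to 4 "S"), weights uniform within each grade's band
#' (the open-ended bands are capped: S at 45 g below, XL at 85 g above),
#' projected areas proportional to weight^(2/3) with log-normal shape
#' jitter, lanes assigned round-robin, and entry frames staggered so eggs
#' within a lane never touch.
#'
#' @param n_eggs Number of eggs (>= 0).
#' @param grade_mix Probabilities over grades 1:4, summing to 1.
#' @param seed Integer seed; the same seed reproduces the same population.
#' @param layout A [build_lane_layout()]; eggs are spread over its lanes.
#' @param shape_jitter_cv Coefficient of variation of the multiplicative
#'   area jitter (default 0.02).
#' @param shape_ratio Egg length-to-width ratio a/b (default 1.3).
#' @param area_coef_px2 Area coefficient, see [area_from_weight()].
#' @param entry_spacing_frames Frames between successive entries in one lane.
#' @param dirt_rate Mean number of dirt spots per egg (Poisson).
#' @param dirt_radius_px Range of dirt-spot radii.
#' @param dirt_darkness Range of dirt reflectance multipliers.
#' @param shell_color Base shell RGB; each egg varies by +-10 per channel.
#' @return List of [egg_spec()] objects.
#' @export
sample_population <- function(n_eggs, grade_mix = c(0.25, 0.25, 0.25, 0.25),
                              seed = 1L,
                              layout = build_lane_layout(1280, 720, 4),
                              shape_jitter_cv = 0.02, shape_ratio = 1.3,
                              area_coef_px2 = default_area_coef(),
                              entry_spacing_frames = 12,
                              dirt_rate = 1.0, dirt_radius_px = c(4, 12),
                              dirt_darkness = c(0.2, 0.5),
                              shell_color = c(190, 140, 95)) {
  if (length(grade_mix) != 4 || any(grade_mix < 0) || sum(grade_mix) == 0)
    stop("`grade_mix` must be 4 non-negative probabilities")
  grade_mix <- grade_mix / sum(grade_mix)
  if (n_eggs == 0) return(list())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # weight bands per grade 1..4; open ends capped at 85 g (XL) and 45 g (S)
  lo <- c(73, 63, 53, 45); hi <- c(85, 73, 63, 53)
  grades <- sample.int(4, n_eggs, replace = TRUE, prob = grade_mix)
  weights <- stats::runif(n_eggs, lo[grades], hi[grades])
  sdlog <- sqrt(log(1 + shape_jitter_cv^2))
  jitter <- exp(stats::rnorm(n_eggs, -sdlog^2 / 2, sdlog))
  areas <- area_from_weight(weights, area_coef_px2) * jitter
  b <- sqrt(areas / (pi * shape_ratio))
  a <- shape_ratio * b
  lanes <- rep(seq_len(layout$n_lanes), length.out = n_eggs)
  slot <- (seq_len(n_eggs) - 1) %/% layout$n_lanes
  entry <- slot * entry_spacing_frames + (lanes - 1) * 3L
  eggs <- vector("list", n_eggs)
  for (i in seq_len(n_eggs)) {
    ndirt <- stats::rpois(1, dirt_rate)
    dirt <- if (ndirt > 0) {
      theta <- stats::runif(ndirt, 0, 2 * pi)
      frac <- stats::runif(ndirt, 0, 1.05)  # > 1 allows boundary-touching dirt
      data.frame(dx = frac * a[i] * cos(theta),
                 dy = frac * b[i] * sin(theta),
                 radius_px = stats::runif(ndirt, dirt_radius_px[1],
                                          dirt_radius_px[2]),
                 darkness = stats::runif(ndirt, dirt_darkness[1],
                                         dirt_darkness[2]))
    } else empty_dirt()
    col <- pmin(255, pmax(0, shell_color + stats::runif(3, -10, 10)))
    lane_w <- diff(layout$lane_bounds[lanes[i], ])
    max_off <- max(0, (lane_w - 2 * a[i]) / 2 - 4)
    eggs[[i]] <- egg_spec(
      true_weight_g = weights[i],
      semi_axes_px = c(a[i], b[i]),
      lane = lanes[i],
      entry_frame = entry[i],
      shell_color = col,
      dirt_spots = dirt,
      x_offset_px = stats::runif(1, -min(10, max_off), min(10, max_off))
    )
  }
  eggs
}
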