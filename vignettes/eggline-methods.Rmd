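---
title: "Camera-based egg grading: models, synthetic scenes and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based egg grading: models, synthetic scenes and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggline)
```

`eggline` models an industrial egg-grading station: a colour camera mounted
above a four-lane roller conveyor inside an illumination cabinet. Eggs
travel single-file down each lane; when an egg's mass centre crosses a
fixed trigger row in the image, its silhouette is measured once and its
weight and EU grade are predicted from that single measurement. This
vignette explains the underlying models, the tunable parameters, what the
synthetic-scene generator does and does not emulate, and the numerical and
design decisions that were genuinely open.

## 1. Camera geometry

For a pinhole camera, an image-plane dimension $w$ at focal length $f$
subtends $\alpha = 2\,\mathrm{atan}\!\left(\frac{w}{2f}\right)$. Lens
vendors quote the *diagonal* field of view; with an aspect ratio
$w\!:\!h$ the diagonal is $d=\sqrt{w^2+h^2}$ in aspect units, so
$f = \frac{d}{2}\cot\frac{\alpha_d}{2}$ recovers the focal length in the
same units and the horizontal/vertical angles follow by re-applying the
half-angle relation to $w$ and $h$. For a 78° 16:9 lens this yields
HFoV 70.43° and VFoV 43.31°:

```{r}
camera_model(78, c(16, 9))
```

A note on conventions: one sometimes sees the FoV written without the
factor 2 in the denominator ($2\arctan(d/f)$). Only the
$2\arctan\!\big(\tfrac{d}{2f}\big)$ convention is self-consistent — it is
the one under which the three angles above belong to a single focal length
— so it is used throughout.

The frame (default 1280 × 720 px) is divided into `n_lanes` contiguous
half-open pixel intervals `[x_lo, x_hi)` by `build_lane_layout()`. Pixel
coordinates are 0-based with the origin at the top-left corner, x to the
right, y downward; eggs flow in +y. The trigger row defaults to mid-frame
(`trigger_fraction = 0.5`): the source system specifies only that
measurement happens when the mass centre passes an "input line", not where
that line is, and mid-ROI maximizes the margin to both ROI edges.

## 2. The detection chain

Per frame, inside the measurement ROI:

1. **RGB → HSV.** Hue in degrees [0, 360), saturation and value in [0, 1].
2. **Smoothing.** Normalized box filter then Gaussian filter, in that
   order, channel-wise, with replicated borders. Defaults 5 × 5 box,
   5 × 5 Gaussian with σ = 1.5 px — enough to suppress the default sensor
   noise (sd 4 intensity units) without moving the silhouette edge by more
   than a fraction of a pixel.
3. **Background removal.** A single HSV box `[hsv_lo, hsv_hi]` keeps shell
   pixels; hue ranges with `lo > hi` wrap through 0° because red/brown
   shells straddle the hue origin. No published range exists — it is
   scene-specific — so the defaults (H 5–60°, S ≥ 0.15, V ≥ 0.40) target
   the synthetic brown-shell palette, and real imagery must set its own
   range in the configuration. The V lower bound is deliberately placed
   near the midpoint of the background and shell values: the smoothing
   step blends edge pixels between the two, and a mid-level threshold
   leaves the recovered silhouette boundary approximately unbiased.
4. **Thresholding.** Otsu's method on the masked grayscale (smoothed V),
   or a fixed threshold. On a well-separated scene this is nearly a no-op
   after the HSV mask; it is kept because it is part of the processing
   chain being modelled, and it matters when the mask passes dim clutter.
5. **Contours.** 8-connected components of at least
   `min_contour_area_px2` (default 500 px², well below any egg and above
   noise specks) are traced with Moore boundary following. The contour
   area is the shoelace (Green's theorem) polygon area of the traced
   boundary, which runs through pixel *centers* and therefore
   underestimates the pixel count by roughly half the perimeter; the test
   suite bounds this discrepancy against brute-force pixel counting.
6. **Minimum enclosing circle and pixel counts.** Welzl's algorithm gives
   the smallest circle containing the contour. Inside that disk the mask's
   zero and non-zero pixels are counted exactly
   (`zero_px + nonzero_px = |disk|`), giving
   `bw_ratio = nonzero / (zero + nonzero)`.

### The dirt correction

Dirt stains are darker than shell and drop out of the HSV mask, so a dirty
egg's raw contour and raw pixel count both under-measure the silhouette —
worst when a stain touches the boundary and bites into the outline. The
published description of the final output ("ratio of the determined
contour area and the zero-pixel rate") is ambiguous, so the corrected
measurement is a design decision of this package:

> `corrected_area_px2` = number of pixels inside the enclosing circle that
> are either mask foreground or lie within the **convex hull** of the
> foreground.

Egg silhouettes are convex, so interior dirt holes *and* boundary bites
are both concavities, and convex restoration cancels both. A plain
morphological hole fill was considered and rejected: a boundary bite is
connected to the outside background, is not a topological hole, and would
survive filling — plain hole-filling cannot beat the raw contour area on
exactly the failure mode the enclosing-circle step exists to fix. The test
suite asserts strict improvement of `corrected_area` over `contour_area`
for boundary-touching dirt, and stability (< 1%) under interior dirt.

## 3. Flow tracking and the exactly-once trigger

Detections are associated frame-to-frame by greedy nearest-neighbour
matching, gated by lane membership and by `max_jump_px` (default twice the
per-frame flow displacement). Single-file lane flow makes anything
heavier-duty unnecessary. A track fires its one measurement when its
latest centroid reaches the trigger row having been above it the frame
before; a track first seen already past the row fires on first sight, so
eggs entering the ROI beyond the line are still measured exactly once.
Tracks unseen for more than two frames past the ROI exit are closed. The
invariant — fired measurements ≡ simulated trigger crossings — is checked
exactly in the acceptance suite over 20 × 100 eggs.

## 4. Weight calibration and grading

Weight is predicted by ordinary least squares from `corrected_area`
(optionally plus perimeter). OLS matches the linear size–weight
correlation the application reports; nothing nonlinear is warranted by a
single geometric feature. The data are split 67% train / 33% test with a
seeded random split, and R² is reported on both portions. Lane position is
deliberately *excluded* from the default feature set: position predicts
nothing about mass and would let the model absorb per-lane illumination
bias instead of exposing it.

Grades follow the EU bands: XL > 73 g, 63 < L ≤ 73, 53 < M ≤ 63, S ≤ 53.
The printed standard leaves exactly 53 g unassigned ("< 53" vs "> 53");
S is defined here as ≤ 53 g so the bands partition the positive axis.

`evaluate_grading()` reports R² (as $1 - SS_{res}/SS_{tot}$), the mean
absolute percentage error, and two per-grade notions of accuracy that must
not be conflated:

* **measurement accuracy** = 100 − mean |% error| of predicted weight,
  per true grade — ≈ 97–98% in the default synthetic regime;
* **classification accuracy** = fraction of eggs whose predicted grade
  equals their true grade — structurally lower (~85%) when weights are
  sampled *uniformly within bands*, because a uniform population puts many
  eggs within one prediction-σ of a band boundary. A physical test with a
  few mid-band reference eggs would show ~100% here; the synthetic
  population is intentionally harder.

## 5. The synthetic conveyor scene

The generator emulates the statistical structure the pipeline relies on:

* **Geometry/kinematics.** 1280 × 720 px frames, 4 lanes, constant flow.
  Pixel scale 2 px/mm (a 60 g egg of ~45 mm minor diameter spans ~90 px);
  0.2 m/s at 30 fps is then 13.33 px/frame. All are configurable.
* **Population.** Grade mix over the four bands; weights uniform within
  each band (open ends capped at 45 g and 85 g, the practical range of
  retail chicken eggs); projected area $\propto$ weight$^{2/3}$
  (isometric scaling) with log-normal shape jitter of CV 2% — the
  irreducible biological scatter of the area→weight relation; shape ratio
  a/b = 1.3.
* **Dirt.** Poisson-count (mean 1.0) darker disks, radius 4–12 px,
  reflectance multiplier 0.2–0.5, placed uniformly with radial overshoot
  up to 1.05 so stains may touch the silhouette boundary — deliberately,
  because that is the failure mode the circle correction addresses.
* **Illumination.** Flat-top super-Gaussian lobes
  $I\exp(-((x-x_0)/s)^4)$ across the frame width, constant along the
  flow. *Multi* mode: one lobe per lane centre, spread 0.41 × lane width
  (lane means then agree within 1%). *Single* mode: one central lobe,
  spread 0.51 × frame width, scaled to the same total power — centre
  lanes bright, outer lanes ~25% dimmer. Under the mid-level V threshold,
  dimmer lanes lose more blended edge pixels, so single-source lighting
  inflates the across-lane dispersion of the area error; the suite
  asserts the direction (multi < single), which the synthetic experiment
  reproduces by an order of magnitude.
* **Noise.** Achromatic Gaussian noise (sd 4 on the 0–255 scale) added to
  all three channels and clipped — sensor noise is luminance-dominated,
  and a single field per frame halves the rendering cost.
* **Truth.** Per frame and egg: centre, weight, grade, and the *rasterized*
  ellipse area (lattice points inside the ellipse at the frame's subpixel
  position) — exactly the pixels the renderer paints, so detector accuracy
  is measured against the drawable truth, not against $\pi ab$ (from which
  the raster count differs by well under 0.1%).

What a green test does **not** establish: performance on real shells
(specular highlights, translucency, shadow between rollers), motion blur,
egg-to-egg contact, cracked or leaking eggs, lens distortion, and any
absolute px→mm scale (the working distance is never specified; all
features stay in pixel units and the calibration absorbs the scale).

Determinism: a scene spec plus seed renders bit-identical frames; the
per-frame noise stream is seeded from `(scene seed, frame index)`. One
documented exception: rendering a sub-region (`region =` /
`render_roi_only = TRUE`, used by the streaming pipeline for speed) draws
a region-sized noise stream, so those pixels are a different — equally
valid — noise realization than a full-frame render.

## 6. Numerical choices

* Angles are stored in degrees (the conventional unit for FoV);
  trigonometry is done in radians internally.
* Lane boundaries use `round(i·W/n)`, half-open, so lanes partition every
  pixel column exactly once (tested exhaustively at small widths).
* Welzl's algorithm uses a deterministic internal shuffle, making the
  enclosing circle independent of contour point order (tested), and is
  verified against brute-force enumeration over pairs and triples.
* Moore tracing terminates on Jacob's criterion *or* on any repeated
  (pixel, backtrack) state — the latter is required for thin 8-connected
  structures, e.g. silhouettes clipped at the ROI border, where Jacob's
  criterion alone can cycle.
* Otsu's threshold is computed on a 256-bin histogram in double precision;
  foreground is `> threshold`.
* Degenerate contours (zero polygon area) are rejected with a message, not
  an error, so one broken speck cannot abort a frame.
* `fit_calibration()` refuses rank-deficient designs by QR rank check and
  names the collinear features.

## 7. Known limitations

* The greedy tracker assumes single-file flow; occlusion and same-lane
  contact are out of scope (the simulator rejects overlapping eggs rather
  than rendering them).
* Calibration is pooled across lanes. Per-lane calibration would mask
  illumination inhomogeneity; whether that is desirable depends on the
  deployment, and pooled is the honest default for evaluating lighting.
* The HSV defaults are tied to the synthetic palette; on real footage the
  range is mandatory configuration, not a default to trust.
* Timing claims of the hardware system (frame-cycle milliseconds) are
  hardware-dependent and deliberately not reproduced.
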