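geom <- screen_geometry()
# geometry with an exactly 0.30 mm pixel pitch for hand calculations
geom30 <- screen_geometry(width_mm = 384, height_mm = 307.2)

test_that("pixel-to-degree conversion matches the arctangent formula and is near-linear below 5 degrees", {
  expect_equal(px_to_deg(30, geom30),
               2 * atan(30 * 0.30 / (2 * 650)) * 180 / pi)
  expect_equal(deg_to_px(px_to_deg(123.4, geom), geom), 123.4)
  # monotone and small-angle linear within 1%
  px <- seq(1, deg_to_px(5, geom), length.out = 50)
  deg <- px_to_deg(px, geom)
  expect_true(all(diff(deg) > 0))
  linear <- px * px_to_deg(1e-6, geom) / 1e-6
  expect_true(all(abs(deg - linear) / deg < 0.01))
})

test_that("two stationary clusters separated by a ballistic sweep give exactly two fixations", {
  dt <- 1000 / 60
  t <- dt * (0:41)
  x <- c(rep(300, 19), 360, 440, rep(500, 21))
  y <- rep(300, 42)
  fx <- detect_fixations(make_stream(t, x, y), geom)
  expect_equal(nrow(fx), 2L)
  expect_equal(fx$centroid_x_px, c(300, 500))
  expect_true(all(fx$duration_ms >= 80))
})

test_that("sub-minimum clusters, blink-only streams and empty streams yield no fixations", {
  dt <- 1000 / 60
  short <- make_stream(dt * (0:3), rep(400, 4), rep(400, 4))  # 50 ms span
  expect_equal(nrow(detect_fixations(short, geom)), 0L)
  blinks <- make_stream(dt * (0:30), rep(0, 31), rep(0, 31))
  expect_equal(nrow(detect_fixations(blinks, geom)), 0L)
  expect_equal(nrow(detect_fixations(make_stream(numeric(0), numeric(0), numeric(0)), geom)), 0L)
})

test_that("non-monotone timestamps are rejected", {
  s <- make_stream(c(0, 20, 10), rep(1, 3), rep(1, 3))
  expect_error(detect_fixations(s, geom), "increasing")
})

test_that("fixation detection agrees with the brute-force dispersion-grouping oracle", {
  set.seed(404)
  for (case in 1:40) {
    t <- numeric(0); x <- numeric(0); y <- numeric(0)
    now <- 0
    while (length(t) < sample(40:200, 1)) {
      kind <- sample(c("hold", "move", "blink", "gap"), 1,
                     prob = c(0.5, 0.3, 0.1, 0.1))
      if (kind == "gap") { now <- now + runif(1, 40, 200); next }
      len <- sample(2:25, 1)
      ts <- now + 1000 / 60 * (seq_len(len) - 1)
      if (kind == "hold") {
        cx <- runif(1, 100, 1100); cy <- runif(1, 100, 900)
        xs <- cx + rnorm(len, 0, sample(c(2, 8, 20), 1))
        ys <- cy + rnorm(len, 0, sample(c(2, 8, 20), 1))
      } else if (kind == "move") {
        xs <- seq(runif(1, 100, 1100), runif(1, 100, 1100), length.out = len)
        ys <- seq(runif(1, 100, 900), runif(1, 100, 900), length.out = len)
      } else {
        xs <- rep(0, len); ys <- rep(0, len)
      }
      t <- c(t, ts); x <- c(x, xs); y <- c(y, ys)
      now <- ts[len] + 1000 / 60
    }
    s <- make_stream(t, x, y)
    got <- detect_fixations(s, geom)
    want <- idt_oracle(s, geom)
    expect_equal(nrow(got), nrow(want), info = paste("case", case))
    expect_equal(got$onset_ms, want$onset_ms, info = paste("case", case))
    expect_equal(got$offset_ms, want$offset_ms, info = paste("case", case))
    expect_equal(got$centroid_x_px, want$centroid_x_px, info = paste("case", case))
  }
})

test_that("saccades connect adjacent fixations: n - 1 structure, blink poisoning, amplitude geometry", {
  dt <- 1000 / 60
  # three stationary clusters; at a 0.5-degree threshold (~19 px) the
  # 30 px step between the first two splits them into distinct fixations
  t <- dt * (0:30)
  x <- c(rep(400, 10), rep(430, 10), rep(800, 11))
  y <- rep(500, 31)
  s <- make_stream(t, x, y)
  fx <- detect_fixations(s, geom30, dispersion_deg = 0.5)
  expect_equal(nrow(fx), 3L)
  sc <- derive_saccades(fx, s, geom30)
  expect_equal(nrow(sc), 2L)
  expect_false(any(sc$is_blink))
  # centroids 400 -> 430 at 0.30 mm pitch, 650 mm: ~0.79 degrees
  expect_equal(sc$amplitude_deg[1], 2 * atan(30 * 0.30 / (2 * 650)) * 180 / pi,
               tolerance = 1e-6)
  expect_lt(abs(sc$amplitude_deg[1] - 0.7933), 1e-3)

  # a blink run inside the transition poisons that saccade
  x2 <- x; x2[21] <- 0; y2 <- y; y2[21] <- 0
  s2 <- make_stream(t, x2, y2)
  fx2 <- detect_fixations(s2, geom30, dispersion_deg = 0.5)
  sc2 <- derive_saccades(fx2, s2, geom30)
  expect_true(any(sc2$is_blink))
  expect_false(any(sc2$is_regression[sc2$is_blink]))
  expect_error(expect_equal(nrow(derive_saccades(fx2[1, , drop = FALSE], s2, geom30)), 0L), NA)
})

test_that("regression rule: 20 px backward on either axis, OR semantics", {
  expect_true(classify_regression(-50, 0))
  expect_false(classify_regression(120, 0))
  expect_false(classify_regression(-10, -10))  # both components under threshold
  expect_true(classify_regression(0, -20))
  expect_true(classify_regression(-20, 35))   # literal rule: sweeps count
  expect_equal(classify_regression(c(-50, 120, -10), c(0, 0, -10)),
               c(TRUE, FALSE, FALSE))
})

test_that("peak speed: zero when stationary, hand value for two samples, brute-force maximum otherwise", {
  dt <- 1000 / 60
  s <- make_stream(dt * (0:9), rep(500, 10), rep(300, 10))
  expect_equal(peak_speed(s, 0, dt * 9, geom), 0)

  one_deg_px <- deg_to_px(1, geom)
  s2 <- make_stream(c(0, dt), c(500, 500 + one_deg_px), c(300, 300))
  expect_equal(peak_speed(s2, 0, dt, geom), 1 / (dt / 1000), tolerance = 1e-9)
  expect_equal(peak_speed(s2, 0, dt, geom), 60, tolerance = 1e-3)

  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:50, 1)
    t <- sort(runif(n, 0, 500))
    x <- runif(n, 0, 1200); y <- runif(n, 0, 1000)
    s3 <- make_stream(t, x, y)
    brute <- max(vapply(seq_len(n - 1), function(i) {
      px_to_deg(sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2), geom) /
        ((t[i + 1] - t[i]) / 1000)
    }, numeric(1)))
    expect_equal(peak_speed(s3, min(t), max(t), geom), brute)
  }
})

test_that("single-sample saccade intervals fall back to centroid displacement over duration", {
  s <- make_stream(c(0, 100), c(1, 2), c(1, 1))
  expect_equal(peak_speed(s, 40, 60, geom, fallback_deg = 2), 2 / 0.020)
})

test_that("AOI filtering is half-open and recomputes the saccade set from retained fixations", {
  aoi <- list(title = c(100, 50, 500, 100), content = c(100, 150, 500, 600))
  # 10 fixations along a chain, 4 outside the AOIs
  cx <- c(200, 300, 700, 250, 300, 550, 200, 300, 90, 499)
  cy <- c(200, 300, 300, 70, 600, 80, 200, 300, 400, 599.9)
  fx <- data.frame(onset_ms = 100 * (1:10), offset_ms = 100 * (1:10) + 80,
                   duration_ms = 80, centroid_x_px = cx, centroid_y_px = cy,
                   mean_pupil_px = 15, n_samples = 5)
  sc <- data.frame(onset_ms = head(fx$offset_ms, -1), offset_ms = fx$onset_ms[-1],
                   duration_ms = 20, dx_px = diff(cx), dy_px = diff(cy),
                   amplitude_px = 1, amplitude_deg = 1, peak_speed_deg_s = 10,
                   is_blink = FALSE, is_regression = FALSE,
                   from_fix = 1:9, to_fix = 2:10)
  out <- filter_aoi(fx, sc, aoi)
  # brute-force membership: half-open on the max edges
  inside <- function(x, y, r) x >= r[1] & x < r[3] & y >= r[2] & y < r[4]
  keep <- inside(cx, cy, aoi$title) | inside(cx, cy, aoi$content)
  expect_equal(sum(keep), 6L)
  expect_equal(nrow(out$fixations), 6L)
  expect_setequal(out$fixations$aoi_label, c("content", "title"))
  # row 3 (x=700), 5 (y=600 max edge), 6 (y=80 but x=550 outside title), 4 kept?
  expect_equal(nrow(out$saccades), sum(keep[1:9] & keep[2:10]))
  # re-indexed anchors point at the retained fixations
  expect_true(all(out$saccades$from_fix >= 1 & out$saccades$to_fix <= nrow(out$fixations)))
  # centroid exactly on a max edge is outside
  edge <- fx; edge$centroid_x_px[1] <- 500; edge$centroid_y_px[1] <- 200
  expect_false(1 %in% which(inside(edge$centroid_x_px, edge$centroid_y_px, aoi$content)[1]))
  expect_error(filter_aoi(fx, sc, list(title = aoi$title)), "content")
})

test_that("detected fixations never overlap, onsets increase, and saccades number fixations minus one", {
  cfg <- default_cfg_small(seed = 21)
  st <- generate_study(cfg)
  for (k in 1:3) {
    ev <- detect_session_events(st$streams[[k]])
    fx <- ev$fixations
    expect_true(all(diff(fx$onset_ms) > 0))
    expect_true(all(fx$onset_ms[-1] >= head(fx$offset_ms, -1)))
    expect_equal(nrow(ev$saccades), nrow(fx) - 1L)
    expect_true(all(ev$saccades$duration_ms > 0))
    expect_true(all(!ev$saccades$is_regression | !ev$saccades$is_blink))
  }
})

test_that("with regression probability zero, backward saccades beyond line-return sweeps are rare", {
  cfg <- default_cfg_small(seed = 33, regression_prob = 0)
  st <- generate_study(cfg)
  n_reg_non_sweep <- 0L; n_sac <- 0L
  for (k in seq_along(st$streams)) {
    ev <- detect_session_events(st$streams[[k]])
    sc <- ev$saccades[!ev$saccades$is_blink, ]
    # tolerate line-return sweeps: leftward but downward
    n_reg_non_sweep <- n_reg_non_sweep +
      sum(sc$is_regression & !(sc$dx_px <= -20 & sc$dy_px > 0))
    n_sac <- n_sac + nrow(sc)
  }
  expect_lt(n_reg_non_sweep / n_sac, 0.02)
})
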