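test_that("average speed is the mean vector magnitude over valid ROI vectors", {
  roi <- roi_mask(rect = c(0, 0, 32, 32), dim = c(32, 32))

  f34 <- make_field(3, 4)
  expect_identical(average_speed(f34, roi), 5)
  expect_identical(average_speed(make_field(0, 0), roi), 0)

  # ROI covering exactly one (1,0) and one (0,1) vector
  f <- make_field(0, 0)
  f$dx[f$gx == 0 & f$gy == 0] <- 1
  f$dy[f$gx == 4 & f$gy == 0] <- 1
  roi2 <- roi_mask(rect = c(0, 0, 8, 4), dim = c(32, 32))
  expect_identical(average_speed(f, roi2), 1)

  # no valid vectors inside the ROI: a classed error, never a silent zero
  f$valid[f$gy == 28] <- FALSE
  roi3 <- roi_mask(rect = c(0, 28, 32, 4), dim = c(32, 32))
  expect_error(average_speed(f, roi3), class = "bamotion_no_valid_vectors")
})

test_that("speed traces have one sample per pair with correct units", {
  roi <- roi_mask(rect = c(0, 0, 32, 32), dim = c(32, 32))
  static <- lapply(1:5, function(k) make_field(0, 0, frame_index = k))
  tr <- speed_trace(static, roi, frame_rate = 100)
  expect_equal(tr$speed, rep(0, 5))
  expect_equal(tr$time_s, (1:5) / 100)

  shift <- lapply(1:4, function(k) make_field(0, 3, frame_index = k))
  tr2 <- speed_trace(shift, roi, frame_rate = 100)
  expect_equal(tr2$speed, rep(3, 4))

  # unit consistency: um/s = px/frame * pixel_size * frame_rate, samplewise
  tr_um <- speed_trace(shift, roi, frame_rate = 100, pixel_size = 0.65)
  expect_equal(tr_um$speed, tr2$speed * 0.65 * 100)
  expect_identical(attr(tr_um, "units"), "um_per_s")

  # a field with no valid ROI vectors becomes NA with a warning
  dead <- make_field(1, 0, valid = FALSE, frame_index = 5L)
  expect_warning(tr3 <- speed_trace(c(shift, list(dead)), roi, 100),
                 "no valid vectors")
  expect_true(is.na(tr3$speed[5]))
  expect_identical(tr3$n_valid[5], 0L)
})

test_that("scaling all vectors scales speeds and distances, not durations", {
  roi <- roi_mask(rect = c(0, 0, 32, 32), dim = c(32, 32))
  base <- lapply(1:30, function(k) {
    v <- if (k %in% 5:14) 4 else 0
    make_field(v, 0, frame_index = k)
  })
  scaled <- lapply(base, function(f) {
    f$dx <- f$dx * 2.5
    f
  })
  tr_a <- speed_trace(base, roi, 100)
  tr_b <- speed_trace(scaled, roi, 100)
  expect_equal(tr_b$speed, tr_a$speed * 2.5)
  ev_a <- detect_contractions(tr_a)
  ev_b <- detect_contractions(tr_b)
  expect_equal(ev_b$duration_s, ev_a$duration_s)
  expect_equal(ev_b$peak_speed, ev_a$peak_speed * 2.5)
  expect_equal(deformation_distance(tr_b, ev_b[1, ]),
               deformation_distance(tr_a, ev_a[1, ]) * 2.5)
})

test_that("contraction detection isolates the first run of each cycle", {
  expect_identical(nrow(detect_contractions(make_trace(rep(0, 50)))), 0L)

  # two cycles of a strong (speed 10) then weak (speed 6) bump
  v <- rep(0, 100)
  v[11:20] <- 10; v[31:40] <- 6
  v[51:60] <- 10; v[71:80] <- 6
  ev <- detect_contractions(make_trace(v), threshold_fraction = 0.2)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$peak_speed, c(10, 10))
  # duration ~ 10 frames at 100 fps, within one frame
  expect_lt(max(abs(ev$duration_s - 0.10)), 0.01)
  # swapping the labelling picks the weak bumps instead
  ev2 <- detect_contractions(make_trace(v), contraction_first = FALSE)
  expect_equal(ev2$peak_speed, c(6, 6))

  # gap closing: a 1-sample dip inside a bump does not split it
  v3 <- rep(0, 40); v3[11:25] <- 8; v3[18] <- 0
  ev3 <- detect_contractions(make_trace(v3), min_separation = 0.02)
  expect_identical(nrow(ev3), 1L)
  expect_lt(abs(ev3$duration_s - 0.15), 0.01)
  # without closing, the dip splits the bump and the first run ends early
  ev3b <- detect_contractions(make_trace(v3), min_separation = 0)
  expect_lt(ev3b$duration_s[1], ev3$duration_s[1] - 0.05)

  expect_error(detect_contractions(make_trace(v), threshold_fraction = 1.2),
               "threshold_fraction")
  expect_warning(detect_contractions(make_trace(c(v[1:50], NA, v[52:100]))),
                 "missing")
})

test_that("durations and deformation distances follow their definitions", {
  expect_equal(contraction_duration(list(onset_s = 0.10, offset_s = 0.25)),
               0.15)
  expect_error(contraction_duration(list(onset_s = 0.3, offset_s = 0.3)),
               "non-positive")

  # rectangle: constant 3 px/frame over a 10-frame event -> 30 px
  tr <- make_trace(rep(3, 50))
  ev <- list(onset_s = 0.10, offset_s = 0.20)
  expect_equal(deformation_distance(tr, ev), 30)

  # zero speed -> zero distance
  expect_equal(deformation_distance(make_trace(rep(0, 50)), ev), 0)

  # triangle 0 -> vmax -> 0 over 2k frames integrates to k * vmax
  k <- 10; vmax <- 6
  v <- c(rep(0, 5), vmax * c(seq(0, 1, length.out = k + 1),
                             seq(1, 0, length.out = k + 1)[-1]), rep(0, 5))
  trt <- make_trace(v)
  evt <- list(onset_s = 6 / 100, offset_s = (6 + 2 * k) / 100)
  expect_equal(deformation_distance(trt, evt), k * vmax)

  # micrometre traces integrate over seconds directly
  tr_um <- make_trace(rep(3, 50), units = "um_per_s")
  expect_equal(deformation_distance(tr_um, ev), 0.3)

  expect_error(deformation_distance(tr, list(onset_s = 2, offset_s = 3)),
               "overlap")
})

test_that("event summaries average across a recording", {
  ev <- data.frame(onset_s = c(0, 1), offset_s = c(0.1, 1.3),
                   duration_s = c(0.1, 0.3),
                   deformation_distance = c(10, 30))
  s <- summarize_events(ev)
  expect_equal(s$n_events, 2)
  expect_equal(s$mean_duration_s, 0.2)
  expect_equal(s$mean_deformation_distance, 20)
  one <- summarize_events(ev[1, ])
  expect_equal(one$mean_duration_s, 0.1)
  expect_error(summarize_events(ev[0, ]), "no events")
})

test_that("group comparison reproduces the Welch formula and its limits", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- compare_groups(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_identical(degen$t, -Inf)
  expect_equal(degen$p, 0)
  expect_identical(compare_groups(c(2, 2), c(2, 2))$t, 0)

  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- compare_groups(a, b)
  # hand-computed Welch statistic
  se2 <- var(a) / 4 + var(b) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$df, df_ref, tolerance = 1e-12)
  expect_equal(got$p, p_ref, tolerance = 1e-12)
  expect_equal(got$sd_a, sd(a))

  # symmetry up to the sign of t
  swap <- compare_groups(b, a)
  expect_equal(swap$t, -got$t)
  expect_equal(swap$p, got$p)

  # pooled-variance variant on request
  pooled <- compare_groups(a, b, var_equal = TRUE)
  expect_equal(pooled$df, 6)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("events are recovered from ground-truth traces across phantom settings", {
  for (period in c(10L, 20L)) {
    for (cf in c(0.3, 0.5, 0.6)) {
      ph <- generate_beating_phantom(
        phantom_config(height = 48, width = 48, n_cycles = 2,
                       period = period, contraction_fraction = cf,
                       contraction_amplitude = 3))
      tt <- true_speed_trace(ph$truth)
      ev <- detect_contractions(tt)
      info <- sprintf("period=%d cf=%.1f", period, cf)
      expect_identical(nrow(ev), 2L, info = info)
      sched <- ph$truth$event_schedule
      fr <- ph$truth$frame_rate
      expect_lt(max(abs(ev$onset_s - sched$contraction_start / fr)), 1 / fr)
      expect_lt(max(abs(ev$offset_s - sched$contraction_end / fr)), 1 / fr)
    }
  }
})

test_that("measured event counts survive frame noise on a fast phantom", {
  # per-pair motion of ~1-2 px so the integer matcher sees the beat
  fast <- function(sig, seed) {
    phantom_config(period = 8, contraction_amplitude = 4, n_cycles = 3,
                   noise_sigma = sig, seed = seed)
  }
  ph0 <- generate_beating_phantom(fast(0, 1))
  n0 <- nrow(analyze_motion(ph0$sequence, roi = ph0$truth$roi)$events)
  expect_identical(n0, 3L)
  for (s in 1:5) {
    phn <- generate_beating_phantom(fast(10, s))
    fitn <- analyze_motion(phn$sequence, roi = phn$truth$roi)
    expect_identical(nrow(fitn$events), n0, info = paste("seed", s))
  }
})
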