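test_that("speckle textures are seeded, seed-sensitive and decorrelate with lag", {
  a <- generate_texture(64, 64, 2, seed = 1)
  b <- generate_texture(64, 64, 2, seed = 1)
  c <- generate_texture(64, 64, 2, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_identical(range(a), c(0L, 255L))

  # autocorrelation at lag (4, 0) must be below the zero-lag value, computed
  # directly on the generated frame
  x <- a - mean(a)
  c0 <- mean(x * x)
  c4 <- mean(x[, 1:60] * x[, 5:64])
  expect_lt(c4, c0)

  expect_error(generate_texture(0, 64), "positive")
  expect_error(generate_texture(64, 64, speckle_grain = 0), "speckle_grain")
})

test_that("translation sequences realise the prescribed shifts exactly", {
  tex <- generate_texture(96, 96, 2, seed = 5)

  zero <- generate_translation_sequence(tex, rbind(c(0, 0)))
  expect_identical(zero$sequence$frames[[1]], zero$sequence$frames[[2]])
  expect_true(all(zero$truth$fields[[1]]$dx == 0))
  expect_true(all(zero$truth$fields[[1]]$dy == 0))

  one <- generate_translation_sequence(tex, rbind(c(2, 1)))
  expect_true(all(one$truth$fields[[1]]$dx == 2))
  expect_true(all(one$truth$fields[[1]]$dy == 1))

  # inverse shifts compose to the identity
  inv <- generate_translation_sequence(tex, rbind(c(3, 0), c(-3, 0)))
  expect_identical(inv$sequence$frames[[1]], inv$sequence$frames[[3]])

  # content conservation: frame k+1 shifted back matches frame k on the overlap
  fr <- one$sequence$frames
  H <- nrow(fr[[1]]); W <- ncol(fr[[1]])
  expect_identical(fr[[2]][(1 + 1):H, (2 + 1):W],
                   fr[[1]][1:(H - 1), 1:(W - 2)])

  expect_error(generate_translation_sequence(tex, rbind(c(50, 0)),
                                             margin = 10),
               "exceeds")
})

test_that("beating phantom is deterministic and degenerates correctly", {
  cfg <- phantom_config(height = 48, width = 48, n_cycles = 2, period = 10)
  p1 <- generate_beating_phantom(cfg)
  p2 <- generate_beating_phantom(cfg)
  expect_identical(p1$sequence$frames, p2$sequence$frames)
  expect_identical(p1$truth$fields, p2$truth$fields)

  still <- generate_beating_phantom(
    phantom_config(height = 48, width = 48, contraction_amplitude = 0))
  expect_true(all(vapply(still$sequence$frames,
                         function(f) identical(f, still$sequence$frames[[1]]),
                         logical(1))))
  tt <- true_speed_trace(still$truth)
  expect_true(all(tt$speed == 0))
})

test_that("phantom ground truth carries the event schedule and two speed bumps per cycle", {
  ph <- generate_beating_phantom(
    phantom_config(height = 64, width = 64, n_cycles = 3, period = 20))
  sched <- ph$truth$event_schedule
  expect_equal(nrow(sched), 3)
  expect_true(all(sched$contraction_start < sched$contraction_end))
  expect_true(all(sched$contraction_end < sched$relaxation_end))
  # non-overlapping, ordered cycles
  expect_true(all(diff(sched$contraction_start) > 0))
  expect_true(all(sched$relaxation_end[-3] < sched$contraction_start[-1]))

  # true mean-speed trace: exactly two plateau maxima per cycle (contraction
  # and relaxation), counted as above-zero runs separated by zero-motion pairs
  tt <- true_speed_trace(ph$truth)
  r <- rle(tt$speed > 1e-12)
  expect_equal(sum(r$values), 2 * 3)

  # ground-truth consistency: trace equals direct recomputation from fields
  covered <- ph$truth$roi[cbind(ph$truth$fields[[1]]$gy + 1,
                                ph$truth$fields[[1]]$gx + 1)]
  direct <- vapply(ph$truth$fields, function(f) {
    mean(sqrt(f$dx[covered]^2 + f$dy[covered]^2))
  }, numeric(1))
  expect_equal(tt$speed, direct)
  # displacement magnitudes never exceed the configured amplitude
  mags <- unlist(lapply(ph$truth$fields, function(f) sqrt(f$dx^2 + f$dy^2)))
  expect_lte(max(mags), ph$truth$config$contraction_amplitude)
})

test_that("additive noise is seeded, clipped and unbiased", {
  ph <- generate_beating_phantom(
    phantom_config(height = 32, width = 32, n_cycles = 1, period = 10))
  expect_identical(add_noise(ph$sequence, 0), ph$sequence)
  n1 <- add_noise(ph$sequence, 5, seed = 9)
  n2 <- add_noise(ph$sequence, 5, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(ph$sequence, 5, seed = 10)))
  rngs <- range(unlist(n1$frames))
  expect_gte(rngs[1], 0)
  expect_lte(rngs[2], 255)

  # law of large numbers on a constant frame: sample mean within 1 unit
  const <- image_sequence(list(matrix(128L, 256, 256)), frame_rate = 100)
  noisy <- add_noise(const, 5, seed = 1)
  expect_lt(abs(mean(noisy$frames[[1]]) - 128), 1)

  expect_error(add_noise(ph$sequence, -1), "non-negative")
})
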