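test_that("mae_score matches its definition and a naive double loop", {
  f0 <- matrix(0L, 32, 32)
  f255 <- matrix(255L, 32, 32)
  cfg <- block_match_config()
  expect_identical(mae_score(f0, f0, c(16, 16), c(0, 0), cfg), 0)
  expect_identical(mae_score(f255, f0, c(16, 16), c(2, -3), cfg), 255)

  prev <- random_frame(40, 40, seed = 11)
  cur <- random_frame(40, 40, seed = 12)
  for (cand in list(c(0, 0), c(3, -2), c(-4, 4))) {
    expect_identical(mae_score(cur, prev, c(20, 20), cand, cfg),
                     naive_mae(cur, prev, 20, 20, cand[1], cand[2]))
  }
  expect_error(mae_score(cur, prev, c(2, 2), c(0, 0), cfg), "outside")
  expect_error(mae_score(cur, prev, c(20, 20), c(30, 0), cfg), "outside")
})

test_that("match_block recovers shifts, ties to zero motion and flags borders", {
  tex <- generate_texture(80, 80, 2, seed = 2)
  same <- match_block(tex, tex, c(40, 40))
  expect_identical(same[c("dx", "dy", "score", "valid")],
                   list(dx = 0L, dy = 0L, score = 0, valid = TRUE))

  sh <- generate_translation_sequence(tex, rbind(c(2, 1)))
  mb <- match_block(sh$sequence$frames[[2]], sh$sequence$frames[[1]],
                    c(30, 30))
  expect_identical(c(mb$dx, mb$dy), c(2L, 1L))

  flat <- matrix(7L, 64, 64)
  tie <- match_block(flat, flat, c(32, 32))
  expect_identical(c(tie$dx, tie$dy), c(0L, 0L))

  border <- match_block(tex, tex, c(4, 4))
  expect_false(border$valid)
  expect_identical(c(border$dx, border$dy), c(0L, 0L))

  expect_error(match_block(tex, matrix(0L, 10, 10), c(5, 5)),
               "equal dimensions")
})

test_that("motion fields have the floor-law grid and recover global shifts", {
  expect_identical(count_grid_vectors(512, 1024, 4), 32768L)
  expect_identical(count_grid_vectors(16, 16, 4), 16L)
  expect_identical(count_grid_vectors(100, 100, 4), 625L)
  expect_error(count_grid_vectors(0, 10, 4), "positive")

  # property: floor arithmetic for all strides 1..16
  for (s in 1:16) {
    expect_identical(count_grid_vectors(37, 53, s),
                     as.integer(floor(53 / s) * floor(37 / s)))
  }

  tex <- generate_texture(120, 140, 2, seed = 4)
  sh <- generate_translation_sequence(tex, rbind(c(3, 0)))
  f <- compute_motion_field(sh$sequence$frames[[1]], sh$sequence$frames[[2]])
  d <- dim(sh$sequence$frames[[1]])
  expect_identical(nrow(f), as.integer(floor(d[2] / 4) * floor(d[1] / 4)))
  expect_true(all(f$dx[f$valid] == 3))
  expect_true(all(f$dy[f$valid] == 0))
  expect_true(all(f$score[f$valid] == 0))
  expect_true(all(f$dx[!f$valid] == 0) && all(f$dy[!f$valid] == 0))

  ident <- compute_motion_field(tex, tex)
  expect_true(all(ident$dx[ident$valid] == 0) &&
                all(ident$dy[ident$valid] == 0))
})

test_that("optimized matcher equals the naive exhaustive oracle bit-exactly", {
  for (seed in 1:4) {
    prev <- random_frame(64, 64, seed = 100 + seed)
    set.seed(200 + seed)
    # correlated pair: shifted content plus fresh pixels, keeps scores nontrivial
    cur <- prev
    cur[, 2:64] <- prev[, 1:63]
    cur[sample(length(cur), 200)] <- sample(0:255, 200, replace = TRUE)
    f <- compute_motion_field(prev, cur)
    o <- naive_motion_field(prev, cur)
    expect_identical(f$dx, o$dx)
    expect_identical(f$dy, o$dy)
    expect_identical(f$score, o$score)
    expect_identical(f$valid, o$valid)
  }
})

test_that("vector components never exceed w and A->B matching negates B->A", {
  prev <- random_frame(64, 64, seed = 31)
  cur <- random_frame(64, 64, seed = 32)
  for (w in c(2L, 4L)) {
    f <- compute_motion_field(prev, cur,
                              block_match_config(max_displacement = w))
    expect_lte(max(abs(c(f$dx, f$dy))), w)
  }

  tex <- generate_texture(120, 120, 2, seed = 8)
  sh <- generate_translation_sequence(tex, rbind(c(2, -1)))
  a <- sh$sequence$frames[[1]]; b <- sh$sequence$frames[[2]]
  fab <- compute_motion_field(a, b)
  fba <- compute_motion_field(b, a)
  both <- fab$valid & fba$valid
  expect_true(all(fab$dx[both] == -fba$dx[both]))
  expect_true(all(fab$dy[both] == -fba$dy[both]))
})

test_that("sequence fields count pairs and track phantom ground truth", {
  tex <- generate_texture(100, 100, 2, seed = 6)
  two <- generate_translation_sequence(tex, rbind(c(1, 0)))
  expect_length(compute_sequence_fields(two$sequence), 1)
  ten <- generate_translation_sequence(
    tex, matrix(c(rep(1, 5), rep(-1, 4), rep(0, 9)), ncol = 2))
  expect_length(compute_sequence_fields(ten$sequence), 9)
  expect_error(
    compute_sequence_fields(image_sequence(list(tex), frame_rate = 100)),
    "at least 2")

  # phantom with amplitude <= w: every valid estimate within 1 px per
  # component of the rounded true displacement at its grid position
  ph <- generate_beating_phantom(
    phantom_config(height = 64, width = 64, n_cycles = 1, period = 10,
                   contraction_amplitude = 3))
  fields <- compute_sequence_fields(ph$sequence)
  for (k in seq_along(fields)) {
    f <- fields[[k]]; g <- ph$truth$fields[[k]]
    expect_lte(max(abs(f$dx[f$valid] - round(g$dx[f$valid]))), 1)
    expect_lte(max(abs(f$dy[f$valid] - round(g$dy[f$valid]))), 1)
  }
})
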