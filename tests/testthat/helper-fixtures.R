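# Hand-built fixtures for the kinetics tests.

# A motion field with prescribed vectors, following the documented return
# contract of compute_motion_field(): one row per grid anchor (x fastest),
# frame_dim/config/frame_index attributes.
make_field <- function(dx, dy, height = 32L, width = 32L, stride = 4L,
                       valid = TRUE, frame_index = 1L, score = 0) {
  gxs <- stride * (0:(floor(width / stride) - 1L))
  gys <- stride * (0:(floor(height / stride) - 1L))
  grid <- expand.grid(gx = gxs, gy = gys)
  n <- nrow(grid)
  out <- data.frame(gx = grid$gx, gy = grid$gy,
                    dx = rep_len(dx, n), dy = rep_len(dy, n),
                    score = rep_len(score, n),
                    valid = rep_len(valid, n))
  attr(out, "frame_dim") <- c(height = height, width = width)
  attr(out, "config") <- block_match_config(stride = stride)
  attr(out, "frame_index") <- as.integer(frame_index)
  class(out) <- c("motion_field", "data.frame")
  out
}

# A speed trace sampled at frame pairs 1..n of a given frame rate.
make_trace <- function(speeds, frame_rate = 100,
                       units = "pixels_per_frame") {
  n <- length(speeds)
  out <- data.frame(time_s = seq_len(n) / frame_rate, speed = speeds,
                    n_valid = rep(10L, n))
  attr(out, "units") <- units
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("speed_trace", "data.frame")
  out
}

# Random 8-bit frame.
random_frame <- function(height, width, seed) {
  set.seed(seed)
  matrix(sample(0:255, height * width, replace = TRUE), height, width)
}
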