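# Synthetic beating-heart phantoms with exactly known motion.
#
# The study's videos are not deposited, so validation runs on sequences whose
# displacement fields are known by construction: speckle textures under pure
# integer translation (the block matcher must recover the shift exactly) and
# a radially contracting speckle disk emulating the outflow tract (event
# timing and true per-pair mean speeds are known exactly).

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = env) else
    rm(".Random.seed", envir = env), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a speckle texture frame
#'
#' Seeded uniform noise smoothed by a `speckle_grain`-wide circular box filter
#' in each direction, then stretched to the full 0-255 range. The result is a
#' high-contrast pattern with correlation length ~`speckle_grain` pixels and
#' no translational symmetry, so block matching on it has a unique optimum.
#'
#' @param height,width texture dimensions in pixels.
#' @param speckle_grain blob size in pixels (>= 1, <= both dimensions).
#' @param seed RNG seed; identical arguments give bit-identical textures.
#' @return a frame (integer matrix).
#' @export
generate_texture <- function(height, width, speckle_grain = 2L, seed = 1L) {
  if (height < 1 || width < 1) {
    stop("texture dimensions must be positive", call. = FALSE)
  }
  g <- as.integer(speckle_grain)
  if (is.na(g) || g < 1L || g > height || g > width) {
    stop("'speckle_grain' must be in [1, min(height, width)]", call. = FALSE)
  }
  m <- with_seed(seed, matrix(stats::runif(height * width), height, width))
  if (g > 1L) {
    kern <- rep(1 / g, g)
    m <- apply(m, 2L, function(col) stats::filter(col, kern, circular = TRUE))
    m <- t(apply(m, 1L, function(row) stats::filter(row, kern, circular = TRUE)))
  }
  m <- (m - min(m)) / (max(m) - min(m))
  as_frame(round(m * 255))
}

# Ground-truth container shared by the generators.
new_phantom_truth <- function(fields, stride, event_schedule, frame_dim,
                              frame_rate, roi = NULL, kind, config = NULL) {
  structure(list(fields = fields, stride = as.integer(stride),
                 event_schedule = event_schedule, frame_dim = frame_dim,
                 frame_rate = frame_rate, roi = roi, kind = kind,
                 config = config),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth (%s): %d frame pair(s), %d event(s), stride %d\n",
              x$kind, length(x$fields), nrow(x$event_schedule), x$stride))
  invisible(x)
}

#' Rigid integer-translation sequence with ground truth
#'
#' Frame `k + 1` is frame `k`'s content shifted by `displacements[k, ]`
#' (positive dx moves content rightwards, positive dy downwards). Frames are
#' crops of an oversized source texture so no wrap-around or undefined pixels
#' appear: the crop margin must cover the largest cumulative shift (plus a
#' safety border, by default the matcher's `w = 4`).
#'
#' @param texture source frame, larger than the output by `2 * margin` in
#'   each dimension.
#' @param displacements an n x 2 matrix (or list of length-2 vectors) of
#'   integer per-pair shifts `(dx, dy)` in pixels.
#' @param margin crop margin in pixels; default
#'   `max(|cumulative shift|) + 4`.
#' @param frame_rate,pixel_size metadata for the output sequence.
#' @param stride grid spacing at which ground truth is recorded.
#' @return a list with elements `sequence` (an [image_sequence()] of
#'   `n + 1` frames) and `truth` (a `phantom_truth` whose per-pair fields hold
#'   the applied shift at every grid position).
#' @export
generate_translation_sequence <- function(texture, displacements,
                                          margin = NULL, frame_rate = 100,
                                          pixel_size = NULL, stride = 4L) {
  texture <- as_frame(texture)
  if (is.list(displacements)) {
    displacements <- do.call(rbind, lapply(displacements, as.integer))
  }
  displacements <- matrix(as.integer(displacements), ncol = 2L)
  if (nrow(displacements) < 1L || anyNA(displacements)) {
    stop("'displacements' must be one or more integer (dx, dy) pairs",
         call. = FALSE)
  }
  cumx <- c(0L, cumsum(displacements[, 1L]))
  cumy <- c(0L, cumsum(displacements[, 2L]))
  if (is.null(margin)) margin <- max(abs(c(cumx, cumy))) + 4L
  margin <- as.integer(margin)
  if (max(abs(c(cumx, cumy))) > margin) {
    stop("cumulative shift exceeds the crop margin", call. = FALSE)
  }
  H <- nrow(texture) - 2L * margin
  W <- ncol(texture) - 2L * margin
  if (H < 1L || W < 1L) {
    stop("texture too small for the requested margin", call. = FALSE)
  }
  frames <- lapply(seq_along(cumx), function(k) {
    texture[(margin + 1L - cumy[k]):(margin + H - cumy[k]),
            (margin + 1L - cumx[k]):(margin + W - cumx[k]), drop = FALSE]
  })
  seq <- image_sequence(frames, frame_rate = frame_rate,
                        pixel_size = pixel_size)
  gp <- grid_positions(H, W, stride)
  fields <- lapply(seq_len(nrow(displacements)), function(k) {
    data.frame(gx = gp$gx, gy = gp$gy,
               dx = rep(as.numeric(displacements[k, 1L]), length(gp$gx)),
               dy = rep(as.numeric(displacements[k, 2L]), length(gp$gx)))
  })
  truth <- new_phantom_truth(
    fields = fields, stride = stride,
    event_schedule = data.frame(contraction_start = integer(0),
                                contraction_end = integer(0),
                                relaxation_end = integer(0)),
    frame_dim = c(height = H, width = W), frame_rate = frame_rate,
    kind = "translation")
  list(sequence = seq, truth = truth)
}

#' Beating-phantom configuration
#'
#' The defaults state the standard validation phantom: a 128 x 128 frame
#' (desk-scale stand-in for the published 1,024 x 512 acquisition), three
#' 20-frame beat cycles at 100 frames/s, a maximal radial contraction of
#' 3 pixels (inside the matcher's default search range w = 4) and a
#' contraction phase occupying half of each cycle.
#'
#' Each cycle is a piecewise-linear pulse in the contraction factor g(t):
#' a rise from 0 to 1 over `round(contraction_fraction * period)` frames (the
#' contraction), one dwell frame at full contraction, a linear fall back to 0
#' (the relaxation), and at least one quiescent frame before the next cycle.
#' The dwell and quiescent frames carry zero motion, which makes contraction
#' onset and offset unambiguous in the speed trace; a sinusoidal pulse would
#' not have that property. `lead_in` static frames precede the first cycle so
#' the first onset has a quiescent baseline.
#'
#' @param height,width frame dimensions in pixels.
#' @param n_cycles number of beat cycles.
#' @param period cycle length in frames (>= 4; rise length is capped at
#'   `period - 3` so every cycle keeps its dwell and quiescent frames).
#' @param contraction_amplitude maximal inward radial displacement of the
#'   tissue boundary, in pixels. A warning is issued above 4 pixels because
#'   per-frame motion may then exceed the default search range.
#' @param contraction_fraction fraction of the period occupied by the
#'   contraction phase, in (0, 1).
#' @param speckle_grain,noise_sigma,seed texture grain (pixels), additive
#'   Gaussian intensity noise s.d. and RNG seed.
#' @param frame_rate frames per second.
#' @param lead_in static frames before the first cycle.
#' @param stride grid spacing at which ground truth is recorded.
#' @param pixel_size micrometres per pixel, or `NULL`.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height = 128L, width = 128L, n_cycles = 3L,
                           period = 20L, contraction_amplitude = 3,
                           contraction_fraction = 0.5, speckle_grain = 2L,
                           noise_sigma = 0, seed = 1L, frame_rate = 100,
                           lead_in = 2L, stride = 4L, pixel_size = NULL) {
  period <- as.integer(period)
  if (is.na(period) || period < 4L) {
    stop("'period' must be at least 4 frames", call. = FALSE)
  }
  if (!(contraction_fraction > 0 && contraction_fraction < 1)) {
    stop("'contraction_fraction' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (contraction_amplitude < 0) {
    stop("'contraction_amplitude' must be non-negative", call. = FALSE)
  }
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative", call. = FALSE)
  if (n_cycles < 1L) stop("'n_cycles' must be at least 1", call. = FALSE)
  if (contraction_amplitude > 4) {
    warning("contraction_amplitude exceeds the default search range w = 4; ",
            "block matching may not recover the motion", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cycles = as.integer(n_cycles), period = period,
                 contraction_amplitude = contraction_amplitude,
                 contraction_fraction = contraction_fraction,
                 speckle_grain = as.integer(speckle_grain),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 frame_rate = frame_rate, lead_in = as.integer(lead_in),
                 stride = as.integer(stride), pixel_size = pixel_size),
            class = "phantom_config")
}

# Per-frame contraction factor g in [0, 1] and the event schedule
# (frame indices, 0-based). nr rise frames, 1 dwell frame at the peak,
# nf fall frames, >= 1 quiescent frame(s) closing the cycle.
pulse_schedule <- function(config) {
  period <- config$period
  nr <- min(max(1L, as.integer(round(config$contraction_fraction * period))),
            period - 3L)
  nf <- period - nr - 2L
  n_frames <- config$lead_in + config$n_cycles * period + 1L
  f <- seq_len(n_frames) - 1L
  u <- f - config$lead_in
  ph <- u %% period
  cyc <- u %/% period
  g <- numeric(n_frames)
  active <- u >= 0L & cyc < config$n_cycles
  rise <- active & ph <= nr
  fall <- active & ph > nr & ph <= nr + 1L + nf
  g[rise] <- ph[rise] / nr
  g[fall] <- 1 - (ph[fall] - nr - 1L) / nf
  starts <- config$lead_in + (seq_len(config$n_cycles) - 1L) * period
  schedule <- data.frame(contraction_start = starts,
                         contraction_end = starts + nr,
                         relaxation_end = starts + period - 1L)
  list(g = g, schedule = schedule, n_rise = nr, n_fall = nf,
       n_frames = n_frames)
}

# Bilinear interpolation of img at 0-based real coordinates (x, y).
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x0 <- pmin(pmax(floor(x), 0), W - 2L)
  y0 <- pmin(pmax(floor(y), 0), H - 2L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1L, x0 + 1L)
  i01 <- cbind(y0 + 1L, x0 + 2L)
  i10 <- cbind(y0 + 2L, x0 + 1L)
  i11 <- cbind(y0 + 2L, x0 + 2L)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

#' Generate a beating-heart phantom with exact ground truth
#'
#' A speckle-textured disk (the tissue) over a static low-contrast background.
#' At contraction factor g the disk is radially rescaled by
#' `k = 1 - amplitude * g / R0` about its centre, so a material point at
#' reference radius r sits at radius `k * r`: the boundary moves inwards by
#' `amplitude * g` pixels and interior displacement scales linearly with
#' radius. Frames are bilinear warps of one reference texture (sub-pixel
#' motion exists; intensities are rounded back to 8-bit).
#'
#' The ground truth records, for every consecutive frame pair, the exact
#' (real-valued) displacement of the tissue at each analysis grid position,
#' the contraction/relaxation event schedule, and an always-tissue disk ROI.
#'
#' @param config a [phantom_config()].
#' @return a list with elements `sequence` (an [image_sequence()]) and
#'   `truth` (a `phantom_truth`).
#' @export
generate_beating_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) {
    stop("'config' must be a phantom_config", call. = FALSE)
  }
  H <- config$height; W <- config$width
  ps <- pulse_schedule(config)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  R0 <- 0.38 * min(H, W)
  A <- config$contraction_amplitude

  tissue <- generate_texture(H, W, config$speckle_grain, config$seed)
  bg_tex <- generate_texture(H, W, config$speckle_grain, config$seed + 1L)
  background <- as_frame(round(bg_tex / 255 * 60))

  X <- matrix(rep(0:(W - 1L), each = H), H, W)
  Y <- matrix(rep(0:(H - 1L), times = W), H, W)
  R <- sqrt((X - cx)^2 + (Y - cy)^2)
  tissue_d <- tissue
  storage.mode(tissue_d) <- "double"

  k_t <- 1 - A * ps$g / R0
  frames <- lapply(seq_len(ps$n_frames), function(t) {
    k <- k_t[t]
    fr <- background
    inside <- R <= k * R0
    if (any(inside)) {
      sx <- cx + (X[inside] - cx) / k
      sy <- cy + (Y[inside] - cy) / k
      v <- round(bilinear_sample(tissue_d, sx, sy))
      fr[inside] <- as.integer(pmin(pmax(v, 0), 255))
    }
    fr
  })
  seq <- image_sequence(frames, frame_rate = config$frame_rate,
                        pixel_size = config$pixel_size)
  if (config$noise_sigma > 0) {
    seq <- add_noise(seq, config$noise_sigma, seed = config$seed + 2L)
  }

  gp <- grid_positions(H, W, config$stride)
  gr <- sqrt((gp$gx - cx)^2 + (gp$gy - cy)^2)
  fields <- lapply(seq_len(ps$n_frames - 1L), function(t) {
    inside <- gr <= k_t[t] * R0
    fac <- k_t[t + 1L] / k_t[t] - 1
    data.frame(gx = gp$gx, gy = gp$gy,
               dx = ifelse(inside, (gp$gx - cx) * fac, 0),
               dy = ifelse(inside, (gp$gy - cy) * fac, 0))
  })
  roi <- R <= (R0 - A)   # disk that is tissue at every contraction phase
  truth <- new_phantom_truth(
    fields = fields, stride = config$stride, event_schedule = ps$schedule,
    frame_dim = c(height = H, width = W), frame_rate = config$frame_rate,
    roi = roi, kind = "beating", config = config)
  list(sequence = seq, truth = truth)
}

#' Add 8-bit Gaussian intensity noise
#'
#' Independent zero-mean Gaussian perturbation per pixel, rounded and clipped
#' to `[0, 255]`. `sigma = 0` returns the input unchanged (and does not touch
#' the RNG); identical seeds give bit-identical output.
#'
#' @param seq an [image_sequence()].
#' @param sigma noise standard deviation in intensity units (>= 0).
#' @param seed RNG seed.
#' @return a noisy [image_sequence()] with the same metadata.
#' @export
add_noise <- function(seq, sigma, seed = 1L) {
  if (!inherits(seq, "image_sequence")) {
    stop("'seq' must be an image_sequence", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  }
  if (sigma == 0) return(seq)
  frames <- with_seed(seed, lapply(seq$frames, function(f) {
    noisy <- f + matrix(stats::rnorm(length(f), sd = sigma), nrow(f), ncol(f))
    as_frame(pmin(pmax(round(noisy), 0), 255))
  }))
  image_sequence(frames, frame_rate = seq$frame_rate,
                 pixel_size = seq$pixel_size)
}

#' Ground-truth mean-speed trace of a phantom
#'
#' The exact counterpart of [speed_trace()]: for every frame pair, the mean
#' magnitude of the true displacement over the grid positions covered by the
#' ROI. Used to validate event detection independently of the integer block
#' matcher (whose per-pair estimates are quantised to whole pixels).
#'
#' @param truth a `phantom_truth`.
#' @param roi a logical mask matrix, [roi_mask()], or `NULL` for the truth's
#'   own ROI (the always-tissue disk for beating phantoms, the full frame for
#'   translation sequences).
#' @param pixel_size micrometres per pixel for unit conversion, or `NULL` to
#'   report pixels/frame.
#' @return a `speed_trace` (see [speed_trace()]).
#' @export
true_speed_trace <- function(truth, roi = NULL, pixel_size = NULL) {
  if (!inherits(truth, "phantom_truth")) {
    stop("'truth' must be a phantom_truth", call. = FALSE)
  }
  if (is.null(roi)) {
    roi <- if (is.null(truth$roi)) {
      matrix(TRUE, truth$frame_dim[["height"]], truth$frame_dim[["width"]])
    } else truth$roi
  }
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  gp <- truth$fields[[1L]]
  covered <- mask[cbind(gp$gy + 1L, gp$gx + 1L)]
  if (!any(covered)) stop("ROI covers no grid positions", call. = FALSE)
  speeds <- vapply(truth$fields, function(f) {
    mean(sqrt(f$dx[covered]^2 + f$dy[covered]^2))
  }, numeric(1))
  times <- seq_along(truth$fields) / truth$frame_rate
  units <- "pixels_per_frame"
  if (!is.null(pixel_size)) {
    speeds <- speeds * pixel_size * truth$frame_rate
    units <- "um_per_s"
  }
  new_speed_trace(times, speeds, rep(sum(covered), length(speeds)),
                  units = units, frame_rate = truth$frame_rate)
}
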