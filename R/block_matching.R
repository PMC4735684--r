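# Exhaustive mean-absolute-error block matching on a dense grid.
#
# Each N x N block of the current frame is compared against displaced copies
# of itself in the previous frame, over all integer offsets (i, j) with
# |i| <= w, |j| <= w (a search window of width N + 2w). The offset minimising
# the mean absolute intensity difference locates where the block's content WAS
# in the previous frame, so the reported motion vector of the tissue is its
# negation: v = (dx, dy) = (-i, -j). A rightward-moving object therefore
# yields positive dx. Only |v| feeds the downstream speed metrics, but the
# sign convention is fixed and documented so the exported vector fields are
# interpretable.
#
# Arithmetic note: intensities are exact integers, so the per-block sum of
# absolute differences is an exact integer (at most 255 * N^2, far below
# 2^53); scores are that sum divided by N^2. This makes the vectorised
# integral-image implementation bit-identical to a naive triple loop.

#' Block-matching configuration
#'
#' Defaults reproduce the published analysis: 16 x 16 pixel blocks, a maximum
#' displacement of 4 pixels per frame (search window of width N + 2w = 24) and
#' one vector every 4 x 4 pixels, which yields 32,768 vectors on a
#' 1,024 x 512 frame.
#'
#' @param block_size N, the block side length in pixels (>= 1).
#' @param max_displacement w, the maximum displacement searched, in pixels per
#'   frame (>= 0).
#' @param stride grid spacing s in pixels: one vector is computed for every
#'   s x s pixel cell (>= 1).
#' @return an object of class `block_match_config`.
#' @export
block_match_config <- function(block_size = 16L, max_displacement = 4L,
                               stride = 4L) {
  block_size <- as.integer(block_size)
  max_displacement <- as.integer(max_displacement)
  stride <- as.integer(stride)
  if (is.na(block_size) || block_size < 1L) {
    stop("'block_size' must be a positive integer", call. = FALSE)
  }
  if (is.na(max_displacement) || max_displacement < 0L) {
    stop("'max_displacement' must be a non-negative integer", call. = FALSE)
  }
  if (is.na(stride) || stride < 1L) {
    stop("'stride' must be a positive integer", call. = FALSE)
  }
  structure(list(block_size = block_size, max_displacement = max_displacement,
                 stride = stride),
            class = "block_match_config")
}

#' @export
print.block_match_config <- function(x, ...) {
  cat(sprintf(
    "block_match_config: N = %d, w = %d (search window %d px), stride = %d\n",
    x$block_size, x$max_displacement, x$block_size + 2L * x$max_displacement,
    x$stride))
  invisible(x)
}

#' Number of grid vectors for a frame geometry
#'
#' One motion vector is computed for every `stride` x `stride` pixel cell, so
#' the count is `floor(width / stride) * floor(height / stride)` regardless of
#' border validity: 32,768 for a 1,024 x 512 frame at stride 4.
#'
#' @param height,width frame dimensions in pixels.
#' @param stride grid spacing in pixels.
#' @return integer count of grid positions.
#' @export
count_grid_vectors <- function(height, width, stride) {
  if (any(c(height, width, stride) <= 0)) {
    stop("'height', 'width' and 'stride' must be positive", call. = FALSE)
  }
  as.integer(floor(width / stride)) * as.integer(floor(height / stride))
}

# Grid anchors in 0-based pixel coordinates: gx = s*k for k = 0 .. floor(W/s)-1
# (x varies fastest). Every position is listed; validity is a separate flag.
grid_positions <- function(height, width, stride) {
  gxs <- stride * (seq_len(floor(width / stride)) - 1L)
  gys <- stride * (seq_len(floor(height / stride)) - 1L)
  list(gx = rep(as.integer(gxs), times = length(gys)),
       gy = rep(as.integer(gys), each = length(gxs)))
}

# Block pixel offsets around an anchor: -floor(N/2) .. N-1-floor(N/2)
# (for even N: -N/2 .. N/2-1, centring the block on its grid point).
block_extent <- function(block_size) {
  lo <- -(block_size %/% 2L)
  c(lo = lo, hi = block_size - 1L + lo)
}

# Candidate offsets (i, j), ordered so that the first strict minimum
# encountered realises the tie-break: smallest |v|^2 first, then smallest dy,
# then smallest dx, where v = (-i, -j) is the reported vector.
candidate_offsets <- function(w) {
  i <- rep(-w:w, times = 2L * w + 1L)
  j <- rep(-w:w, each = 2L * w + 1L)
  dx <- -i
  dy <- -j
  ord <- order(dx^2 + dy^2, dy, dx)
  list(i = i[ord], j = j[ord])
}

check_frame_pair <- function(previous, current) {
  previous <- as_frame(previous)
  current <- as_frame(current)
  if (!identical(dim(previous), dim(current))) {
    stop("'previous' and 'current' frames must have equal dimensions",
         call. = FALSE)
  }
  list(previous = previous, current = current)
}

#' Mean absolute error of one block against a displaced block
#'
#' The matching criterion: the mean over the N^2 block pixels of
#' `|f_t(m, n) - f_{t-1}(m + i, n + j)|`, where `f_t` is the current frame and
#' the block is centred on `anchor`. Zero if and only if the two blocks are
#' pixel-identical.
#'
#' @param current,previous frames (integer matrices of equal size).
#' @param anchor grid position `c(gx, gy)` in 0-based pixel coordinates.
#' @param candidate offset `c(i, j)` into the previous frame.
#' @param config a [block_match_config()].
#' @return the mean absolute intensity difference (>= 0).
#' @export
mae_score <- function(current, previous, anchor, candidate,
                      config = block_match_config()) {
  fp <- check_frame_pair(previous, current)
  N <- config$block_size
  ext <- block_extent(N)
  h <- nrow(fp$current); w <- ncol(fp$current)
  gx <- anchor[[1L]]; gy <- anchor[[2L]]
  i <- candidate[[1L]]; j <- candidate[[2L]]
  x0 <- gx + ext[["lo"]]; x1 <- gx + ext[["hi"]]
  y0 <- gy + ext[["lo"]]; y1 <- gy + ext[["hi"]]
  if (x0 < 0L || y0 < 0L || x1 > w - 1L || y1 > h - 1L ||
      x0 + i < 0L || y0 + j < 0L || x1 + i > w - 1L || y1 + j > h - 1L) {
    stop("block or displaced block lies outside the frame", call. = FALSE)
  }
  cur <- fp$current[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), drop = FALSE]
  prv <- fp$previous[(y0 + j + 1L):(y1 + j + 1L),
                     (x0 + i + 1L):(x1 + i + 1L), drop = FALSE]
  sum(abs(cur - prv)) / (N * N)
}

#' Match a single block between two frames
#'
#' Exhaustive search over all offsets with `|i| <= w`, `|j| <= w`. The result
#' is invalid (vector `(0, 0)`, score `NA`) when the centred block or any
#' candidate position would leave the frame; ties are broken towards the
#' smallest vector magnitude, then smallest dy, then smallest dx, so constant
#' frames report "no motion".
#'
#' @inheritParams mae_score
#' @return a list with elements `dx`, `dy` (tissue displacement, previous ->
#'   current frame), `score` and `valid`.
#' @export
match_block <- function(current, previous, anchor,
                        config = block_match_config()) {
  fp <- check_frame_pair(previous, current)
  N <- config$block_size; w <- config$max_displacement
  ext <- block_extent(N)
  H <- nrow(fp$current); W <- ncol(fp$current)
  gx <- anchor[[1L]]; gy <- anchor[[2L]]
  if (gx + ext[["lo"]] - w < 0L || gy + ext[["lo"]] - w < 0L ||
      gx + ext[["hi"]] + w > W - 1L || gy + ext[["hi"]] + w > H - 1L) {
    return(list(dx = 0L, dy = 0L, score = NA_real_, valid = FALSE))
  }
  cand <- candidate_offsets(w)
  best <- Inf; bi <- 0L; bj <- 0L
  cur <- fp$current[(gy + ext[["lo"]] + 1L):(gy + ext[["hi"]] + 1L),
                    (gx + ext[["lo"]] + 1L):(gx + ext[["hi"]] + 1L),
                    drop = FALSE]
  for (k in seq_along(cand$i)) {
    i <- cand$i[k]; j <- cand$j[k]
    prv <- fp$previous[(gy + j + ext[["lo"]] + 1L):(gy + j + ext[["hi"]] + 1L),
                       (gx + i + ext[["lo"]] + 1L):(gx + i + ext[["hi"]] + 1L),
                       drop = FALSE]
    s <- sum(abs(cur - prv))
    if (s < best) {
      best <- s; bi <- i; bj <- j
    }
  }
  list(dx = -bi, dy = -bj, score = best / (N * N), valid = TRUE)
}

#' Dense motion-vector field between two consecutive frames
#'
#' Computes one motion vector for every `stride` x `stride` pixel cell of the
#' frame by exhaustive MAE block matching. The returned data frame has one row
#' per grid position (all `floor(width/stride) * floor(height/stride)` of
#' them); positions whose block or search window would leave the frame are
#' flagged `valid = FALSE` and carry vector `(0, 0)` with score `NA`.
#'
#' The implementation evaluates each of the `(2w+1)^2` candidate offsets over
#' the whole frame at once via an integral image of absolute differences; the
#' result is bit-identical to per-block exhaustive search because all sums are
#' exact integer arithmetic.
#'
#' @param previous,current frames (integer matrices of equal size).
#' @param config a [block_match_config()].
#' @param frame_index index of the later frame of the pair (0-based), recorded
#'   in the output for bookkeeping.
#' @return a data frame of class `motion_field` with columns `gx`, `gy`
#'   (0-based pixel coordinates of the grid anchor), `dx`, `dy` (integer
#'   pixels/frame), `score` (mean absolute error of the best match) and
#'   `valid`; frame geometry and configuration are kept in attributes.
#' @export
compute_motion_field <- function(previous, current,
                                 config = block_match_config(),
                                 frame_index = 1L) {
  fp <- check_frame_pair(previous, current)
  N <- config$block_size; w <- config$max_displacement; s <- config$stride
  ext <- block_extent(N)
  H <- nrow(fp$current); W <- ncol(fp$current)
  gp <- grid_positions(H, W, s)
  n <- length(gp$gx)
  if (n == 0L) stop("frame too small for the requested stride", call. = FALSE)

  valid <- gp$gx + ext[["lo"]] - w >= 0L & gp$gy + ext[["lo"]] - w >= 0L &
    gp$gx + ext[["hi"]] + w <= W - 1L & gp$gy + ext[["hi"]] + w <= H - 1L

  dx <- integer(n); dy <- integer(n); score <- rep(NA_real_, n)
  va <- which(valid)
  if (length(va) > 0L) {
    cur <- fp$current; prv <- fp$previous
    storage.mode(cur) <- "double"; storage.mode(prv) <- "double"
    # block corners (1-based rows/cols) for the valid anchors
    r1 <- gp$gy[va] + ext[["lo"]] + 1L; r2 <- gp$gy[va] + ext[["hi"]] + 1L
    c1 <- gp$gx[va] + ext[["lo"]] + 1L; c2 <- gp$gx[va] + ext[["hi"]] + 1L
    idx_br <- cbind(r2 + 1L, c2 + 1L); idx_tr <- cbind(r1, c2 + 1L)
    idx_bl <- cbind(r2 + 1L, c1); idx_tl <- cbind(r1, c1)

    cand <- candidate_offsets(w)
    best <- rep(Inf, length(va))
    bi <- integer(length(va)); bj <- integer(length(va))
    D <- matrix(0, H, W)
    for (k in seq_along(cand$i)) {
      i <- cand$i[k]; j <- cand$j[k]
      rmin <- max(1L, 1L - j); rmax <- min(H, H - j)
      cmin <- max(1L, 1L - i); cmax <- min(W, W - i)
      D[] <- 0
      D[rmin:rmax, cmin:cmax] <-
        abs(cur[rmin:rmax, cmin:cmax, drop = FALSE] -
            prv[(rmin + j):(rmax + j), (cmin + i):(cmax + i), drop = FALSE])
      # padded integral image: P[r+1, c+1] = sum of D[1:r, 1:c]
      P <- matrix(0, H + 1L, W + 1L)
      P[-1L, -1L] <- t(apply(apply(D, 2L, cumsum), 1L, cumsum))
      sums <- P[idx_br] - P[idx_tr] - P[idx_bl] + P[idx_tl]
      better <- sums < best
      if (any(better)) {
        best[better] <- sums[better]
        bi[better] <- i
        bj[better] <- j
      }
    }
    dx[va] <- -bi; dy[va] <- -bj
    score[va] <- best / (N * N)
  }

  out <- data.frame(gx = gp$gx, gy = gp$gy, dx = dx, dy = dy,
                    score = score, valid = valid)
  attr(out, "frame_dim") <- c(height = H, width = W)
  attr(out, "config") <- config
  attr(out, "frame_index") <- as.integer(frame_index)
  class(out) <- c("motion_field", "data.frame")
  out
}

#' Motion fields for every consecutive frame pair of a sequence
#'
#' @param seq an [image_sequence()] with at least two frames.
#' @param config a [block_match_config()].
#' @return a list of `length(seq) - 1` motion fields; field `k` is computed
#'   from frames `k` and `k + 1` and carries `frame_index = k` (0-based index
#'   of the later frame).
#' @export
compute_sequence_fields <- function(seq, config = block_match_config()) {
  if (!inherits(seq, "image_sequence")) {
    stop("'seq' must be an image_sequence", call. = FALSE)
  }
  nf <- length(seq$frames)
  if (nf < 2L) {
    stop("motion analysis needs at least 2 frames", call. = FALSE)
  }
  lapply(seq_len(nf - 1L), function(k) {
    compute_motion_field(seq$frames[[k]], seq$frames[[k + 1L]],
                         config = config, frame_index = k)
  })
}

#' @export
print.motion_field <- function(x, ...) {
  d <- attr(x, "frame_dim")
  cat(sprintf(
    "motion_field: %d grid vectors (%d valid) on a %d x %d frame, pair -> frame %d\n",
    nrow(x), sum(x$valid), d[["width"]], d[["height"]],
    attr(x, "frame_index")))
  invisible(x)
}
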