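# Independent naive exhaustive-search block matcher.
#
# Deliberately written as plain loops, sharing no code with the package's
# integral-image implementation: this is the oracle the optimized matcher is
# compared against, bit for bit. The only shared *convention* is the one the
# package documents: blocks centred on grid anchors (offsets -floor(N/2) ..
# N-1-floor(N/2)), vector = minus the minimising offset, ties broken towards
# the smallest |v|^2, then smallest dy, then smallest dx.

naive_motion_field <- function(previous, current, N = 16L, w = 4L, s = 4L) {
  H <- nrow(current); W <- ncol(current)
  lo <- -(N %/% 2L); hi <- N - 1L + lo
  gxs <- s * (0:(floor(W / s) - 1L))
  gys <- s * (0:(floor(H / s) - 1L))
  grid <- expand.grid(gx = gxs, gy = gys)   # gx varies fastest
  n <- nrow(grid)
  dx <- integer(n); dy <- integer(n)
  score <- rep(NA_real_, n); valid <- logical(n)

  # candidate offsets in tie-break priority order
  cand <- expand.grid(i = -w:w, j = -w:w)
  cand$vx <- -cand$i; cand$vy <- -cand$j
  cand <- cand[order(cand$vx^2 + cand$vy^2, cand$vy, cand$vx), ]

  for (q in seq_len(n)) {
    gx <- grid$gx[q]; gy <- grid$gy[q]
    if (gx + lo - w < 0L || gy + lo - w < 0L ||
        gx + hi + w > W - 1L || gy + hi + w > H - 1L) next
    valid[q] <- TRUE
    cur <- current[(gy + lo + 1L):(gy + hi + 1L),
                   (gx + lo + 1L):(gx + hi + 1L)]
    best <- Inf; bvx <- 0L; bvy <- 0L
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      prv <- previous[(gy + j + lo + 1L):(gy + j + hi + 1L),
                      (gx + i + lo + 1L):(gx + i + hi + 1L)]
      ss <- 0
      for (col in seq_len(N)) ss <- ss + sum(abs(cur[, col] - prv[, col]))
      if (ss < best) {
        best <- ss; bvx <- cand$vx[r]; bvy <- cand$vy[r]
      }
    }
    dx[q] <- bvx; dy[q] <- bvy; score[q] <- best / (N * N)
  }
  data.frame(gx = grid$gx, gy = grid$gy, dx = dx, dy = dy,
             score = score, valid = valid)
}

# Naive double-loop MAE for one block and one candidate offset.
naive_mae <- function(current, previous, gx, gy, i, j, N = 16L) {
  lo <- -(N %/% 2L)
  total <- 0
  for (a in 0:(N - 1L)) {
    for (b in 0:(N - 1L)) {
      m <- gy + lo + a; nn <- gx + lo + b
      total <- total + abs(current[m + 1L, nn + 1L] -
                             previous[m + j + 1L, nn + i + 1L])
    }
  }
  total / (N * N)
}
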