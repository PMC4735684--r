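# From vector fields to contraction kinetics.
#
# The spatial average |V| of motion-vector magnitudes over the valid vectors
# inside an ROI is the "average speed" of the tissue at one frame pair;
# contraction and relaxation both give positive values. Plotted against time
# it shows two bumps per beat; events are isolated by thresholding, and each
# contraction is summarised by its duration and by the time integral of the
# average speed over the event (the averaged contraction deformation
# distance, i.e. the mean path length travelled by the tissue).

#' Region of interest
#'
#' Either a boolean mask matching the frame geometry or an axis-aligned
#' rectangle in 0-based pixel coordinates. A grid position is covered when the
#' mask is true at its anchor pixel.
#'
#' @param mask logical (or 0/1 numeric) matrix, nonzero = inside; or `NULL`
#'   when `rect` is given.
#' @param rect rectangle `c(x0, y0, width, height)` in pixels, 0-based.
#' @param dim frame dimensions `c(height, width)`; required with `rect`,
#'   optional (consistency-checked) with `mask`.
#' @return an object of class `roi_mask` holding the logical mask.
#' @export
roi_mask <- function(mask = NULL, rect = NULL, dim = NULL) {
  if (is.null(mask) == is.null(rect)) {
    stop("give exactly one of 'mask' or 'rect'", call. = FALSE)
  }
  if (!is.null(rect)) {
    if (is.null(dim)) stop("'dim' is required with 'rect'", call. = FALSE)
    rect <- as.numeric(rect)
    if (length(rect) != 4L || rect[3L] <= 0 || rect[4L] <= 0) {
      stop("'rect' must be c(x0, y0, width, height) with positive size",
           call. = FALSE)
    }
    H <- dim[[1L]]; W <- dim[[2L]]
    if (rect[1L] < 0 || rect[2L] < 0 ||
        rect[1L] + rect[3L] > W || rect[2L] + rect[4L] > H) {
      stop("rectangle does not fit inside the frame", call. = FALSE)
    }
    mask <- matrix(FALSE, H, W)
    mask[(rect[2L] + 1L):(rect[2L] + rect[4L]),
         (rect[1L] + 1L):(rect[1L] + rect[3L])] <- TRUE
  } else {
    if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
    mask <- mask != 0
    if (!is.null(dim) && !identical(base::dim(mask), as.integer(dim))) {
      stop("mask dimensions do not match the frame", call. = FALSE)
    }
  }
  if (!any(mask)) stop("ROI is empty", call. = FALSE)
  structure(list(mask = mask), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d of %d pixels inside (%d x %d frame)\n",
              sum(x$mask), length(x$mask), ncol(x$mask), nrow(x$mask)))
  invisible(x)
}

#' Grid positions covered by an ROI
#'
#' @param roi an [roi_mask()] or logical matrix.
#' @param stride grid spacing in pixels.
#' @return data frame of covered grid anchors `gx`, `gy` (0-based).
#' @export
covered_grid_positions <- function(roi, stride = 4L) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi != 0
  gp <- grid_positions(nrow(mask), ncol(mask), stride)
  keep <- mask[cbind(gp$gy + 1L, gp$gx + 1L)]
  data.frame(gx = gp$gx[keep], gy = gp$gy[keep])
}

roi_cover_flags <- function(field, roi) {
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi != 0
  d <- attr(field, "frame_dim")
  if (!is.null(d) &&
      !identical(dim(mask), as.integer(c(d[["height"]], d[["width"]])))) {
    stop("ROI dimensions do not match the motion field's frame", call. = FALSE)
  }
  mask[cbind(field$gy + 1L, field$gx + 1L)]
}

#' ROI-averaged speed of one motion field
#'
#' The spatial average `(1/N_ROI) * sum_i sqrt(dx_i^2 + dy_i^2)` over the
#' valid vectors whose grid anchor lies inside the ROI. An ROI with no valid
#' vectors is an error (condition class `bamotion_no_valid_vectors`), not a
#' silent zero.
#'
#' @param field a motion field from [compute_motion_field()].
#' @param roi an [roi_mask()] or logical matrix.
#' @return mean vector magnitude in pixels/frame.
#' @export
average_speed <- function(field, roi) {
  sel <- field$valid & roi_cover_flags(field, roi)
  if (!any(sel)) {
    stop(structure(class = c("bamotion_no_valid_vectors", "error", "condition"),
                   list(message = "no valid motion vectors inside the ROI",
                        call = sys.call())))
  }
  mean(sqrt(field$dx[sel]^2 + field$dy[sel]^2))
}

new_speed_trace <- function(time_s, speed, n_valid, units, frame_rate) {
  out <- data.frame(time_s = time_s, speed = speed,
                    n_valid = as.integer(n_valid))
  attr(out, "units") <- units
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("speed_trace", "data.frame")
  out
}

#' Average-speed trace over a sequence of motion fields
#'
#' One sample per frame pair. Field `k` (frames `k-1 -> k`, 0-based) is
#' timestamped at `frame_index / frame_rate`, i.e. at the arrival of the later
#' frame. Speeds are pixels/frame, or micrometres/second when `pixel_size` is
#' given (`speed_um_s = speed_px_frame * pixel_size * frame_rate`). Time
#' points whose ROI holds no valid vector become `NA` with a warning; they are
#' excluded downstream rather than zero-filled, since a zero would fabricate
#' apparent quiescence.
#'
#' @param fields list of motion fields from [compute_sequence_fields()].
#' @param roi an [roi_mask()] or logical matrix.
#' @param frame_rate frames per second.
#' @param pixel_size micrometres per pixel, or `NULL`.
#' @return a data frame of class `speed_trace` with columns `time_s`, `speed`
#'   and `n_valid` (`N_ROI`, the number of valid vectors averaged).
#' @export
speed_trace <- function(fields, roi, frame_rate, pixel_size = NULL) {
  if (length(fields) < 1L) stop("no motion fields given", call. = FALSE)
  n <- length(fields)
  speeds <- numeric(n); nval <- integer(n); times <- numeric(n)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    sel <- f$valid & roi_cover_flags(f, roi)
    nval[k] <- sum(sel)
    speeds[k] <- if (nval[k] > 0L) {
      mean(sqrt(f$dx[sel]^2 + f$dy[sel]^2))
    } else NA_real_
    fi <- attr(f, "frame_index")
    times[k] <- (if (is.null(fi)) k else fi) / frame_rate
  }
  if (anyNA(speeds)) {
    warning(sprintf("%d time point(s) had no valid vectors in the ROI; %s",
                    sum(is.na(speeds)), "set to NA"), call. = FALSE)
  }
  units <- "pixels_per_frame"
  if (!is.null(pixel_size)) {
    speeds <- speeds * pixel_size * frame_rate
    units <- "um_per_s"
  }
  new_speed_trace(times, speeds, nval, units, frame_rate)
}

#' @export
print.speed_trace <- function(x, ...) {
  cat(sprintf("speed_trace: %d samples, units %s, peak %.4g\n",
              nrow(x), attr(x, "units"), suppressWarnings(max(x$speed,
                                                              na.rm = TRUE))))
  invisible(x)
}

#' @export
plot.speed_trace <- function(x, events = NULL, ...) {
  ylab <- if (identical(attr(x, "units"), "um_per_s")) {
    "average speed (um/s)"
  } else "average speed (pixels/frame)"
  graphics::plot(x$time_s, x$speed, type = "l", xlab = "time (s)",
                 ylab = ylab, ...)
  if (!is.null(events) && nrow(events) > 0L) {
    for (k in seq_len(nrow(events))) {
      graphics::rect(events$onset_s[k], graphics::par("usr")[3L],
                     events$offset_s[k], graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("firebrick", 0.15),
                     border = NA)
    }
    graphics::points(events$peak_s, events$peak_speed, pch = 19,
                     col = "firebrick")
  }
  invisible(x)
}

#' Detect contraction events in a speed trace
#'
#' Threshold-based isolation: (i) the threshold is
#' `threshold_fraction * max(speed)`; (ii) maximal runs of samples at or above
#' the threshold are found, closing sub-threshold gaps shorter than
#' `min_separation`; (iii) runs are paired into beat cycles and, by default,
#' the first run of each cycle is labelled the contraction (outflow-tract
#' distension follows ventricular ejection, so the contraction bump precedes
#' the relaxation bump; set `contraction_first = FALSE` to swap); (iv) each
#' contraction run becomes one event whose onset and offset are the threshold
#' crossings, linearly interpolated between samples, and whose peak is the
#' run's maximum.
#'
#' `NA` samples (time points without valid vectors) can never lie inside a
#' run; a warning reports how many were excluded. An all-zero trace yields no
#' events. Degenerate events that would have zero duration (single-sample runs
#' clipped at both trace ends) are dropped.
#'
#' @param trace a [speed_trace()].
#' @param threshold_fraction fraction of the trace maximum, in (0, 1).
#' @param min_separation minimum quiescent gap, in seconds, required to split
#'   two runs; shorter gaps are bridged.
#' @param contraction_first label the first run of each cycle as the
#'   contraction (default) or the second.
#' @return a data frame of class `contraction_events` with columns `onset_s`,
#'   `peak_s`, `offset_s`, `duration_s` and `peak_speed`; the threshold used
#'   is stored in the `threshold` attribute.
#' @export
detect_contractions <- function(trace, threshold_fraction = 0.2,
                                min_separation = 0, contraction_first = TRUE) {
  if (!inherits(trace, "speed_trace") || nrow(trace) == 0L) {
    stop("'trace' must be a non-empty speed_trace", call. = FALSE)
  }
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("'threshold_fraction' must lie strictly in (0, 1)", call. = FALSE)
  }
  t <- trace$time_s; v <- trace$speed
  if (anyNA(v)) {
    warning(sprintf("excluding %d missing time point(s) from event detection",
                    sum(is.na(v))), call. = FALSE)
  }
  vmax <- suppressWarnings(max(v, na.rm = TRUE))
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      peak_speed = numeric(0))
  if (!is.finite(vmax) || vmax <= 0) {
    attr(empty, "threshold") <- 0
    class(empty) <- c("contraction_events", "data.frame")
    return(empty)
  }
  thr <- threshold_fraction * vmax
  dt <- if (nrow(trace) > 1L) stats::median(diff(t)) else 1 / max(
    attr(trace, "frame_rate"), 1)

  above <- !is.na(v) & v >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # close interior sub-threshold gaps shorter than min_separation
  if (min_separation > 0 && length(r$values) > 2L) {
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1L && k < length(r$values) &&
          r$lengths[k] * dt < min_separation &&
          !anyNA(v[starts[k]:ends[k]])) {
        above[starts[k]:ends[k]] <- TRUE
      }
    }
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
  }
  run_idx <- which(r$values)
  if (length(run_idx) == 0L) {
    attr(empty, "threshold") <- thr
    class(empty) <- c("contraction_events", "data.frame")
    return(empty)
  }
  pick <- if (contraction_first) {
    run_idx[seq_along(run_idx) %% 2L == 1L]
  } else {
    run_idx[seq_along(run_idx) %% 2L == 0L]
  }
  ev <- lapply(pick, function(k) {
    a <- starts[k]; b <- ends[k]
    onset <- if (a > 1L && !is.na(v[a - 1L])) {
      t[a - 1L] + (thr - v[a - 1L]) / (v[a] - v[a - 1L]) * (t[a] - t[a - 1L])
    } else t[a]
    offset <- if (b < length(v) && !is.na(v[b + 1L])) {
      t[b] + (v[b] - thr) / (v[b] - v[b + 1L]) * (t[b + 1L] - t[b])
    } else t[b]
    pk <- a - 1L + which.max(v[a:b])
    c(onset = onset, peak = t[pk], offset = offset, peak_speed = v[pk])
  })
  ev <- do.call(rbind, ev)
  out <- data.frame(onset_s = ev[, "onset"], peak_s = ev[, "peak"],
                    offset_s = ev[, "offset"],
                    duration_s = ev[, "offset"] - ev[, "onset"],
                    peak_speed = ev[, "peak_speed"])
  out <- out[out$duration_s > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  class(out) <- c("contraction_events", "data.frame")
  out
}

#' Contraction duration
#'
#' @param event one row of a `contraction_events` data frame (or any list
#'   with `onset_s` and `offset_s`).
#' @return duration in seconds, `offset_s - onset_s`.
#' @export
contraction_duration <- function(event) {
  d <- event$offset_s - event$onset_s
  if (any(d <= 0)) stop("event has non-positive duration", call. = FALSE)
  d
}

#' Averaged contraction deformation distance
#'
#' The time integral of the average speed over the contraction interval
#' (trapezoidal rule over the trace samples inside `[onset_s, offset_s]`,
#' with linearly interpolated endpoint values). Since the average speed is the
#' mean displacement magnitude of the tissue per unit time, the integral is
#' the mean path length travelled during the contraction: pixels for a
#' pixels/frame trace, micrometres for a converted trace. The alternative
#' reading of the endpoint (mean per-frame displacement) is
#' `deformation_distance / duration`.
#'
#' @param trace a [speed_trace()].
#' @param event one row of a `contraction_events` data frame.
#' @return the deformation distance (>= 0).
#' @export
deformation_distance <- function(trace, event) {
  t <- trace$time_s; v <- trace$speed
  on <- event$onset_s; off <- event$offset_s
  if (length(on) != 1L || length(off) != 1L || off <= on) {
    stop("'event' must be a single interval with offset > onset",
         call. = FALSE)
  }
  if (off < min(t) || on > max(t)) {
    stop("event does not overlap the trace", call. = FALSE)
  }
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("trace has fewer than 2 usable samples",
                         call. = FALSE)
  inner <- which(ok & t > on & t < off)
  v_on <- stats::approx(t[ok], v[ok], xout = on, rule = 2)$y
  v_off <- stats::approx(t[ok], v[ok], xout = off, rule = 2)$y
  ts <- c(on, t[inner], off)
  vs <- c(v_on, v[inner], v_off)
  integral <- sum(diff(ts) * (utils::head(vs, -1L) + utils::tail(vs, -1L)) / 2)
  if (identical(attr(trace, "units"), "pixels_per_frame")) {
    # speed is px/frame but time is seconds: rescale to frames
    integral <- integral * attr(trace, "frame_rate")
  }
  integral
}

#' Per-recording event summary
#'
#' Arithmetic means across the events of one recording (one animal): mean
#' contraction duration and, when available, mean deformation distance.
#'
#' @param events a `contraction_events` data frame, optionally carrying a
#'   `deformation_distance` column (added by [analyze_motion()]).
#' @param trace optional [speed_trace()]; when given and the column is
#'   absent, deformation distances are computed from it.
#' @return a list with `n_events`, `mean_duration_s` and
#'   `mean_deformation_distance` (`NA` if not computable).
#' @export
summarize_events <- function(events, trace = NULL) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("no events to summarise", call. = FALSE)
  }
  dd <- events$deformation_distance
  if (is.null(dd) && !is.null(trace)) {
    dd <- vapply(seq_len(nrow(events)), function(k) {
      deformation_distance(trace, events[k, , drop = FALSE])
    }, numeric(1))
  }
  list(n_events = nrow(events),
       mean_duration_s = mean(events$duration_s),
       mean_deformation_distance = if (is.null(dd)) NA_real_ else mean(dd))
}

#' Two-group comparison of per-animal endpoint values
#'
#' Welch's two-sample t-test (two-sided) by default; the pooled-variance
#' Student variant is available with `var_equal = TRUE`. Group means and
#' sample standard deviations (n - 1 denominator) are reported alongside the
#' statistic. When both groups have zero variance the test degenerates: equal
#' means give `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b numeric vectors of per-animal values (length >= 2).
#' @param var_equal use the pooled-variance Student t-test instead of Welch.
#' @param alpha significance level for the reported flag.
#' @return an object of class `group_comparison`.
#' @export
compare_groups <- function(group_a, group_b, var_equal = FALSE,
                           alpha = 0.05) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b)) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    eq <- mean(a) == mean(b)
    t_stat <- if (eq) 0 else sign(mean(a) - mean(b)) * Inf
    df <- length(a) + length(b) - 2
    p <- if (eq) 1 else 0
    method <- "degenerate (zero variance in both groups)"
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal,
                        alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
    method <- tt$method
  }
  structure(list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                 t = t_stat, df = df, p = p,
                 significant = p < alpha, alpha = alpha, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Two-group comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  group A: %.4g +/- %.4g (mean +/- s.d., n = %d)\n",
              x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  group B: %.4g +/- %.4g (mean +/- s.d., n = %d)\n",
              x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.4g, df = %.4g, P = %.4g %s\n", x$t, x$df, x$p,
              if (x$significant) sprintf("(*P < %.2g)", x$alpha)
              else sprintf("(NS: P > %.2g)", x$alpha)))
  invisible(x)
}
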