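# File formats.
#
# No TIFF package is available in this environment, so a minimal baseline
# TIFF codec is implemented here: uncompressed, strip-based, little- or
# big-endian on read (little-endian on write), 8-bit grayscale natively,
# 8-bit RGB collapsed to luminance and 16-bit grayscale rescaled to 8 bits on
# read. This covers the multi-page phantom files the package writes and the
# plain exports of typical microscopy software. Binary PGM is supported as a
# second plain carrier for single frames and ROI masks.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

tiff_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(u16(value), u16(0L)) else u32(value)
  c(u16(tag), u16(type), u32(count), val)
}

#' Write frames as a multi-page uncompressed TIFF
#'
#' Baseline grayscale TIFF, 8 bits per sample, one strip per page,
#' little-endian. Round-trips bit-exactly through [read_tiff()].
#'
#' @param x an [image_sequence()], a single frame, or a list of frames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path) {
  frames <- if (inherits(x, "image_sequence")) x$frames
            else if (is.matrix(x)) list(as_frame(x))
            else lapply(x, as_frame)
  n <- length(frames)
  if (n < 1L) stop("nothing to write", call. = FALSE)
  ifd_size <- 2L + 9L * 12L + 4L
  chunks <- vector("list", 2L * n + 1L)
  offset <- 8L
  ifd_offsets <- integer(n); data_offsets <- integer(n)
  payloads <- vector("list", n)
  for (p in seq_len(n)) {
    f <- frames[[p]]
    npix <- length(f)
    padded <- npix + npix %% 2L
    data_offsets[p] <- offset
    ifd_offsets[p] <- offset + padded
    payload <- as.raw(as.vector(t(f)))
    if (padded > npix) payload <- c(payload, as.raw(0L))
    payloads[[p]] <- payload
    offset <- ifd_offsets[p] + ifd_size
  }
  chunks[[1L]] <- c(charToRaw("II"), u16(42L), u32(ifd_offsets[1L]))
  for (p in seq_len(n)) {
    f <- frames[[p]]
    H <- nrow(f); W <- ncol(f)
    entries <- c(
      tiff_entry(256L, 4L, 1L, W),              # ImageWidth
      tiff_entry(257L, 4L, 1L, H),              # ImageLength
      tiff_entry(258L, 3L, 1L, 8L),             # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),             # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),             # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, data_offsets[p]),# StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),             # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, H),              # RowsPerStrip
      tiff_entry(279L, 4L, 1L, H * W)           # StripByteCounts
    )
    nxt <- if (p < n) ifd_offsets[p + 1L] else 0L
    chunks[[2L * p]] <- payloads[[p]]
    chunks[[2L * p + 1L]] <- c(u16(9L), entries, u32(nxt))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(do.call(c, chunks), con)
  invisible(path)
}

#' Read a (multi-page) TIFF as a list of 8-bit frames
#'
#' Supports uncompressed strip-based TIFF, either byte order. 8-bit grayscale
#' is read exactly; 8-bit RGB is converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B) and 16-bit grayscale is rescaled from the
#' full 0-65535 range to 0-255, both with a message. Compressed or tiled
#' files are rejected.
#'
#' @param path TIFF file path.
#' @return a list of frames (integer matrices).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("'", path, "' is not a TIFF file", call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("'", path, "' is not a TIFF file", call. = FALSE)
  geti <- function(off, size, n = 1L) {
    # signed = FALSE is only allowed for 1- and 2-byte reads; 4-byte offsets
    # in files this codec handles stay far below 2^31
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  }
  if (geti(2L, 2L) != 42L) stop("'", path, "' is not a TIFF file",
                                call. = FALSE)
  # 32-bit offsets can exceed R's signed int when read as LONG; read unsigned
  getlong <- function(off, n = 1L) {
    readBin(raw[(off + 1L):(off + 4L * n)], "integer", n = n, size = 4L,
            endian = endian)
  }
  get_values <- function(type, count, valoff) {
    # BYTE, ASCII, SHORT, LONG; other field types (rationals etc.) belong to
    # tags this codec ignores and are skipped
    size <- if (type <= 4L) c(1L, 1L, 2L, 4L)[type] else NA_integer_
    if (is.na(size)) return(NULL)
    total <- size * count
    if (total <= 4L) {
      geti(valoff, size, count)
    } else {
      geti(geti(valoff, 4L), size, count)
    }
  }
  frames <- list()
  ifd <- geti(4L, 4L)
  while (ifd != 0L) {
    n_entries <- geti(ifd, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- geti(off, 2L)
      type <- geti(off + 2L, 2L)
      count <- geti(off + 4L, 4L)
      tags[[as.character(tag)]] <- get_values(type, count, off + 8L)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- g(256L); H <- g(257L)
    if (is.null(W) || is.null(H)) stop("TIFF page lacks dimensions",
                                       call. = FALSE)
    if (!is.null(g(322L))) stop("tiled TIFF is not supported", call. = FALSE)
    if (g(259L, 1L)[1L] != 1L) {
      stop("compressed TIFF is not supported; re-save uncompressed",
           call. = FALSE)
    }
    spp <- g(277L, 1L)[1L]
    bits <- g(258L, 8L)
    photometric <- g(262L, 1L)[1L]
    offs <- g(273L); counts <- g(279L)
    if (is.null(offs) || is.null(counts)) {
      stop("TIFF page lacks strip layout", call. = FALSE)
    }
    bytes <- do.call(c, lapply(seq_along(offs), function(s) {
      raw[(offs[s] + 1L):(offs[s] + counts[s])]
    }))
    if (all(bits == 8L) && spp == 1L) {
      m <- matrix(as.integer(bytes[seq_len(W * H)]), nrow = H, ncol = W,
                  byrow = TRUE)
      if (identical(photometric, 0L)) m <- 255L - m
    } else if (all(bits == 8L) && spp == 3L) {
      px <- as.integer(bytes[seq_len(3L * W * H)])
      r <- px[seq(1L, length(px), by = 3L)]
      gch <- px[seq(2L, length(px), by = 3L)]
      b <- px[seq(3L, length(px), by = 3L)]
      message("converting RGB TIFF page to grayscale luminance")
      m <- matrix(as.integer(round(0.2126 * r + 0.7152 * gch + 0.0722 * b)),
                  nrow = H, ncol = W, byrow = TRUE)
    } else if (all(bits == 16L) && spp == 1L) {
      v <- readBin(bytes, "integer", n = W * H, size = 2L, signed = FALSE,
                   endian = endian)
      message("rescaling 16-bit TIFF page to 8 bits (full-range)")
      m <- matrix(as.integer(round(v / 65535 * 255)), nrow = H, ncol = W,
                  byrow = TRUE)
    } else {
      stop(sprintf("unsupported TIFF sample layout (%d samples x %s bits)",
                   spp, paste(bits, collapse = "/")), call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- as_frame(m)
    ifd <- geti(ifd + 2L + n_entries * 12L, 4L)
  }
  if (length(frames) == 0L) stop("TIFF file contains no pages", call. = FALSE)
  frames
}

#' @rdname write_tiff
#' @export
write_pgm <- function(x, path) {
  f <- as_frame(if (is.matrix(x)) x else x$frames[[1L]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(f), nrow(f))), con)
  writeBin(as.raw(as.vector(t(f))), con)
  invisible(path)
}

#' @rdname read_tiff
#' @export
read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw[1:2])
  if (!txt %in% c("P5", "P2")) stop("'", path, "' is not a PGM file",
                                    call. = FALSE)
  # tokenize the header (magic, width, height, maxval), skipping comments
  pos <- 3L; tokens <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") {
      while (rawToChar(raw[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      tok <- ""
      while (grepl("[0-9]", rawToChar(raw[pos]))) {
        tok <- paste0(tok, rawToChar(raw[pos])); pos <- pos + 1L
      }
      tokens <- c(tokens, tok)
    } else {
      pos <- pos + 1L
    }
  }
  W <- as.integer(tokens[1L]); H <- as.integer(tokens[2L])
  maxval <- as.integer(tokens[3L])
  if (maxval > 255L) stop("16-bit PGM is not supported", call. = FALSE)
  if (txt == "P5") {
    pos <- pos + 1L   # single whitespace byte after maxval
    px <- as.integer(raw[pos:(pos + W * H - 1L)])
  } else {
    body <- rawToChar(raw[pos:length(raw)])
    px <- as.integer(strsplit(trimws(body), "\\s+")[[1L]])[seq_len(W * H)]
  }
  as_frame(matrix(px, nrow = H, ncol = W, byrow = TRUE))
}

# Natural numeric sort: order by the first integer embedded in the file name,
# so f2 sorts before f10; ties and number-free names fall back to lexicographic.
natural_sort <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+).*$", "\\1", base)))
  files[order(is.na(num), num, base)]
}

#' Read an image sequence from disk
#'
#' `path` may be a multi-page TIFF, a single PGM, or a directory of
#' single-frame TIFF/PGM files which are ordered by natural numeric sort of
#' their names (`f2` before `f10`). Acquisition metadata is never guessed from
#' the files: `frame_rate` (and optionally `pixel_size`) must be supplied.
#'
#' @param path file or directory path.
#' @param frame_rate frames per second.
#' @param pixel_size micrometres per pixel, or `NULL`.
#' @return an [image_sequence()].
#' @export
read_sequence <- function(path, frame_rate, pixel_size = NULL) {
  read_one <- function(p) {
    if (grepl("\\.pgm$", p, ignore.case = TRUE)) list(read_pgm(p))
    else read_tiff(p)
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|pgm)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      stop("no TIFF/PGM frames found in '", path, "'", call. = FALSE)
    }
    files <- natural_sort(files)
    per_file <- lapply(files, read_one)
    frames <- do.call(c, per_file)
    names(frames) <- NULL
    src <- rep(basename(files), vapply(per_file, length, integer(1)))
    d <- dim(frames[[1L]])
    bad <- which(!vapply(frames, function(f) identical(dim(f), d),
                         logical(1)))
    if (length(bad) > 0L) {
      stop(sprintf("frame '%s' has dimensions differing from the first frame",
                   src[bad[1L]]), call. = FALSE)
    }
  } else if (file.exists(path)) {
    frames <- read_one(path)
  } else {
    stop("input path '", path, "' does not exist", call. = FALSE)
  }
  image_sequence(frames, frame_rate = frame_rate, pixel_size = pixel_size)
}

#' Resolve an ROI specification
#'
#' Accepts an [roi_mask()], a logical/0-1 matrix, a rectangle
#' `c(x0, y0, width, height)` (numeric vector or `"x0,y0,w,h"` string), or a
#' path to a TIFF/PGM mask image whose nonzero pixels mark the inside.
#'
#' @param spec the ROI specification.
#' @param dim frame dimensions `c(height, width)`.
#' @return an [roi_mask()].
#' @export
read_roi <- function(spec, dim) {
  if (inherits(spec, "roi_mask")) {
    if (!identical(base::dim(spec$mask), as.integer(dim))) {
      stop("ROI mask dimensions do not match the frames", call. = FALSE)
    }
    return(spec)
  }
  if (is.matrix(spec)) return(roi_mask(mask = spec, dim = dim))
  if (is.numeric(spec) && length(spec) == 4L) {
    return(roi_mask(rect = spec, dim = dim))
  }
  if (is.character(spec) && length(spec) == 1L) {
    if (grepl("^\\s*[0-9]+\\s*(,\\s*[0-9]+\\s*){3}$", spec)) {
      return(roi_mask(rect = as.numeric(strsplit(spec, ",")[[1L]]),
                      dim = dim))
    }
    if (!file.exists(spec)) {
      stop("ROI file '", spec, "' does not exist", call. = FALSE)
    }
    m <- if (grepl("\\.pgm$", spec, ignore.case = TRUE)) read_pgm(spec)
         else read_tiff(spec)[[1L]]
    if (!identical(base::dim(m), as.integer(dim))) {
      stop("ROI mask dimensions do not match the frames", call. = FALSE)
    }
    return(roi_mask(mask = m != 0, dim = dim))
  }
  stop("cannot interpret the ROI specification", call. = FALSE)
}

#' Export motion fields, traces, events and ground truth as CSV
#'
#' Stable schemas with units in every numeric column name. Field CSV:
#' `frame_index, gx_px, gy_px, dx_px, dy_px, score, valid` (one row per grid
#' position per frame pair; `frame_index` is the 0-based index of the later
#' frame). Trace CSV: `time_s, speed_px_per_frame` (or `speed_um_per_s`),
#' `n_valid`. Events CSV: `onset_s, peak_s, offset_s, duration_s, peak_speed,
#' deformation_distance_px` (or `_um`, when present).
#'
#' @param fields list of motion fields (or a single one).
#' @param trace a [speed_trace()].
#' @param events a `contraction_events` data frame.
#' @param truth a `phantom_truth`.
#' @param path,events_path output file paths.
#' @return the path written, invisibly.
#' @name csv_export
NULL

#' @rdname csv_export
#' @export
write_field_csv <- function(fields, path) {
  if (inherits(fields, "motion_field")) fields <- list(fields)
  rows <- do.call(rbind, lapply(fields, function(f) {
    data.frame(frame_index = attr(f, "frame_index"),
               gx_px = f$gx, gy_px = f$gy, dx_px = f$dx, dy_px = f$dy,
               score = f$score, valid = f$valid)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_export
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(time_s = trace$time_s, speed = trace$speed,
                    n_valid = trace$n_valid)
  names(out)[2L] <- if (identical(attr(trace, "units"), "um_per_s")) {
    "speed_um_per_s"
  } else "speed_px_per_frame"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_export
#' @export
write_events_csv <- function(events, path) {
  out <- as.data.frame(events)
  if ("deformation_distance" %in% names(out)) {
    u <- attr(events, "distance_units")
    names(out)[names(out) == "deformation_distance"] <-
      if (identical(u, "um")) "deformation_distance_um"
      else "deformation_distance_px"
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_export
#' @export
write_truth_csv <- function(truth, path, events_path = NULL) {
  rows <- do.call(rbind, lapply(seq_along(truth$fields), function(k) {
    f <- truth$fields[[k]]
    data.frame(frame_index = k, gx_px = f$gx, gy_px = f$gy,
               dx_px = f$dx, dy_px = f$dy)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  if (!is.null(events_path)) {
    ev <- truth$event_schedule
    utils::write.csv(
      data.frame(start_frame = ev$contraction_start,
                 peak_frame = ev$contraction_end,
                 end_frame = ev$relaxation_end),
      events_path, row.names = FALSE)
  }
  invisible(path)
}
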