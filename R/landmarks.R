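#' Body landmark index map (33-point schema)
#'
#' Named constant table of the zero-based indices used by the 33-point body
#' landmark convention: shoulders 11/12, elbows 13/14, wrists 15/16, index
#' fingers 19/20, hips 23/24, knees 25/26, ankles 27/28 (left/right).
#'
#' @return named integer vector of zero-based landmark indices.
#' @export
body_landmarks <- function() {
  c(shoulder_l = 11L, shoulder_r = 12L,
    elbow_l = 13L, elbow_r = 14L,
    wrist_l = 15L, wrist_r = 16L,
    index_l = 19L, index_r = 20L,
    hip_l = 23L, hip_r = 24L,
    knee_l = 25L, knee_r = 26L,
    ankle_l = 27L, ankle_r = 28L)
}

n_points_for <- function(kind) switch(kind, body = 33L, face = 478L,
                                      stop("kind must be 'body' or 'face'"))

#' Construct a landmark frame
#'
#' One camera's landmarks at one instant. `points` must have exactly 33
#' rows for `kind = "body"` and 478 for `kind = "face"`, with columns
#' `x, y, z, visibility`; x and y are normalized image coordinates in
#' `[0, 1]` with the origin at the top-left and y increasing downward, z is
#' a unitless relative depth and visibility a confidence in `[0, 1]`.
#'
#' @param kind `"body"` or `"face"`.
#' @param points numeric matrix or data frame with columns x, y, z,
#'   visibility.
#' @param frame_index nonnegative integer.
#' @param timestamp seconds.
#' @param camera_label `"A"`, `"B"` or `"C"`.
#' @return object of class `landmark_frame`.
#' @export
landmark_frame <- function(kind, points, frame_index, timestamp = NA_real_,
                           camera_label = "A") {
  kind <- match.arg(kind, c("body", "face"))
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z", "visibility")])
  rownames(pts) <- NULL
  n <- n_points_for(kind)
  if (nrow(pts) != n) {
    stop(sprintf("schema error at frame_index %s: %s frame has %d points, expected %d",
                 format(frame_index), kind, nrow(pts), n), call. = FALSE)
  }
  if (!all(is.finite(pts[, c("x", "y")]))) {
    stop(sprintf("non-finite x/y coordinates at frame_index %s",
                 format(frame_index)), call. = FALSE)
  }
  if (any(pts[, "visibility"] < 0 | pts[, "visibility"] > 1, na.rm = TRUE)) {
    stop("visibility must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(frame_index) == 1L, frame_index >= 0,
            frame_index == round(frame_index))
  camera_label <- match.arg(camera_label, c("A", "B", "C"))
  structure(list(kind = kind, points = pts,
                 frame_index = as.integer(frame_index),
                 timestamp = as.numeric(timestamp),
                 camera_label = camera_label),
            class = "landmark_frame")
}

#' Construct a camera stream
#'
#' An ordered sequence of landmark frames from one camera. All frames must
#' share the stream's kind and camera label and have strictly increasing
#' frame indices.
#'
#' @param frames list of [landmark_frame()] objects.
#' @param fps frames per second (> 0).
#' @param resolution pixel size `c(width, height)`.
#' @return object of class `camera_stream`.
#' @export
camera_stream <- function(frames, fps = 30, resolution = c(1920L, 1080L)) {
  stopifnot(is.list(frames), length(frames) >= 1L, fps > 0,
            length(resolution) == 2L, all(resolution > 0))
  kinds <- vapply(frames, function(f) f$kind, character(1))
  labels <- vapply(frames, function(f) f$camera_label, character(1))
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (length(unique(kinds)) != 1L || length(unique(labels)) != 1L) {
    stop("all frames in a stream must share kind and camera_label",
         call. = FALSE)
  }
  if (any(diff(idx) <= 0)) {
    stop("ordering error: frame_index must be strictly increasing",
         call. = FALSE)
  }
  structure(list(camera_label = labels[1], kind = kinds[1], frames = frames,
                 fps = fps, resolution = as.integer(resolution)),
            class = "camera_stream")
}

#' @export
print.camera_stream <- function(x, ...) {
  cat(sprintf("<camera_stream %s> %d %s frames @ %g fps, %dx%d\n",
              x$camera_label, length(x$frames), x$kind, x$fps,
              x$resolution[1], x$resolution[2]))
  invisible(x)
}

#' @export
length.camera_stream <- function(x) length(x$frames)

#' Read a landmark stream from disk
#'
#' Two plain-text dialects are supported and auto-detected from the file
#' extension (`.jsonl` vs `.csv`):
#' * JSON-lines: one frame per line, an object with fields `kind`,
#'   `frame_index`, `timestamp`, `camera_label` and `points` (array of
#'   `{x, y, z, visibility}` objects).
#' * CSV: one row per (frame, point) with columns
#'   `frame,idx,x,y,z,visibility`; kind and camera label are taken from the
#'   arguments.
#'
#' @param path file path.
#' @param kind `"body"` or `"face"` (enforced against the file contents).
#' @param camera_label camera label used for the CSV dialect (the JSON-lines
#'   dialect carries its own).
#' @param fps,resolution stream metadata, recorded as given (the dialects do
#'   not carry them).
#' @return a [camera_stream()].
#' @export
read_landmark_stream <- function(path, kind, camera_label = "A",
                                 fps = 30, resolution = c(1920L, 1080L)) {
  kind <- match.arg(kind, c("body", "face"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    frames <- read_stream_csv(path, kind, camera_label)
  } else {
    frames <- read_stream_jsonl(path, kind)
  }
  if (length(frames) == 0L) {
    stop("empty landmark stream: ", path, call. = FALSE)
  }
  camera_stream(frames, fps = fps, resolution = resolution)
}

read_stream_jsonl <- function(path, kind) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    if (!identical(rec$kind, kind)) {
      stop(sprintf("schema error at frame_index %s: kind '%s' does not match requested '%s'",
                   format(rec$frame_index), rec$kind, kind), call. = FALSE)
    }
    landmark_frame(kind, as.data.frame(rec$points), rec$frame_index,
                   rec$timestamp %||% NA_real_, rec$camera_label %||% "A")
  })
}

read_stream_csv <- function(path, kind, camera_label) {
  tab <- utils::read.csv(path)
  need <- c("frame", "idx", "x", "y", "z", "visibility")
  if (!all(need %in% names(tab))) {
    stop("CSV dialect requires columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  unname(lapply(split(tab, tab$frame), function(d) {
    d <- d[order(d$idx), ]
    landmark_frame(kind, d[, c("x", "y", "z", "visibility")], d$frame[1],
                   camera_label = camera_label)
  }))
}

#' Write a landmark stream to disk
#'
#' Inverse of [read_landmark_stream()]; the dialect is chosen from the file
#' extension. Round-trips losslessly up to numeric formatting (15
#' significant digits).
#'
#' @param stream a [camera_stream()].
#' @param path output path ending in `.jsonl` or `.csv`.
#' @return the path, invisibly.
#' @export
write_landmark_stream <- function(stream, path) {
  stopifnot(inherits(stream, "camera_stream"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(stream$frames, function(f) {
      data.frame(frame = f$frame_index, idx = seq_len(nrow(f$points)) - 1L,
                 x = f$points[, "x"], y = f$points[, "y"],
                 z = f$points[, "z"], visibility = f$points[, "visibility"])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    lines <- vapply(stream$frames, function(f) {
      jsonlite::toJSON(list(kind = f$kind, frame_index = f$frame_index,
                            timestamp = f$timestamp,
                            camera_label = f$camera_label,
                            points = as.data.frame(f$points)),
                       auto_unbox = TRUE, digits = NA, na = "null")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Synchronize camera streams by integer frame offsets
#'
#' Discards each stream's first `offsets[i]` frames and co-indexes the
#' remainder; the aligned length is the minimum remaining length.
#' Synchronization is by frame offset only -- streams with differing frame
#' rates are rejected rather than resampled.
#'
#' @param streams list of 1-3 [camera_stream()] objects.
#' @param offsets nonnegative integer per-stream frame offsets.
#' @return object of class `sync_session`: list with `streams` (trimmed),
#'   `aligned_length`.
#' @export
synchronize <- function(streams, offsets = rep(0L, length(streams))) {
  if (inherits(streams, "camera_stream")) streams <- list(streams)
  stopifnot(length(streams) >= 1L, length(streams) <= 3L,
            length(offsets) == length(streams),
            all(offsets >= 0), all(offsets == round(offsets)))
  fps <- vapply(streams, function(s) s$fps, numeric(1))
  if (length(unique(fps)) != 1L) {
    stop("streams have differing fps; resampling is not supported",
         call. = FALSE)
  }
  trimmed <- Map(function(s, off) {
    if (off >= length(s$frames)) {
      stop(sprintf("empty alignment: stream %s exhausted by offset %d",
                   s$camera_label, off), call. = FALSE)
    }
    s$frames <- s$frames[(off + 1):length(s$frames)]
    s
  }, streams, as.integer(offsets))
  n <- min(vapply(trimmed, function(s) length(s$frames), integer(1)))
  trimmed <- lapply(trimmed, function(s) { s$frames <- s$frames[1:n]; s })
  structure(list(streams = trimmed, aligned_length = n),
            class = "sync_session")
}

#' Write a per-frame REBA points table to CSV
#'
#' Columns `frame, camera, neck, trunk, leg, upper_arm, lower_arm, wrist`;
#' occlusion sentinels (0) are preserved verbatim. Round-trips losslessly
#' with [read_points_table()].
#'
#' @param points_series data frame in the same column layout (as produced
#'   by [grade_stream()] or [make_points_fixture()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_points_table <- function(points_series, path) {
  cols <- c("frame", "camera", "neck", "trunk", "leg", "upper_arm",
            "lower_arm", "wrist")
  df <- as.data.frame(points_series)
  if (nrow(df) == 0L) stop("empty points series", call. = FALSE)
  if (!all(cols %in% names(df))) {
    stop("points series must have columns ", paste(cols, collapse = ","),
         call. = FALSE)
  }
  ok <- tryCatch(
    suppressWarnings({
      utils::write.csv(df[, cols], path, row.names = FALSE)
      TRUE
    }),
    error = function(e) FALSE)
  if (!ok) stop("could not write points table to ", path, call. = FALSE)
  invisible(path)
}

#' Read a per-frame REBA points table from CSV
#'
#' @param path CSV written by [write_points_table()].
#' @return data frame with columns `frame, camera, neck, trunk, leg,
#'   upper_arm, lower_arm, wrist`.
#' @export
read_points_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("frame", "camera", "neck", "trunk", "leg", "upper_arm",
            "lower_arm", "wrist")
  if (!all(cols %in% names(df))) {
    stop("not a points table: missing columns", call. = FALSE)
  }
  df[, cols]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
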