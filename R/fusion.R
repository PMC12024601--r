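joint_cols <- c("neck", "trunk", "leg", "upper_arm", "lower_arm", "wrist")

#' Fuse one instant's REBA points across cameras
#'
#' Per joint, the maximum point across the supplied cameras. The occlusion
#' sentinel 0 loses to any positive value, so a joint is 0 in the fused
#' vector only if it is 0 in every camera. Fusion is commutative and
#' idempotent.
#'
#' @param per_camera_points list of 1-3 [reba_points()] vectors (or
#'   coercible length-6 numerics).
#' @return fused [reba_points()] vector.
#' @export
#' @examples
#' fuse_frame(list(c(3, 0, 0, 2, 2, 3), c(1, 1, 1, 1, 1, 1),
#'                 c(3, 3, 1, 3, 2, 3)))  # (3, 3, 1, 3, 2, 3)
fuse_frame <- function(per_camera_points) {
  if (inherits(per_camera_points, "reba_points")) {
    per_camera_points <- list(per_camera_points)
  }
  if (length(per_camera_points) < 1L) {
    stop("fuse_frame needs at least one camera's points", call. = FALSE)
  }
  pts <- lapply(per_camera_points, function(p) {
    if (!inherits(p, "reba_points")) {
      p <- do.call(reba_points, as.list(as.numeric(p)))
    }
    p
  })
  fused <- Reduce(pmax, lapply(pts, unclass))
  do.call(reba_points, as.list(fused))
}

#' Average a per-frame REBA point series into a single point vector
#'
#' Per joint: the arithmetic mean over frames including any 0 occlusion
#' sentinels, rounded to the nearest integer (halves away from zero), then
#' clamped to a minimum of 1 (a REBA grade of 0 cannot be assigned). This
#' zeros-included mean-round-clamp convention is the unique simple rule
#' that reproduces both bundled reference average rows, including a
#' fully-occluded joint clamping to 1.
#'
#' @param series data frame (or matrix) with one row per frame and the six
#'   joint columns `neck, trunk, leg, upper_arm, lower_arm, wrist`.
#' @return averaged [reba_points()] vector (all entries >= 1).
#' @export
aggregate_series <- function(series) {
  m <- as_points_matrix(series)
  if (nrow(m) < 1L) stop("series must have at least one frame", call. = FALSE)
  means <- colMeans(m)
  rounded <- round_half_away(means)
  if (any(rounded < 1)) {
    warning("joint(s) unobservable in every frame clamped to 1: ",
            paste(joint_cols[rounded < 1], collapse = ", "), call. = FALSE)
  }
  clamped <- pmax(rounded, 1)
  do.call(reba_points, as.list(clamped))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

as_points_matrix <- function(series) {
  if (is.matrix(series)) {
    m <- series
    if (ncol(m) != 6L) stop("expected six joint columns", call. = FALSE)
    colnames(m) <- joint_cols
  } else {
    df <- as.data.frame(series)
    if (!all(joint_cols %in% names(df))) {
      stop("series must have columns ", paste(joint_cols, collapse = ","),
           call. = FALSE)
    }
    m <- as.matrix(df[, joint_cols])
  }
  storage.mode(m) <- "double"
  m
}

#' Fraction of occluded joint cells in a points series
#'
#' The fraction of cells equal to the 0 sentinel across all frames and all
#' six joints.
#'
#' @param series data frame/matrix of per-frame REBA points (six joint
#'   columns).
#' @return fraction in `[0, 1]`.
#' @export
occlusion_rate <- function(series) {
  m <- as_points_matrix(series)
  if (nrow(m) < 1L) stop("series must have at least one frame", call. = FALSE)
  mean(m == 0)
}

#' Grade every frame of a synchronized session, per camera
#'
#' Runs joint-angle extraction and the REBA graders over each body stream
#' of the session. When a face stream is supplied, head pose is estimated
#' per frame and the resulting neck point is injected into the matching
#' camera's row (the face camera is the only one that measures the neck).
#'
#' @param session a `sync_session` of body streams from [synchronize()].
#' @param face_stream optional face [camera_stream()], already aligned with
#'   the session (same co-indexing).
#' @param flags a [posture_flags()] object.
#' @param visibility_threshold minimum landmark visibility.
#' @param intrinsics optional [camera_intrinsics()] for head-pose
#'   estimation; default derived from the face stream resolution.
#' @param neck_reference `"absolute"` or `"trunk_relative"`.
#' @return data frame with columns `frame, camera` and the six joints.
#' @export
grade_stream <- function(session, face_stream = NULL,
                         flags = posture_flags(),
                         visibility_threshold = 0.5,
                         intrinsics = NULL,
                         neck_reference = "absolute") {
  stopifnot(inherits(session, "sync_session"))
  n <- session$aligned_length

  neck_points <- rep(NA_integer_, n)
  face_label <- NULL
  if (!is.null(face_stream)) {
    stopifnot(inherits(face_stream, "camera_stream"),
              face_stream$kind == "face")
    face_label <- face_stream$camera_label
    if (is.null(intrinsics)) {
      intrinsics <- default_intrinsics(face_stream$resolution[1],
                                       face_stream$resolution[2])
    }
    fm <- face_model()
    n_face <- min(n, length(face_stream$frames))
    for (i in seq_len(n_face)) {
      f <- face_stream$frames[[i]]
      obs_norm <- f$points[fm$landmark_ids + 1L, c("x", "y")]
      visible <- all(f$points[fm$landmark_ids + 1L, "visibility"] >=
                       visibility_threshold)
      if (!visible) next
      obs <- cbind(obs_norm[, 1] * face_stream$resolution[1],
                   obs_norm[, 2] * face_stream$resolution[2])
      pose <- tryCatch(estimate_head_pose(obs, fm, intrinsics),
                       error = function(e) NULL)
      if (!is.null(pose)) {
        neck_points[i] <- grade_neck(pose$pitch, flags$neck_twist_or_side)
      }
    }
  }

  rows <- list()
  for (s in session$streams) {
    res <- s$resolution
    for (i in seq_len(n)) {
      ang <- extract_joint_angles(s$frames[[i]], head = NULL,
                                  visibility_threshold = visibility_threshold,
                                  resolution = res,
                                  neck_reference = neck_reference)
      p <- grade_joint_angles(ang, flags)
      if (!is.null(face_label) && s$camera_label == face_label &&
          !is.na(neck_points[i])) {
        p["neck"] <- neck_points[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = i - 1L, camera = s$camera_label,
        neck = p[["neck"]], trunk = p[["trunk"]], leg = p[["legs"]],
        upper_arm = p[["upper_arm"]], lower_arm = p[["lower_arm"]],
        wrist = p[["wrist"]])
    }
  }
  out <- do.call(rbind, rows)
  # if the face camera has no body stream, carry the neck as its own row set
  if (!is.null(face_label) && !face_label %in% out$camera &&
      any(!is.na(neck_points))) {
    extra <- data.frame(frame = seq_len(n) - 1L, camera = face_label,
                        neck = ifelse(is.na(neck_points), 0L, neck_points),
                        trunk = 0L, leg = 0L, upper_arm = 0L,
                        lower_arm = 0L, wrist = 0L)
    out <- rbind(out, extra)
  }
  out[order(out$frame, out$camera), ]
}

#' Assess a synchronized multi-camera session end to end
#'
#' Pipeline: per-frame grading per camera ([grade_stream()]), per-instant
#' cross-camera fusion ([fuse_frame()]), temporal averaging
#' ([aggregate_series()]), chart scoring ([reba_total()]) and risk banding.
#' Reports the per-camera and post-fusion occlusion rates.
#'
#' @inheritParams grade_stream
#' @param adj an [adjustments()] object.
#' @param window optional integer range `c(first, last)` of co-indexed
#'   frames (zero-based, inclusive) to average over; default all frames.
#' @return object of class `session_result`: list with `graded` (per
#'   camera per frame), `fused_series`, `averaged_points`, `breakdown`,
#'   `occlusion_single` (named per camera), `occlusion_fused`.
#' @export
assess_session <- function(session, face_stream = NULL,
                           flags = posture_flags(), adj = adjustments(),
                           visibility_threshold = 0.5, intrinsics = NULL,
                           neck_reference = "absolute", window = NULL) {
  graded <- grade_stream(session, face_stream, flags, visibility_threshold,
                         intrinsics, neck_reference)
  assess_points_table(graded, adj = adj, window = window)
}

#' Assess a pre-graded per-frame points table
#'
#' Same fusion/averaging/scoring chain as [assess_session()], starting from
#' an already-graded table (e.g. read with [read_points_table()]).
#'
#' @param graded data frame with columns `frame, camera` and the six joint
#'   columns; 0 marks occluded cells.
#' @param adj an [adjustments()] object.
#' @param window optional inclusive frame range `c(first, last)`.
#' @return a `session_result`, see [assess_session()].
#' @export
assess_points_table <- function(graded, adj = adjustments(), window = NULL) {
  stopifnot(all(c("frame", "camera", joint_cols) %in% names(graded)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    graded <- graded[graded$frame >= window[1] & graded$frame <= window[2], ]
    if (nrow(graded) == 0L) stop("window selects no frames", call. = FALSE)
  }
  frames <- sort(unique(graded$frame))
  fused <- do.call(rbind, lapply(frames, function(fr) {
    sub <- graded[graded$frame == fr, ]
    f <- fuse_frame(lapply(seq_len(nrow(sub)),
                           function(i) as.numeric(sub[i, joint_cols])))
    cbind(data.frame(frame = fr), as.data.frame(as.list(unclass(f)))[,
      c("neck", "trunk", "legs", "upper_arm", "lower_arm", "wrist")] |>
        stats::setNames(joint_cols))
  }))
  averaged <- aggregate_series(fused[, joint_cols])
  breakdown <- reba_total(averaged, adj)
  occ_single <- vapply(split(graded, graded$camera),
                       function(d) occlusion_rate(d[, joint_cols]),
                       numeric(1))
  structure(list(graded = graded, fused_series = fused,
                 averaged_points = averaged, breakdown = breakdown,
                 occlusion_single = occ_single,
                 occlusion_fused = occlusion_rate(fused[, joint_cols])),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d frames, %d cameras\n",
              length(unique(x$graded$frame)),
              length(unique(x$graded$camera))))
  cat("averaged points:", paste(names(x$averaged_points), x$averaged_points,
                                sep = "=", collapse = " "), "\n")
  cat(sprintf("REBA total %d (%s risk); occlusion single %s, fused %.3f\n",
              x$breakdown$total, x$breakdown$band,
              paste(sprintf("%s=%.3f", names(x$occlusion_single),
                            x$occlusion_single), collapse = " "),
              x$occlusion_fused))
  invisible(x)
}
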