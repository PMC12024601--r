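#' Interior angle at a vertex
#'
#' Angle at `b` in the triangle `a-b-c`, in degrees, always in `[0, 180]`.
#' Works for 2-D or 3-D points. Computed via `atan2(|cross|, dot)`, which is
#' numerically stable near 0 and 180 degrees.
#'
#' @param a,b,c numeric points of equal length (2 or 3).
#' @return angle in degrees.
#' @export
angle_at <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    stop("degenerate geometry: zero-length limb vector at the vertex",
         call. = FALSE)
  }
  if (length(u) == 2L) u <- c(u, 0)
  if (length(v) == 2L) v <- c(v, 0)
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

# angle of vector v (y-down image coords) away from image "up", degrees
angle_from_vertical <- function(v) {
  up <- c(0, -1)
  atan2(abs(v[1] * up[2] - v[2] * up[1]), sum(v * up)) * 180 / pi
}

# pixel coordinates of zero-based landmark id
lm_xy <- function(frame, id, resolution) {
  p <- frame$points[id + 1L, ]
  c(p[["x"]] * resolution[1], p[["y"]] * resolution[2])
}

lm_vis <- function(frame, ids) min(frame$points[ids + 1L, "visibility"])

#' Trunk flexion from a body landmark frame
#'
#' Unsigned angle between the mid-hip to mid-shoulder segment and the image
#' vertical; 0 is upright, larger values lean. Returns `NA` (joint missing)
#' when any of the hip or shoulder landmarks falls below the visibility
#' threshold.
#'
#' @param frame a body [landmark_frame()].
#' @param visibility_threshold minimum landmark visibility (default 0.5).
#' @param resolution pixel size `c(width, height)` used to de-normalize
#'   coordinates before angle computation.
#' @return trunk flexion in degrees, or `NA`.
#' @export
trunk_flexion <- function(frame, visibility_threshold = 0.5,
                          resolution = c(1920, 1080)) {
  stopifnot(inherits(frame, "landmark_frame"), frame$kind == "body")
  bl <- body_landmarks()
  need <- bl[c("hip_l", "hip_r", "shoulder_l", "shoulder_r")]
  if (lm_vis(frame, need) < visibility_threshold) return(NA_real_)
  mid_hip <- (lm_xy(frame, bl[["hip_l"]], resolution) +
                lm_xy(frame, bl[["hip_r"]], resolution)) / 2
  mid_sh <- (lm_xy(frame, bl[["shoulder_l"]], resolution) +
               lm_xy(frame, bl[["shoulder_r"]], resolution)) / 2
  angle_from_vertical(mid_sh - mid_hip)
}

#' Posture modifier flags
#'
#' The boolean REBA modifiers that a sparse landmark set cannot reliably
#' infer; they default to `FALSE` and are asserted per session (e.g. from a
#' config file) when the analyst observes them.
#'
#' @param neck_twist_or_side,trunk_twist_or_side,shoulder_raised,arm_abducted,arm_supported,wrist_deviated,unilateral_stance
#'   logical flags.
#' @export
posture_flags <- function(neck_twist_or_side = FALSE,
                          trunk_twist_or_side = FALSE,
                          shoulder_raised = FALSE,
                          arm_abducted = FALSE,
                          arm_supported = FALSE,
                          wrist_deviated = FALSE,
                          unilateral_stance = FALSE) {
  flags <- list(neck_twist_or_side = neck_twist_or_side,
                trunk_twist_or_side = trunk_twist_or_side,
                shoulder_raised = shoulder_raised,
                arm_abducted = arm_abducted,
                arm_supported = arm_supported,
                wrist_deviated = wrist_deviated,
                unilateral_stance = unilateral_stance)
  stopifnot(all(vapply(flags, is.logical, logical(1))))
  structure(flags, class = "posture_flags")
}

#' Extract joint angles from a body landmark frame
#'
#' Computes, per side where applicable:
#' * `trunk`: mid-hip to mid-shoulder line against the image vertical;
#' * `upper_arm`: shoulder-to-elbow segment against the trunk-down line
#'   (against the image vertical when the hips are unobservable);
#' * `lower_arm`: interior elbow angle (shoulder, elbow, wrist);
#' * `wrist`: 180 minus the interior wrist angle (elbow, wrist, index);
#' * `knee`: 180 minus the interior knee angle (hip, knee, ankle);
#' * `neck`: taken from the supplied head pose (pitch), `NA` when absent.
#'
#' Angles are computed in the 2-D image plane of the camera; each camera's
#' view is graded independently and occlusion is resolved downstream by
#' cross-camera fusion. A joint is marked missing (`NA`) when its indicator
#' landmarks fall below `visibility_threshold`: hips+shoulders for the
#' trunk, elbow for the upper arm, wrist for the lower arm, index finger
#' for the wrist, ankle for the knee. Indicator sets are disjoint across
#' joints so that occlusions affect joints independently.
#'
#' @param body a body [landmark_frame()].
#' @param head a `head_pose` from [estimate_head_pose()], or `NULL`.
#' @param visibility_threshold minimum visibility (default 0.5).
#' @param resolution pixel size `c(width, height)`.
#' @param neck_reference `"absolute"` (camera-frame pitch, default) or
#'   `"trunk_relative"`.
#' @return object of class `joint_angles`: list of per-joint angles in
#'   degrees (`NA` = missing), with `$sides` holding per-side values.
#' @export
extract_joint_angles <- function(body, head = NULL,
                                 visibility_threshold = 0.5,
                                 resolution = c(1920, 1080),
                                 neck_reference = "absolute") {
  stopifnot(inherits(body, "landmark_frame"), body$kind == "body")
  bl <- body_landmarks()
  thr <- visibility_threshold
  xy <- function(name) lm_xy(body, bl[[name]], resolution)
  vis <- function(names) lm_vis(body, bl[names]) >= thr

  trunk <- trunk_flexion(body, thr, resolution)

  trunk_down <- NULL
  if (!is.na(trunk)) {
    mid_hip <- (xy("hip_l") + xy("hip_r")) / 2
    mid_sh <- (xy("shoulder_l") + xy("shoulder_r")) / 2
    trunk_down <- mid_hip - mid_sh
  }

  side <- function(s) {
    sh <- xy(paste0("shoulder_", s)); el <- xy(paste0("elbow_", s))
    wr <- xy(paste0("wrist_", s)); ix <- xy(paste0("index_", s))
    hp <- xy(paste0("hip_", s)); kn <- xy(paste0("knee_", s))
    ak <- xy(paste0("ankle_", s))
    ua <- if (!vis(c(paste0("shoulder_", s), paste0("elbow_", s)))) NA_real_
    else {
      ref <- if (is.null(trunk_down)) c(0, 1) else trunk_down  # y-down: down
      v <- el - sh
      atan2(abs(v[1] * ref[2] - v[2] * ref[1]), sum(v * ref)) * 180 / pi
    }
    la <- if (!vis(paste0("wrist_", s))) NA_real_
    else angle_at(sh, el, wr)
    wrst <- if (!vis(paste0("index_", s))) NA_real_
    else 180 - angle_at(el, wr, ix)
    knee <- if (!vis(paste0("ankle_", s))) NA_real_
    else 180 - angle_at(hp, kn, ak)
    c(upper_arm = ua, lower_arm = la, wrist = wrst, knee = knee)
  }
  l <- side("l"); r <- side("r")

  neck <- if (is.null(head)) NA_real_
  else neck_angle(head, trunk_flexion = ifelse(is.na(trunk), 0, trunk),
                  reference = neck_reference)

  worse <- function(a, b) {
    if (is.na(a) && is.na(b)) NA_real_
    else max(a, b, na.rm = TRUE)
  }
  structure(list(
    neck = neck,
    trunk = trunk,
    upper_arm = worse(l[["upper_arm"]], r[["upper_arm"]]),
    lower_arm = worse_lower_arm(l[["lower_arm"]], r[["lower_arm"]]),
    wrist = worse(l[["wrist"]], r[["wrist"]]),
    knee = worse(l[["knee"]], r[["knee"]]),
    sides = list(l = l, r = r)
  ), class = "joint_angles")
}

# the lower-arm grade is best (1) in the 60-100 band; the conservative
# per-side choice is the side whose grade is worse, tie-broken by distance
# from the band center
worse_lower_arm <- function(a, b) {
  if (is.na(a) && is.na(b)) return(NA_real_)
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  ga <- grade_lower_arm(a); gb <- grade_lower_arm(b)
  if (ga != gb) return(if (ga > gb) a else b)
  if (abs(a - 80) >= abs(b - 80)) a else b
}

#' Grade extracted joint angles into REBA points
#'
#' Applies the per-joint graders to a [extract_joint_angles()] result,
#' taking the conservative (worse) side for per-side joints and rendering
#' missing joints as the 0 occlusion sentinel.
#'
#' @param angles a `joint_angles` object.
#' @param flags a [posture_flags()] object.
#' @return a [reba_points()] vector (0 = joint unobservable).
#' @export
grade_joint_angles <- function(angles, flags = posture_flags()) {
  stopifnot(inherits(angles, "joint_angles"), inherits(flags, "posture_flags"))
  reba_points(
    neck = grade_neck(angles$neck, flags$neck_twist_or_side),
    trunk = grade_trunk(angles$trunk, flags$trunk_twist_or_side),
    legs = grade_legs(angles$knee, flags$unilateral_stance),
    upper_arm = grade_upper_arm(angles$upper_arm, flags$shoulder_raised,
                                flags$arm_abducted, flags$arm_supported),
    lower_arm = grade_lower_arm(angles$lower_arm),
    wrist = grade_wrist(angles$wrist, flags$wrist_deviated)
  )
}
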