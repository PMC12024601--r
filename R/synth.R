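#' Specify a synthetic capture scene
#'
#' An articulated skeleton in a static work posture, observed by a ring of
#' three ideal pinhole cameras. Camera A (azimuth 0) faces the subject and
#' carries the face stream used for head-pose/neck estimation; cameras B
#' and C sit at +/-120 degrees, seeing the subject obliquely from the left
#' and right, 30 degrees away from a pure sagittal view. Cameras are
#' mounted at 1.2 m and aimed horizontally at the subject axis, far enough
#' away (default ring radius 6 m, tele focal) that projection is close to
#' weak-perspective.
#'
#' All prescribed angles are degrees. Per-side angles take a length-2
#' vector `(left, right)` or a scalar applied to both sides.
#'
#' @param trunk_lean forward trunk lean.
#' @param shoulder_flexion upper-arm flexion relative to the trunk line.
#' @param elbow_interior interior elbow angle (180 = straight arm).
#' @param wrist_deviation wrist bend away from the forearm line.
#' @param knee_flexion knee flexion (0 = straight leg).
#' @param head_pitch,head_yaw,head_roll head rotation (camera-A frame;
#'   pitch positive = forward flexion).
#' @param n_frames frames to render per camera.
#' @param occlusion_rate per-camera per-frame per-joint probability of
#'   occlusion.
#' @param noise_sigma Gaussian landmark noise, normalized image units.
#' @param seed integer seed; the whole render is seed-deterministic.
#' @param flags a [posture_flags()] object (also used for ground truth).
#' @param segment_lengths named list of segment lengths in meters
#'   (defaults: trunk 0.5, neck 0.12, upper_arm 0.3, forearm 0.28, hand
#'   0.18, thigh 0.45, shank 0.45, hip_width 0.3, shoulder_width 0.38,
#'   pelvis_height 0.9).
#' @param camera_azimuths ring azimuths in degrees (A, B, C).
#' @param camera_radius ring radius in meters.
#' @param camera_height camera mount height in meters.
#' @param resolution image size in pixels; focal defaults to the width.
#' @param fps nominal frame rate.
#' @param face_zoom focal multiplier of the face channel of camera A
#'   relative to the body channel (a face-directed camera is zoomed on the
#'   face); the matching intrinsics are returned by [render_views()].
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(trunk_lean = 30, shoulder_flexion = 30,
                       elbow_interior = 80, wrist_deviation = 5,
                       knee_flexion = 0, head_pitch = 10, head_yaw = 0,
                       head_roll = 0, n_frames = 1L, occlusion_rate = 0,
                       noise_sigma = 0, seed = 1L,
                       flags = posture_flags(),
                       segment_lengths = list(),
                       camera_azimuths = c(A = 0, B = 120, C = -120),
                       camera_radius = 6, camera_height = 1.2,
                       resolution = c(1920L, 1080L), fps = 30,
                       face_zoom = 4) {
  seg <- utils::modifyList(list(
    trunk = 0.5, neck = 0.12, upper_arm = 0.3, forearm = 0.28, hand = 0.18,
    thigh = 0.45, shank = 0.45, hip_width = 0.3, shoulder_width = 0.38,
    pelvis_height = 0.9), segment_lengths)
  if (any(unlist(seg) <= 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  both <- function(x) if (length(x) == 1L) c(l = x, r = x)
  else stats::setNames(as.numeric(x), c("l", "r"))
  stopifnot(occlusion_rate >= 0, occlusion_rate <= 1, noise_sigma >= 0,
            n_frames >= 1, length(camera_azimuths) == 3L, camera_radius > 0)
  structure(list(
    trunk_lean = trunk_lean,
    shoulder_flexion = both(shoulder_flexion),
    elbow_interior = both(elbow_interior),
    wrist_deviation = both(wrist_deviation),
    knee_flexion = both(knee_flexion),
    head = c(pitch = head_pitch, yaw = head_yaw, roll = head_roll),
    n_frames = as.integer(n_frames), occlusion_rate = occlusion_rate,
    noise_sigma = noise_sigma, seed = as.integer(seed), flags = flags,
    seg = seg, camera_azimuths = camera_azimuths,
    camera_radius = camera_radius, camera_height = camera_height,
    resolution = as.integer(resolution), fps = fps,
    face_zoom = face_zoom), class = "scene_spec")
}

# sagittal-plane direction, parameterized by angle from straight down,
# positive rotating forward (+z); world frame: x lateral, y up, z forward
sag_dir <- function(phi_deg) {
  a <- phi_deg * pi / 180
  c(0, -cos(a), sin(a))
}

#' Build the 3-D skeleton realizing a scene's prescribed angles
#'
#' Kinematic chain in world coordinates (x lateral, y up in meters, z
#' toward camera A): pelvis to trunk to neck/head; shoulders to elbows to
#' wrists to index fingers; hips to knees to ankles. Motion is in the
#' sagittal plane; left/right may carry different prescriptions.
#'
#' @param spec a [scene_spec()].
#' @return named list of 3-D joint coordinates (each a length-3 numeric).
#' @export
build_skeleton <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  seg <- spec$seg
  tau <- spec$trunk_lean
  mid_hip <- c(0, seg$pelvis_height, 0)
  trunk_up <- sag_dir(180 - tau)
  mid_shoulder <- mid_hip + seg$trunk * trunk_up
  head <- mid_shoulder + seg$neck * trunk_up
  out <- list(mid_hip = mid_hip, mid_shoulder = mid_shoulder, head = head)
  for (s in c("l", "r")) {
    lat <- if (s == "l") 1 else -1
    sh <- mid_shoulder + c(lat * seg$shoulder_width / 2, 0, 0)
    hp <- mid_hip + c(lat * seg$hip_width / 2, 0, 0)
    phi_arm <- -tau + spec$shoulder_flexion[[s]]
    el <- sh + seg$upper_arm * sag_dir(phi_arm)
    phi_fore <- phi_arm + 180 - spec$elbow_interior[[s]]
    wr <- el + seg$forearm * sag_dir(phi_fore)
    phi_hand <- phi_fore + spec$wrist_deviation[[s]]
    ix <- wr + seg$hand * sag_dir(phi_hand)
    kn <- hp + seg$thigh * sag_dir(0)
    ak <- kn + seg$shank * sag_dir(spec$knee_flexion[[s]])
    out[paste0(c("shoulder_", "hip_", "elbow_", "wrist_", "index_",
                 "knee_", "ankle_"), s)] <- list(sh, hp, el, wr, ix, kn, ak)
  }
  out
}

# camera pose on the ring; horizontal viewing axis, y_cam points down
ring_camera <- function(azimuth_deg, radius, height) {
  a <- azimuth_deg * pi / 180
  pos <- c(radius * sin(a), height, radius * cos(a))
  z <- c(0, height, 0) - pos
  z <- z / sqrt(sum(z^2))
  up <- c(0, 1, 0)
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  list(R = R, t = as.numeric(-R %*% pos), pos = pos)
}

# angle (degrees) between a world segment and a camera's image plane
segment_inclination <- function(p, q, cam) {
  d <- q - p
  d <- d / sqrt(sum(d^2))
  asin(min(1, abs(sum(d * cam$R[3, ])))) * 180 / pi
}

# ground-truth angles and REBA points implied by the prescriptions
scene_truth <- function(spec) {
  worse <- function(x) max(x)
  angles <- list(
    neck = unname(spec$head["pitch"]),
    trunk = spec$trunk_lean,
    upper_arm = worse(spec$shoulder_flexion),
    lower_arm = spec$elbow_interior[[
      which.max(vapply(c("l", "r"), function(s)
        grade_lower_arm(spec$elbow_interior[[s]]) * 1000 +
          abs(spec$elbow_interior[[s]] - 80), numeric(1)))]],
    wrist = worse(spec$wrist_deviation),
    knee = worse(spec$knee_flexion))
  fl <- spec$flags
  points <- reba_points(
    neck = grade_neck(angles$neck, fl$neck_twist_or_side),
    trunk = grade_trunk(angles$trunk, fl$trunk_twist_or_side),
    legs = grade_legs(angles$knee, fl$unilateral_stance),
    upper_arm = grade_upper_arm(angles$upper_arm, fl$shoulder_raised,
                                fl$arm_abducted, fl$arm_supported),
    lower_arm = max(grade_lower_arm(spec$elbow_interior[["l"]]),
                    grade_lower_arm(spec$elbow_interior[["r"]])),
    wrist = grade_wrist(angles$wrist, fl$wrist_deviated))
  list(angles = angles, points = points)
}

#' Render a scene to three synchronized camera streams
#'
#' Projects the skeleton through each ring camera into the 33-point body
#' schema (joint landmarks exact; unused landmarks filled by fixed offsets
#' with visibility 1) and renders a 478-point face stream for camera A with
#' the six head-pose landmarks exact. Occlusion is injected per camera,
#' frame and joint independently at `occlusion_rate` by zeroing the
#' visibility of the joint's indicator landmarks; Gaussian noise of
#' `noise_sigma` is added to normalized image coordinates. Landmarks whose
#' defining segment points mostly along a camera's viewing axis (more than
#' 45 degrees out of the image plane) get reduced visibility, emulating the
#' unreliability of heavily foreshortened limbs. Fully seed-deterministic.
#'
#' @param spec a [scene_spec()].
#' @return list with `session` (a `sync_session` of three body streams),
#'   `face_stream` (camera A), `truth` (ground-truth angles, REBA points
#'   and the injected occlusion masks), and `spec`.
#' @export
render_views <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  sk <- build_skeleton(spec)
  res <- spec$resolution
  intr <- default_intrinsics(res[1], res[2])
  cams <- lapply(spec$camera_azimuths, ring_camera,
                 radius = spec$camera_radius, height = spec$camera_height)
  labels <- c("A", "B", "C")
  joints <- c("neck", "trunk", "legs", "upper_arm", "lower_arm", "wrist")

  bl <- body_landmarks()
  # indicator landmarks zeroed when a joint is occluded (disjoint by joint)
  indicators <- list(
    trunk = bl[c("hip_l", "hip_r")],
    upper_arm = bl[c("elbow_l", "elbow_r")],
    lower_arm = bl[c("wrist_l", "wrist_r")],
    wrist = bl[c("index_l", "index_r")],
    legs = bl[c("ankle_l", "ankle_r")])
  # segments whose foreshortening makes a joint's angle unreliable
  seg_sets <- list(
    trunk = list(c("mid_hip", "mid_shoulder")),
    upper_arm = list(c("shoulder_l", "elbow_l"), c("shoulder_r", "elbow_r")),
    lower_arm = list(c("shoulder_l", "elbow_l"), c("elbow_l", "wrist_l"),
                     c("shoulder_r", "elbow_r"), c("elbow_r", "wrist_r")),
    wrist = list(c("elbow_l", "wrist_l"), c("wrist_l", "index_l"),
                 c("elbow_r", "wrist_r"), c("wrist_r", "index_r")),
    legs = list(c("hip_l", "knee_l"), c("knee_l", "ankle_l"),
                c("hip_r", "knee_r"), c("knee_r", "ankle_r")))

  # A segment pointing more than 35 degrees out of a camera's image plane
  # is depth-dominated there: its projected angle is unreliable, so the
  # affected joint's indicator landmarks get low visibility. The 35-degree
  # threshold keeps the +/-120-degree ring cameras (at most 30 degrees of
  # out-of-plane component for sagittal motion) always reliable while
  # gating the frontal camera whenever foreshortening could inflate a
  # grade.
  base_vis <- lapply(seq_along(cams), function(ci) {
    vis <- rep(1, 33)
    for (j in names(seg_sets)) {
      short <- any(vapply(seg_sets[[j]], function(pq)
        segment_inclination(sk[[pq[1]]], sk[[pq[2]]], cams[[ci]]) > 35,
        logical(1)))
      if (short) vis[indicators[[j]] + 1L] <- 0.2
    }
    vis
  })

  body_world <- body_world_points(sk)
  n <- spec$n_frames
  occ <- array(FALSE, dim = c(3, n, 6),
               dimnames = list(camera = labels, frame = NULL, joint = joints))
  if (spec$occlusion_rate > 0) {
    occ[] <- stats::runif(length(occ)) < spec$occlusion_rate
  }

  streams <- vector("list", 3)
  face_frames <- vector("list", n)
  fmodel <- face_model()
  head_R <- euler_to_matrix(spec$head["pitch"], spec$head["yaw"],
                            spec$head["roll"])
  head_cam_a <- as.numeric(cams[[1]]$R %*% sk$head + cams[[1]]$t)

  for (ci in 1:3) {
    uv <- project_points(body_world, cams[[ci]]$R, cams[[ci]]$t, intr)
    norm_xy <- cbind(uv[, 1] / res[1], uv[, 2] / res[2])
    depth <- as.numeric(body_world %*% cams[[ci]]$R[3, ] + cams[[ci]]$t[3])
    frames <- vector("list", n)
    for (fi in seq_len(n)) {
      xy <- norm_xy
      if (spec$noise_sigma > 0) {
        xy <- xy + matrix(stats::rnorm(length(xy), 0, spec$noise_sigma),
                          ncol = 2)
      }
      vis <- base_vis[[ci]]
      for (j in setdiff(joints, "neck")) {
        if (occ[ci, fi, j]) vis[indicators[[j]] + 1L] <- 0
      }
      pts <- data.frame(x = xy[, 1], y = xy[, 2],
                        z = depth - mean(depth), visibility = vis)
      frames[[fi]] <- landmark_frame("body", pts, fi - 1L,
                                     timestamp = (fi - 1) / spec$fps,
                                     camera_label = labels[ci])
    }
    streams[[ci]] <- camera_stream(frames, fps = spec$fps, resolution = res)
  }

  # the face camera is zoomed on the face (longer focal), as a dedicated
  # face-directed camera would be; the matching intrinsics are returned
  face_intr <- camera_intrinsics(spec$face_zoom * res[1],
                                 res[1] / 2, res[2] / 2)
  face_world <- sweep(0.2 * fmodel$model_points %*% t(head_R), 2,
                      head_cam_a, `+`)
  face_uv <- project_points(face_world, diag(3), c(0, 0, 0), face_intr)
  face_norm <- cbind(face_uv[, 1] / res[1], face_uv[, 2] / res[2])
  for (fi in seq_len(n)) {
    m <- matrix(NA_real_, 478, 2)
    ang <- seq(0, 2 * pi, length.out = 479)[1:478]
    m[, 1] <- face_norm[1, 1] + 0.02 * cos(ang)
    m[, 2] <- face_norm[1, 2] + 0.02 * sin(ang)
    m[fmodel$landmark_ids + 1L, ] <- face_norm
    if (spec$noise_sigma > 0) {
      idx <- fmodel$landmark_ids + 1L
      m[idx, ] <- m[idx, ] + matrix(stats::rnorm(12, 0, spec$noise_sigma),
                                    ncol = 2)
    }
    vis <- rep(1, 478)
    if (occ[1, fi, "neck"]) vis[fmodel$landmark_ids + 1L] <- 0
    face_frames[[fi]] <- landmark_frame(
      "face", data.frame(x = m[, 1], y = m[, 2], z = 0, visibility = vis),
      fi - 1L, timestamp = (fi - 1) / spec$fps, camera_label = "A")
  }

  list(session = synchronize(streams),
       face_stream = camera_stream(face_frames, fps = spec$fps,
                                   resolution = res),
       face_intrinsics = face_intr,
       truth = c(scene_truth(spec), list(occlusion = occ)),
       spec = spec)
}

# place all 33 landmarks in world coordinates; non-joint landmarks get
# fixed plausible offsets so schema validation passes without affecting
# the measured angles
body_world_points <- function(sk) {
  bl <- body_landmarks()
  pts <- matrix(NA_real_, 33, 3)
  for (nm in names(bl)) pts[bl[[nm]] + 1L, ] <- sk[[nm]]
  head <- sk$head
  # face-region landmarks 0-10 around the head
  face_off <- rbind(c(0, 0.03, 0.09), c(0.03, 0.05, 0.08),
                    c(0.04, 0.05, 0.08), c(0.05, 0.05, 0.07),
                    c(-0.03, 0.05, 0.08), c(-0.04, 0.05, 0.08),
                    c(-0.05, 0.05, 0.07), c(0.07, 0.04, 0.02),
                    c(-0.07, 0.04, 0.02), c(0.02, -0.01, 0.08),
                    c(-0.02, -0.01, 0.08))
  for (i in 0:10) pts[i + 1L, ] <- head + face_off[i + 1L, ]
  hand_off <- c(0, -0.02, 0.01)
  pts[17 + 1L, ] <- sk$wrist_l + hand_off   # pinky
  pts[18 + 1L, ] <- sk$wrist_r + hand_off
  pts[21 + 1L, ] <- sk$wrist_l + c(0.02, 0, 0.02)  # thumb
  pts[22 + 1L, ] <- sk$wrist_r + c(-0.02, 0, 0.02)
  pts[29 + 1L, ] <- sk$ankle_l + c(0, -0.03, -0.05)  # heel
  pts[30 + 1L, ] <- sk$ankle_r + c(0, -0.03, -0.05)
  pts[31 + 1L, ] <- sk$ankle_l + c(0, -0.03, 0.12)   # foot index
  pts[32 + 1L, ] <- sk$ankle_r + c(0, -0.03, 0.12)
  pts
}

#' Sample a random work posture with band-interior joint angles
#'
#' Draws a REBA grade per joint uniformly, then samples each prescribed
#' angle uniformly inside that grade's band, keeping a safety margin from
#' the band edges. The margins are sized to the worst-case angular
#' distortion of the ring geometry (oblique cameras compress sagittal
#' angles by up to ~4 degrees per segment at 30 degrees off-side, plus a
#' small perspective residual at the default 6 m radius), so that every
#' camera that measures a joint grades it like the prescription. This is
#' what makes noiseless end-to-end recovery exact rather than
#' probabilistic; real captures have no such guarantee, which is why the
#' noisy/occluded properties are tested separately.
#'
#' @param seed integer seed for the draw (also recorded in the returned
#'   scene specification).
#' @param ... passed on to [scene_spec()] (e.g. `n_frames`,
#'   `occlusion_rate`, `noise_sigma`).
#' @return a [scene_spec()].
#' @export
random_scene_spec <- function(seed = 1L, ...) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  in_band <- function(bands) {
    b <- bands[[sample.int(length(bands), 1)]]
    stats::runif(1, b[1], b[2])
  }
  two <- function(bands) c(in_band(bands), in_band(bands))
  trunk <- in_band(list(c(0, 0), c(7, 14), c(27, 50), c(66, 80)))
  spec <- scene_spec(
    trunk_lean = trunk,
    shoulder_flexion = two(list(c(0, 13), c(27, 38), c(53, 82), c(98, 118))),
    elbow_interior = two(list(c(72, 88), c(25, 48), c(112, 170))),
    wrist_deviation = two(list(c(0, 4), c(27, 45))),
    knee_flexion = two(list(c(0, 17), c(39, 51), c(72, 88))),
    head_pitch = in_band(list(c(2, 16), c(24, 42))),
    head_yaw = stats::runif(1, -10, 10),
    head_roll = stats::runif(1, -10, 10),
    seed = seed, ...)
  spec
}

#' Bundled reference point tables
#'
#' Small reference tables used throughout the tests and examples:
#' * `"fusion_instant"`: one instant graded by three cameras, with two
#'   joints occluded in camera C1 (per-frame fusion demo);
#' * `"frame_series"`: six frames of fused per-joint points (temporal
#'   averaging demo, no occlusion);
#' * `"occluded_series"`: six frames from a single camera with 10 occluded
#'   cells (zero handling demo);
#' * `"survey"`: per-joint points and observed REBA totals for 18 assessed
#'   dental practitioners (4 of them standing: subjects 13, 14, 16, 18);
#' * `"optimization"`: the response-surface optimization solutions
#'   (minimization and maximization) with chart verification scores.
#'
#' @param profile which table to build.
#' @return a data frame; point tables use the
#'   `frame, camera, neck, trunk, leg, upper_arm, lower_arm, wrist` layout.
#' @export
make_points_fixture <- function(profile = c("fusion_instant", "frame_series",
                                            "occluded_series", "survey",
                                            "optimization")) {
  profile <- match.arg(profile)
  switch(profile,
    fusion_instant = data.frame(
      frame = 0L, camera = c("C1", "C2", "C3"),
      neck = c(3, 1, 3), trunk = c(0, 1, 3), leg = c(0, 1, 1),
      upper_arm = c(2, 1, 3), lower_arm = c(2, 1, 2), wrist = c(3, 1, 3)),
    frame_series = data.frame(
      frame = 0:5, camera = "fused",
      neck = c(2, 2, 1, 2, 3, 3), trunk = c(2, 2, 2, 2, 2, 2),
      leg = c(1, 1, 1, 1, 1, 1), upper_arm = c(3, 5, 2, 4, 1, 3),
      lower_arm = c(2, 2, 2, 2, 2, 2), wrist = c(1, 2, 1, 1, 1, 2)),
    occluded_series = data.frame(
      frame = 0:5, camera = "single",
      neck = c(0, 0, 1, 2, 0, 3), trunk = c(2, 0, 2, 2, 2, 2),
      leg = c(1, 1, 1, 1, 1, 1), upper_arm = c(0, 5, 0, 3, 1, 3),
      lower_arm = c(2, 2, 0, 2, 2, 2), wrist = c(0, 2, 0, 0, 1, 1)),
    survey = data.frame(
      subject = 1:18,
      neck = c(2, 2, 3, 2, 2, 2, 2, 2, 2, 3, 3, 2, 3, 2, 2, 3, 2, 3),
      trunk = c(4, 3, 3, 5, 4, 3, 3, 4, 4, 3, 3, 3, 4, 3, 3, 4, 4, 3),
      leg = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 3, 2, 1, 3, 1, 2),
      upper_arm = c(4, 4, 5, 6, 4, 5, 4, 4, 4, 4, 4, 3, 5, 3, 4, 4, 4, 3),
      lower_arm = c(1, 1, 1, 1, 1, 2, 1, 1, 2, 1, 2, 2, 1, 2, 1, 1, 2, 1),
      wrist = rep(2, 18),
      reba = c(9, 8, 10, 12, 9, 10, 8, 9, 10, 9, 10, 8, 12, 9, 8, 12, 10,
               10),
      standing = 1:18 %in% c(13, 14, 16, 18)),
    optimization = data.frame(
      goal = c("maximization", "minimization"),
      N = c(2.98, 2), T = c(4.90, 3), U.A = c(4.05, 3), L.A = c(1.0, 1),
      response = c(11.11, 7.2), desirability = c(1.0, 0.95),
      verification_N = c(3, 2), verification_T = c(5, 3),
      verification_U.A = c(4, 3), verification_L.A = c(1, 1),
      verification_reba = c(11, 7)))
}
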