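#' Canonical six-point face template
#'
#' The head-pose estimator uses six stable face landmarks: nose tip, the
#' outer eye corners, the mouth corners, and the chin. In the 478-point face
#' schema these carry (zero-based) indices 1, 33, 263, 61, 291 and 199. The
#' template coordinates live in a unitless canonical head frame with x to
#' the subject's left on the image (right on screen), y downward, z away
#' from the camera at rest; the nose tip is the origin. Any rigid template
#' suffices for rotation recovery; this one is used consistently by the
#' estimator, the tests and the synthetic renderer.
#'
#' @return list with `landmark_ids` (zero-based indices into the face
#'   schema) and `model_points` (6x3 matrix).
#' @export
face_model <- function() {
  pts <- rbind(
    nose    = c( 0.000,  0.000, 0.000),
    eye_r   = c(-0.225, -0.170, 0.135),
    eye_l   = c( 0.225, -0.170, 0.135),
    mouth_r = c(-0.150,  0.150, 0.125),
    mouth_l = c( 0.150,  0.150, 0.125),
    chin    = c( 0.000,  0.330, 0.065)
  )
  list(landmark_ids = c(1L, 33L, 263L, 61L, 291L, 199L),
       model_points = pts)
}

#' Pinhole camera intrinsics
#'
#' @param focal focal length in pixels (must be positive).
#' @param cx,cy principal point in pixels.
#' @param distortion radial/tangential coefficients `(k1, k2, p1, p2, k3)`;
#'   shorter vectors are zero-padded. Default: no distortion.
#' @return object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal, cx, cy, distortion = numeric(5)) {
  stopifnot(is.numeric(focal), length(focal) == 1L, focal > 0,
            is.finite(cx), is.finite(cy))
  distortion <- c(as.numeric(distortion), numeric(5))[1:5]
  structure(list(focal = focal, cx = cx, cy = cy, distortion = distortion),
            class = "camera_intrinsics")
}

#' Default intrinsics for an uncalibrated camera
#'
#' The common head-pose heuristic: focal length equal to the image width,
#' principal point at the image center, zero distortion.
#'
#' @param width,height image size in pixels.
#' @export
default_intrinsics <- function(width, height) {
  camera_intrinsics(focal = width, cx = width / 2, cy = height / 2)
}

#' Project 3-D points through a pinhole camera
#'
#' Applies the rigid transform `X_cam = R X + t`, perspective division,
#' radial/tangential distortion, and the intrinsic mapping to pixel
#' coordinates. Points at or behind the camera plane are an error.
#'
#' @param points_3d n x 3 matrix of points in the object/world frame.
#' @param rotation 3x3 rotation matrix or length-3 axis-angle vector.
#' @param translation length-3 translation (camera frame).
#' @param intrinsics a [camera_intrinsics()] object.
#' @return n x 2 matrix of pixel coordinates (u, v), v increasing downward.
#' @export
project_points <- function(points_3d, rotation, translation, intrinsics) {
  pts <- as.matrix(points_3d)
  if (ncol(pts) != 3L || !all(is.finite(pts))) {
    stop("`points_3d` must be a finite n x 3 matrix", call. = FALSE)
  }
  R <- if (is.matrix(rotation)) rotation else rodrigues_to_matrix(rotation)
  check_rotation_matrix(R)
  cam <- pts %*% t(R) + matrix(translation, nrow(pts), 3, byrow = TRUE)
  if (any(cam[, 3] <= 1e-9)) {
    stop("point at or behind the camera plane (z <= 0)", call. = FALSE)
  }
  x <- cam[, 1] / cam[, 3]
  y <- cam[, 2] / cam[, 3]
  d <- intrinsics$distortion
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  cbind(u = intrinsics$focal * xd + intrinsics$cx,
        v = intrinsics$focal * yd + intrinsics$cy)
}

#' Estimate head pose from six observed face landmarks
#'
#' Perspective-n-point estimation: finds the rotation and translation that
#' minimize the reprojection error of the canonical face template onto the
#' observed image points. Initialization is a scaled-orthographic
#' (weak-perspective Procrustes) estimate; refinement is Gauss-Newton /
#' Levenberg-Marquardt on the six-parameter pose. The rotation is
#' decomposed into pitch/yaw/roll with [euler_from_matrix()]; pitch (about
#' the lateral axis, positive = forward flexion) feeds the neck grader.
#'
#' @param observed_2d 6 x 2 matrix of image points in pixels, same row
#'   order as `model$model_points`.
#' @param model face template, see [face_model()].
#' @param intrinsics a [camera_intrinsics()] object.
#' @param max_iter maximum refinement iterations.
#' @return object of class `head_pose`: list with `rotation_vector`,
#'   `rotation_matrix`, `translation`, `pitch`, `yaw`, `roll` (degrees) and
#'   `reprojection_rms` (pixels).
#' @export
estimate_head_pose <- function(observed_2d, model = face_model(),
                               intrinsics, max_iter = 100L) {
  obs <- as.matrix(observed_2d)
  if (nrow(obs) != 6L || ncol(obs) != 2L || !all(is.finite(obs))) {
    stop("`observed_2d` must be a finite 6 x 2 matrix", call. = FALSE)
  }
  mp <- model$model_points
  # degenerate geometry: observations (or template) collinear
  if (svd(scale(obs, scale = FALSE))$d[2] < 1e-8 * max(1, sd(obs))) {
    stop("degenerate geometry: observed points are collinear", call. = FALSE)
  }

  par0 <- weak_perspective_init(obs, mp, intrinsics)
  res_fun <- function(par) {
    R <- rodrigues_to_matrix(par[1:3])
    uv <- tryCatch(project_points(mp, R, par[4:6], intrinsics),
                   error = function(e) NULL)
    if (is.null(uv)) return(NULL)
    as.numeric(uv - obs)
  }
  fit <- lm_refine(par0, res_fun, max_iter = max_iter)
  if (!fit$converged) {
    stop(sprintf("head-pose refinement did not converge in %d iterations",
                 max_iter), call. = FALSE)
  }
  R <- rodrigues_to_matrix(fit$par[1:3])
  eul <- euler_from_matrix(R)
  structure(list(
    rotation_vector = fit$par[1:3],
    rotation_matrix = R,
    translation = fit$par[4:6],
    pitch = unname(eul["pitch"]),
    yaw = unname(eul["yaw"]),
    roll = unname(eul["roll"]),
    reprojection_rms = sqrt(mean(fit$residual^2)),
    iterations = fit$iterations
  ), class = "head_pose")
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf(
    "<head_pose> pitch %.2f deg, yaw %.2f deg, roll %.2f deg (RMS %.3g px)\n",
    x$pitch, x$yaw, x$roll, x$reprojection_rms))
  invisible(x)
}

#' Neck angle from a head pose
#'
#' In `"absolute"` mode (the default) the neck angle is the camera-frame
#' head pitch, which is what a face-only estimation chain measures. In
#' `"trunk_relative"` mode the trunk flexion is subtracted so that the
#' angle is measured against the trunk line (flexion positive).
#'
#' @param pose a `head_pose` object.
#' @param trunk_flexion trunk flexion in degrees (used only in
#'   `"trunk_relative"` mode).
#' @param reference `"absolute"` or `"trunk_relative"`.
#' @return neck angle in degrees.
#' @export
neck_angle <- function(pose, trunk_flexion = 0,
                       reference = c("absolute", "trunk_relative")) {
  reference <- match.arg(reference)
  stopifnot(inherits(pose, "head_pose"))
  if (reference == "absolute") pose$pitch else pose$pitch - trunk_flexion
}

# Scaled-orthographic (weak perspective) pose initialization:
# solve obs_centered ~ M %*% model_centered for a 2x3 matrix M, then
# orthogonalize the rows to get the first two rotation rows and a scale.
weak_perspective_init <- function(obs, mp, intrinsics) {
  xn <- (obs[, 1] - intrinsics$cx) / intrinsics$focal
  yn <- (obs[, 2] - intrinsics$cy) / intrinsics$focal
  oc <- cbind(xn - mean(xn), yn - mean(yn))
  mc <- scale(mp, scale = FALSE)
  M <- t(qr.solve(mc, oc))              # 2 x 3, least squares
  s1 <- sqrt(sum(M[1, ]^2)); s2 <- sqrt(sum(M[2, ]^2))
  s <- (s1 + s2) / 2
  if (s < 1e-12) stop("degenerate geometry in pose initialization",
                      call. = FALSE)
  r1 <- M[1, ] / s1
  r2 <- M[2, ] - sum(M[2, ] * r1) * r1
  r2 <- r2 / sqrt(sum(r2^2))
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R <- rbind(r1, r2, r3)
  # nearest rotation matrix via SVD
  sv <- svd(R)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  tz <- 1 / s
  t0 <- c(mean(xn) * tz - mean(mp %*% R[1, ]),
          mean(yn) * tz - mean(mp %*% R[2, ]),
          tz)
  if (t0[3] <= 0) t0[3] <- abs(t0[3]) + 1
  c(matrix_to_rodrigues(R), t0)
}

# Minimal Levenberg-Marquardt with numeric forward-difference Jacobian.
lm_refine <- function(par, res_fun, max_iter = 100L, tol = 1e-12) {
  r <- res_fun(par)
  if (is.null(r)) stop("invalid initial pose", call. = FALSE)
  cost <- sum(r^2)
  lambda <- 1e-3
  n <- length(par)
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), n)
    h <- pmax(1e-7, 1e-7 * abs(par))
    for (j in seq_len(n)) {
      pj <- par; pj[j] <- pj[j] + h[j]
      rj <- res_fun(pj)
      if (is.null(rj)) rj <- r
      J[, j] <- (rj - r) / h[j]
    }
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (k in 1:10) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        pnew <- par + as.numeric(step)
        rnew <- res_fun(pnew)
        if (!is.null(rnew) && sum(rnew^2) < cost) {
          par <- pnew; r <- rnew
          dcost <- cost - sum(rnew^2)
          cost <- sum(rnew^2)
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (dcost < tol * (1 + cost)) {
            return(list(par = par, residual = r, converged = TRUE,
                        iterations = it))
          }
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) {
      return(list(par = par, residual = r, converged = TRUE, iterations = it))
    }
  }
  list(par = par, residual = r, converged = cost < 1e6, iterations = max_iter)
}
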