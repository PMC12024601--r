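# Independent oracles used to cross-check the geometry code. These are
# deliberately implemented with different math than the package (quaternion
# algebra, homogeneous matrices, high-precision acos) so that agreement is
# evidence, not tautology.

# axis-angle -> unit quaternion
quat_from_axis_angle <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-300) return(c(1, 0, 0, 0))
  c(cos(theta / 2), sin(theta / 2) * rvec / theta)
}

quat_mul <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

# rotate a vector by a unit quaternion: v' = q v q*
quat_rotate <- function(q, v) {
  qv <- c(0, v)
  qc <- c(q[1], -q[2:4])
  quat_mul(quat_mul(q, qv), qc)[2:4]
}

# columns of R are the rotated basis vectors
rotation_matrix_from_quat <- function(q) {
  sapply(1:3, function(i) quat_rotate(q, diag(3)[, i]))
}

# oracle rotation matrix for an axis-angle vector via quaternions
oracle_rodrigues <- function(rvec) {
  rotation_matrix_from_quat(quat_from_axis_angle(rvec))
}

# pinhole projection as explicit homogeneous matrix arithmetic
oracle_project <- function(points_3d, R, tvec, focal, cx, cy) {
  K <- matrix(c(focal, 0, 0, 0, focal, 0, cx, cy, 1), 3, 3)
  P <- K %*% cbind(R, tvec)
  h <- P %*% rbind(t(points_3d), 1)
  cbind(h[1, ] / h[3, ], h[2, ] / h[3, ])
}

# high-precision interior angle via the numerically careful 2*atan2 form
oracle_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  2 * atan2(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2))) * 180 / pi
}

# small uniform body frame for IO/extraction tests
flat_body_frame <- function(frame_index = 0L, camera_label = "A",
                            visibility = 1) {
  landmark_frame("body",
                 data.frame(x = rep(0.5, 33), y = rep(0.5, 33), z = 0,
                            visibility = visibility),
                 frame_index, camera_label = camera_label)
}

simple_stream <- function(n, camera_label = "A", fps = 30) {
  camera_stream(lapply(seq_len(n) - 1L, flat_body_frame,
                       camera_label = camera_label), fps = fps)
}

joint_cols <- c("neck", "trunk", "leg", "upper_arm", "lower_arm", "wrist")

points_of <- function(row) as.numeric(row[joint_cols])
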