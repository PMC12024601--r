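#' @title REBA worksheet lookup tables
#' @description The three lookup tables of the standard REBA employee
#'   assessment worksheet, embedded as constants. Table A combines neck,
#'   trunk and leg points (1-9); Table B combines upper-arm, lower-arm and
#'   wrist points (1-9); Table C combines Score A and Score B (1-12). All
#'   three are monotone nondecreasing in every argument.
#' @name reba-tables
NULL

# Table A: dims neck (1-3) x trunk (1-5) x legs (1-4)
.reba_table_a <- local({
  a <- array(NA_integer_, dim = c(3, 5, 4),
             dimnames = list(neck = 1:3, trunk = 1:5, legs = 1:4))
  a[1, , ] <- rbind(c(1, 2, 3, 4),
                    c(2, 3, 4, 5),
                    c(2, 4, 5, 6),
                    c(3, 5, 6, 7),
                    c(4, 6, 7, 8))
  a[2, , ] <- rbind(c(1, 2, 3, 4),
                    c(3, 4, 5, 6),
                    c(4, 5, 6, 7),
                    c(5, 6, 7, 8),
                    c(6, 7, 8, 9))
  a[3, , ] <- rbind(c(3, 3, 5, 6),
                    c(4, 5, 6, 7),
                    c(5, 6, 7, 8),
                    c(6, 7, 8, 9),
                    c(7, 8, 9, 9))
  storage.mode(a) <- "integer"
  a
})

# Table B: dims upper_arm (1-6) x lower_arm (1-2) x wrist (1-3)
.reba_table_b <- local({
  b <- array(NA_integer_, dim = c(6, 2, 3),
             dimnames = list(upper_arm = 1:6, lower_arm = 1:2, wrist = 1:3))
  b[, 1, ] <- rbind(c(1, 2, 2),
                    c(1, 2, 3),
                    c(3, 4, 5),
                    c(4, 5, 5),
                    c(6, 7, 8),
                    c(7, 8, 8))
  b[, 2, ] <- rbind(c(1, 2, 3),
                    c(2, 3, 4),
                    c(4, 5, 5),
                    c(5, 6, 7),
                    c(8, 8, 8),
                    c(8, 9, 9))
  storage.mode(b) <- "integer"
  b
})

# Table C: Score A (1-12) x Score B (1-12)
.reba_table_c <- local({
  m <- rbind(
    c(1, 1, 1, 2, 3, 3, 4, 5, 6, 7, 7, 7),
    c(1, 2, 2, 3, 4, 4, 5, 6, 6, 7, 7, 8),
    c(2, 3, 3, 3, 4, 5, 6, 7, 7, 8, 8, 8),
    c(3, 4, 4, 4, 5, 6, 7, 8, 8, 9, 9, 9),
    c(4, 4, 4, 5, 6, 7, 8, 8, 9, 9, 9, 9),
    c(6, 6, 6, 7, 8, 8, 9, 9, 10, 10, 10, 10),
    c(7, 7, 7, 8, 9, 9, 9, 10, 10, 11, 11, 11),
    c(8, 8, 8, 9, 10, 10, 10, 10, 10, 11, 11, 11),
    c(9, 9, 9, 10, 10, 10, 11, 11, 11, 12, 12, 12),
    c(10, 10, 10, 11, 11, 11, 11, 12, 12, 12, 12, 12),
    c(11, 11, 11, 11, 12, 12, 12, 12, 12, 12, 12, 12),
    c(12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12))
  dimnames(m) <- list(score_a = 1:12, score_b = 1:12)
  storage.mode(m) <- "integer"
  m
})

check_point <- function(x, lo, hi, what) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < lo || x > hi) {
    stop(sprintf("%s point must be an integer in [%d, %d], got %s",
                 what, lo, hi, format(x)), call. = FALSE)
  }
  as.integer(x)
}

#' REBA Table A lookup (neck, trunk, legs)
#'
#' @param neck neck point, 1-3.
#' @param trunk trunk point, 1-5.
#' @param legs leg point, 1-4.
#' @return integer posture score 1-9.
#' @export
table_a <- function(neck, trunk, legs) {
  .reba_table_a[check_point(neck, 1, 3, "neck"),
                check_point(trunk, 1, 5, "trunk"),
                check_point(legs, 1, 4, "legs")]
}

#' REBA Table B lookup (upper arm, lower arm, wrist)
#'
#' @param upper_arm upper-arm point, 1-6.
#' @param lower_arm lower-arm point, 1-2.
#' @param wrist wrist point, 1-3.
#' @return integer posture score 1-9.
#' @export
table_b <- function(upper_arm, lower_arm, wrist) {
  .reba_table_b[check_point(upper_arm, 1, 6, "upper_arm"),
                check_point(lower_arm, 1, 2, "lower_arm"),
                check_point(wrist, 1, 3, "wrist")]
}

#' REBA Table C lookup (Score A, Score B)
#'
#' @param score_a Score A, 1-12.
#' @param score_b Score B, 1-12.
#' @return integer score 1-12.
#' @export
table_c <- function(score_a, score_b) {
  .reba_table_c[check_point(score_a, 1, 12, "score_a"),
                check_point(score_b, 1, 12, "score_b")]
}

#' Construct a per-joint REBA point vector
#'
#' Bundles the six per-joint REBA points. A value of 0 is the occlusion
#' sentinel: it marks a joint that could not be observed and is never a
#' valid grade -- it must be removed by camera fusion or by the
#' average-then-clamp rule before the chart is applied.
#'
#' @param neck 0-3. @param trunk 0-5. @param legs 0-4.
#' @param upper_arm 0-6. @param lower_arm 0-2. @param wrist 0-3.
#' @return named integer vector of class `reba_points`.
#' @export
reba_points <- function(neck, trunk, legs, upper_arm, lower_arm, wrist) {
  p <- c(neck = check_point(neck, 0, 3, "neck"),
         trunk = check_point(trunk, 0, 5, "trunk"),
         legs = check_point(legs, 0, 4, "legs"),
         upper_arm = check_point(upper_arm, 0, 6, "upper_arm"),
         lower_arm = check_point(lower_arm, 0, 2, "lower_arm"),
         wrist = check_point(wrist, 0, 3, "wrist"))
  structure(p, class = "reba_points")
}

#' Load, coupling and activity adjustments
#'
#' Additive REBA modifiers: load/force is added to Table A's result to give
#' Score A, coupling to Table B's result to give Score B, and activity to
#' Table C's result to give the final score. The package default is
#' `(1, 1, 1)`, the calibration that reproduces the bundled survey totals;
#' pass other values per session when load, grip or activity differ.
#'
#' @param load 0-3. @param coupling 0-3. @param activity 0-3.
#' @export
adjustments <- function(load = 1L, coupling = 1L, activity = 1L) {
  structure(list(load = check_point(load, 0, 3, "load"),
                 coupling = check_point(coupling, 0, 3, "coupling"),
                 activity = check_point(activity, 0, 3, "activity")),
            class = "reba_adjustments")
}

#' Grade the neck angle
#'
#' 0-20 degrees of flexion scores 1; more than 20 degrees of flexion or any
#' extension (negative angle) scores 2; twisting or side-bending adds 1,
#' capped at 3.
#'
#' @param angle neck angle in degrees; negative values are extension;
#'   `NA` marks an unobservable joint and yields the 0 sentinel.
#' @param twist_or_side logical posture modifier.
#' @return integer point 0-3.
#' @export
grade_neck <- function(angle, twist_or_side = FALSE) {
  if (is.na(angle)) return(0L)
  base <- if (angle >= 0 && angle <= 20) 1L else 2L
  min(base + as.integer(twist_or_side), 3L)
}

#' Grade the trunk angle
#'
#' Upright (within `upright_tol` of vertical) scores 1; up to 20 degrees of
#' flexion or extension scores 2; 20-60 degrees of flexion or more than 20
#' degrees of extension scores 3; over 60 degrees of flexion scores 4;
#' twist/side-bend adds 1, capped at 5.
#'
#' @param angle trunk flexion in degrees (negative = extension), `NA` for
#'   unobservable.
#' @param twist_or_side logical modifier.
#' @param upright_tol tolerance (degrees) within which the trunk counts as
#'   upright; video-derived angles are never exactly zero.
#' @return integer point 0-5.
#' @export
grade_trunk <- function(angle, twist_or_side = FALSE, upright_tol = 2) {
  if (is.na(angle)) return(0L)
  base <- if (abs(angle) <= upright_tol) 1L
          else if (abs(angle) <= 20) 2L
          else if (angle > 60) 4L
          else 3L  # 20-60 flexion, or extension beyond 20
  min(base + as.integer(twist_or_side), 5L)
}

#' Grade the legs
#'
#' Bilateral weight bearing scores 1, unilateral/unstable 2; knee flexion
#' of 30-60 degrees adds 1 and beyond 60 degrees adds 2, capped at 4.
#'
#' @param knee_flexion knee flexion in degrees, `NA` for unobservable.
#' @param unilateral logical: one-legged or unstable stance.
#' @return integer point 0-4.
#' @export
grade_legs <- function(knee_flexion, unilateral = FALSE) {
  if (is.na(knee_flexion)) return(0L)
  base <- if (unilateral) 2L else 1L
  add <- if (knee_flexion > 60) 2L else if (knee_flexion >= 30) 1L else 0L
  min(base + add, 4L)
}

#' Grade the upper arm
#'
#' Within -20 to 20 degrees scores 1; 20-45 degrees of flexion or extension
#' beyond 20 degrees scores 2; 45-90 degrees scores 3; beyond 90 degrees
#' scores 4. Shoulder raised and arm abducted each add 1; arm supported
#' subtracts 1. Result clamped to 1-6.
#'
#' @param angle upper-arm flexion in degrees relative to the trunk line
#'   (negative = extension), `NA` for unobservable.
#' @param raised,abducted,supported logical modifiers.
#' @return integer point 0-6.
#' @export
grade_upper_arm <- function(angle, raised = FALSE, abducted = FALSE,
                            supported = FALSE) {
  if (is.na(angle)) return(0L)
  base <- if (angle >= -20 && angle <= 20) 1L
          else if (angle > 90) 4L
          else if (angle > 45) 3L
          else 2L  # 20-45 flexion, or extension beyond 20
  p <- base + as.integer(raised) + as.integer(abducted) -
    as.integer(supported)
  max(1L, min(p, 6L))
}

#' Grade the lower arm
#'
#' Elbow flexion of 60-100 degrees scores 1; anything else scores 2.
#'
#' @param angle interior elbow angle in degrees, `NA` for unobservable.
#' @return integer point 0-2.
#' @export
grade_lower_arm <- function(angle) {
  if (is.na(angle)) return(0L)
  if (angle >= 60 && angle <= 100) 1L else 2L
}

#' Grade the wrist
#'
#' Within 15 degrees of neutral scores 1, beyond scores 2; deviation or
#' twist adds 1, capped at 3.
#'
#' @param angle wrist flexion/extension in degrees, `NA` for unobservable.
#' @param deviated logical modifier.
#' @return integer point 0-3.
#' @export
grade_wrist <- function(angle, deviated = FALSE) {
  if (is.na(angle)) return(0L)
  base <- if (abs(angle) <= 15) 1L else 2L
  min(base + as.integer(deviated), 3L)
}

#' Assemble the full REBA score from per-joint points
#'
#' Score A = Table A(neck, trunk, legs) + load; Score B = Table B(upper
#' arm, lower arm, wrist) + coupling; both clamped to 12. The total is
#' Table C(Score A, Score B) + activity, clamped to 15, and is classified
#' into a risk band with [classify_risk()].
#'
#' All six points must be valid grades (>= 1): the 0 occlusion sentinel
#' must have been removed by fusion or clamping beforehand.
#'
#' @param points a [reba_points()] vector (or coercible named/positional
#'   numeric of length 6).
#' @param adj an [adjustments()] object.
#' @return object of class `reba_score`: list with `points`, `score_a`,
#'   `score_b`, `score_c`, `total`, `band` and the adjustments used.
#' @export
#' @examples
#' reba_total(reba_points(2, 3, 1, 4, 1, 2))  # total 8, high risk
reba_total <- function(points, adj = adjustments()) {
  if (!inherits(points, "reba_points")) {
    points <- do.call(reba_points, as.list(as.numeric(points)))
  }
  if (any(points == 0L)) {
    stop(paste0("occlusion sentinel (0) present in joints: ",
                paste(names(points)[points == 0L], collapse = ", "),
                "; fuse cameras or clamp before scoring"), call. = FALSE)
  }
  stopifnot(inherits(adj, "reba_adjustments"))
  sa <- min(table_a(points[["neck"]], points[["trunk"]], points[["legs"]]) +
              adj$load, 12L)
  sb <- min(table_b(points[["upper_arm"]], points[["lower_arm"]],
                    points[["wrist"]]) + adj$coupling, 12L)
  sc <- table_c(sa, sb)
  total <- min(sc + adj$activity, 15L)
  structure(list(points = points, score_a = sa, score_b = sb, score_c = sc,
                 total = total, band = classify_risk(total), adjustments = adj),
            class = "reba_score")
}

#' @export
print.reba_score <- function(x, ...) {
  cat(sprintf("<reba_score> A=%d B=%d C=%d total=%d (%s risk)\n",
              x$score_a, x$score_b, x$score_c, x$total, x$band))
  cat("points:", paste(names(x$points), x$points, sep = "=",
                       collapse = " "), "\n")
  invisible(x)
}

#' Classify a REBA total into a risk band
#'
#' 1 is negligible; 2-3 low; 4-7 medium; 8-10 high; 11-15 very high.
#'
#' @param total REBA total in 1-15.
#' @return factor level among `negligible`, `low`, `medium`, `high`,
#'   `very_high`.
#' @export
classify_risk <- function(total) {
  total <- check_point(total, 1, 15, "total")
  if (total == 1) "negligible"
  else if (total <= 3) "low"
  else if (total <= 7) "medium"
  else if (total <= 10) "high"
  else "very_high"
}
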