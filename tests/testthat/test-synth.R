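test_that("skeleton realizes prescribed angles exactly", {
  # neutral standing pose
  sk0 <- build_skeleton(scene_spec(trunk_lean = 0, shoulder_flexion = 0,
                                   elbow_interior = 180,
                                   wrist_deviation = 0, knee_flexion = 0))
  trunk_vec <- sk0$mid_shoulder - sk0$mid_hip
  expect_equal(trunk_vec[1], 0)
  expect_equal(atan2(abs(trunk_vec[3]), trunk_vec[2]) * 180 / pi, 0,
               tolerance = 1e-9)

  # forward kinematics vs the interior-angle oracle
  sk <- build_skeleton(scene_spec(elbow_interior = 90))
  expect_equal(oracle_angle(sk$shoulder_l, sk$elbow_l, sk$wrist_l), 90,
               tolerance = 1e-9)
  sk2 <- build_skeleton(scene_spec(knee_flexion = 40, wrist_deviation = 20))
  expect_equal(180 - oracle_angle(sk2$hip_r, sk2$knee_r, sk2$ankle_r), 40,
               tolerance = 1e-9)
  expect_equal(180 - oracle_angle(sk2$elbow_l, sk2$wrist_l, sk2$index_l),
               20, tolerance = 1e-9)

  # mirrored prescriptions give mirror-symmetric coordinates
  a <- build_skeleton(scene_spec(shoulder_flexion = c(20, 70),
                                 elbow_interior = c(80, 120)))
  b <- build_skeleton(scene_spec(shoulder_flexion = c(70, 20),
                                 elbow_interior = c(120, 80)))
  expect_equal(a$wrist_l * c(-1, 1, 1), b$wrist_r, tolerance = 1e-12)

  expect_error(scene_spec(segment_lengths = list(trunk = 0)), "positive")
})

test_that("rendering is bit-identical for identical seeds", {
  sc <- scene_spec(n_frames = 3, occlusion_rate = 0.2, noise_sigma = 0.002,
                   seed = 123)
  r1 <- render_views(sc)
  r2 <- render_views(sc)
  expect_identical(r1$session, r2$session)
  expect_identical(r1$face_stream, r2$face_stream)
  expect_identical(r1$truth, r2$truth)

  r3 <- render_views(scene_spec(n_frames = 3, occlusion_rate = 0.2,
                                noise_sigma = 0.002, seed = 124))
  expect_false(identical(r1$session, r3$session))
})

test_that("noiseless sessions recover ground-truth points exactly", {
  # 50 random band-interior scenes, no noise, no occlusion: the fused and
  # averaged points must equal the prescription-implied points exactly
  for (s in 1:50) {
    sc <- random_scene_spec(seed = s, n_frames = 2)
    rv <- render_views(sc)
    res <- suppressWarnings(
      assess_session(rv$session, rv$face_stream,
                     intrinsics = rv$face_intrinsics))
    expect_identical(unclass(res$averaged_points),
                     unclass(rv$truth$points),
                     label = sprintf("seed %d", s))
  }
})

test_that("independent per-camera occlusion multiplies out under fusion", {
  # joints observable by all three cameras (trunk, legs in the default
  # posture) are occluded per camera at ~0.3 and post-fusion at ~0.3^3
  sc <- scene_spec(n_frames = 1200, occlusion_rate = 0.3, seed = 99)
  rv <- render_views(sc)
  res <- suppressWarnings(
    assess_session(rv$session, rv$face_stream,
                   intrinsics = rv$face_intrinsics))
  for (j in c("trunk", "leg")) {
    singles <- vapply(split(res$graded, res$graded$camera),
                      function(d) mean(d[[j]] == 0), numeric(1))
    fusedr <- mean(res$fused_series[[j]] == 0)
    # binomial 4-sigma tolerances at n = 1200
    expect_true(all(abs(singles - 0.3) < 4 * sqrt(0.3 * 0.7 / 1200)))
    expect_lt(abs(fusedr - 0.027), 4 * sqrt(0.027 * 0.973 / 1200))
    expect_true(all(fusedr <= singles))
  }
  # the injected masks agree with what the pipeline measured
  m <- rv$truth$occlusion
  expect_equal(mean(m[1, , "trunk"] & m[2, , "trunk"] & m[3, , "trunk"]),
               mean(res$fused_series$trunk == 0))
})

test_that("noisy occluded sessions stay within one REBA point of truth", {
  diffs <- vapply(1:20, function(s) {
    sc <- random_scene_spec(seed = 1000 + s, n_frames = 30,
                            occlusion_rate = 0.3, noise_sigma = 0.002)
    rv <- render_views(sc)
    res <- suppressWarnings(
      assess_session(rv$session, rv$face_stream,
                     intrinsics = rv$face_intrinsics))
    res$breakdown$total - reba_total(rv$truth$points)$total
  }, numeric(1))
  expect_gte(mean(abs(diffs) <= 1), 0.9)
})

test_that("rendered schema is exact: 33 body and 478 face landmarks", {
  rv <- render_views(scene_spec(n_frames = 1, seed = 1))
  for (st in rv$session$streams) {
    expect_equal(nrow(st$frames[[1]]$points), 33L)
  }
  expect_equal(nrow(rv$face_stream$frames[[1]]$points), 478L)
  # the six pose landmarks carry the projected template exactly
  fm <- face_model()
  expect_true(all(is.finite(
    rv$face_stream$frames[[1]]$points[fm$landmark_ids + 1L, c("x", "y")])))
})

test_that("reference fixtures have the documented shapes and contents", {
  fi <- make_points_fixture("fusion_instant")
  expect_equal(nrow(fi), 3L)
  expect_equal(sum(fi[joint_cols] == 0), 2L)

  oc <- make_points_fixture("occluded_series")
  expect_equal(dim(oc[joint_cols]), c(6L, 6L))
  expect_equal(sum(oc[joint_cols] == 0), 10L)

  sv <- make_points_fixture("survey")
  expect_equal(nrow(sv), 18L)
  expect_equal(sum(sv$standing), 4L)
  expect_true(all(sv$wrist == 2))
  expect_true(all(sv[!sv$standing, "leg"] == 1))

  opt <- make_points_fixture("optimization")
  expect_equal(opt$verification_reba, c(11, 7))
})
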