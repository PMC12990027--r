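test_that("interpolate_pose endpoints are exact and t is validated", {
  set.seed(31)
  a <- random_transform()
  b <- random_transform()
  expect_identical(interpolate_pose(a, b, 0), a)
  expect_identical(interpolate_pose(a, b, 1), b)
  expect_error(interpolate_pose(a, b, -0.01), "\\[0, 1\\]")
  expect_error(interpolate_pose(a, b, 1.01), "\\[0, 1\\]")
})

test_that("SLERP midpoint matches the closed-form half-angle rotation", {
  a <- identity_transform()
  b <- rigid_transform(c(cos(pi / 4), 0, 0, sin(pi / 4)))  # 90 deg about z
  mid <- interpolate_pose(a, b, 0.5)
  expect_equal(mid$q, c(cos(pi / 8), 0, 0, sin(pi / 8)), tolerance = 1e-12)
  expect_equal(rotation_angle(mid), pi / 4, tolerance = 1e-12)
  expect_equal(mid$t, c(0, 0, 0))
})

test_that("SLERP from identity equals the axis-angle scaling oracle", {
  set.seed(32)
  for (i in 1:10) {
    b <- random_transform(max_trans = 0)
    ang <- rotation_angle(b)
    ax <- rotation_axis(b)
    for (t in c(0.2, 0.5, 0.9)) {
      got <- interpolate_pose(identity_transform(), b, t)
      want <- rigid_transform(c(cos(t * ang / 2), sin(t * ang / 2) * ax))
      expect_lt(rot_error(got, want), 1e-9)
    }
  }
})

test_that("pure translation interpolates linearly with zero rotation", {
  a <- identity_transform()
  b <- rigid_transform(c(1, 0, 0, 0), c(4, 0, 0))
  got <- interpolate_pose(a, b, 0.25)
  expect_equal(got$t, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(rotation_angle(got), 0)
})

test_that("interpolate_segment emits n strictly intermediate poses", {
  a <- identity_transform()
  ang <- 10 * pi / 180
  b <- rigid_transform(c(cos(ang / 2), 0, 0, sin(ang / 2)), c(0, 8, -2))
  seg <- interpolate_segment(a, b, 100)
  expect_length(seg, 100)
  expect_error(interpolate_segment(a, b, 0), ">= 1")
  one <- interpolate_segment(a, b, 1)
  expect_equal(one[[1]]$q, interpolate_pose(a, b, 0.5)$q, tolerance = 1e-15)
  expect_equal(one[[1]]$t, interpolate_pose(a, b, 0.5)$t, tolerance = 1e-15)
})

test_that("angular speed is uniform within a segment", {
  set.seed(33)
  a <- random_transform()
  b <- random_transform()
  frames <- c(list(a), interpolate_segment(a, b, 50), list(b))
  steps <- vapply(seq_len(length(frames) - 1), function(i) {
    rot_error(frames[[i + 1]], frames[[i]])
  }, numeric(1))
  expect_lt(max(steps) - min(steps), 1e-9)
})

test_that("reversal symmetry: b->a at t equals a->b at 1 - t", {
  set.seed(34)
  for (i in 1:10) {
    a <- random_transform()
    b <- random_transform()
    for (t in c(0.1, 0.3, 0.7)) {
      fwd <- interpolate_pose(a, b, 1 - t)
      rev <- interpolate_pose(b, a, t)
      expect_equal(quat_canonical(rev$q), quat_canonical(fwd$q),
                   tolerance = 1e-9)
      expect_equal(rev$t, fwd$t, tolerance = 1e-9)
    }
  }
})

test_that("build_trajectory matches the counting oracle", {
  mesh <- generate_arch_mesh(100, 35)
  rec <- generate_pose_records(mesh, excursion_params(seed = 35))
  ps <- estimate_pose_set(rec$meshes)
  tr <- build_trajectory(ps, 100)
  expect_length(tr$poses, oracle_frame_count(default_sequence(), 100))
  expect_length(tr$poses, 607)
  expect_equal(tr$keyframe_indices, c(1, 102, 203, 304, 405, 506, 607))
  expect_true(all(diff(tr$times) > 0))
  # keyframes reproduce the pose-set transforms exactly (same stored values)
  for (k in seq_along(tr$keyframe_indices)) {
    lb <- tr$keyframe_labels[k]
    expect_identical(tr$poses[[tr$keyframe_indices[k]]], ps$poses[[lb]])
  }
  expect_true(validate_trajectory(tr))
})

test_that("two-segment trajectory with n = 1 enumerates to 5 frames", {
  ps <- manual_pose_set(list(
    MIP = identity_transform(),
    PROTRUSIVE = rigid_transform(c(1, 0, 0, 0), c(0, 8, -2)),
    RIGHT_LATEROTRUSIVE = identity_transform(),
    LEFT_LATEROTRUSIVE = identity_transform()
  ))
  tr <- build_trajectory(ps, 1, c("MIP", "PROTRUSIVE", "MIP"))
  expect_length(tr$poses, 5)
  expect_equal(tr$poses[[2]]$t, c(0, 4, -1))   # outbound midpoint
  expect_identical(tr$poses[[3]], ps$poses$PROTRUSIVE)
  expect_equal(tr$poses[[4]]$t, c(0, 4, -1))   # return midpoint
  expect_equal(tr$segment_labels[2], "MIP->PROTRUSIVE")
  expect_equal(tr$segment_labels[4], "PROTRUSIVE->MIP")
})

test_that("degenerate all-identity pose sets still build valid trajectories", {
  ps <- manual_pose_set(stats::setNames(
    rep(list(identity_transform()), 4), pose_labels()))
  tr <- build_trajectory(ps, 10)
  expect_true(all(vapply(tr$poses, function(p) {
    is_identity_transform(p, 1e-12, 1e-12)
  }, logical(1))))
  expect_true(validate_trajectory(tr))
})

test_that("build_trajectory rejects unanchored sequences and unknown labels", {
  ps <- manual_pose_set(stats::setNames(
    rep(list(identity_transform()), 4), pose_labels()))
  expect_error(build_trajectory(ps, 10, c("PROTRUSIVE", "MIP")),
               "start and end at MIP")
  expect_error(build_trajectory(ps, 10, c("MIP", "RETRUSIVE", "MIP")),
               "RETRUSIVE")
  expect_error(build_trajectory(ps, 0), ">= 1")
})

test_that("apply_pose is rigid and inverts cleanly", {
  mesh <- generate_arch_mesh(300, 36)
  same <- apply_pose(mesh, identity_transform())
  expect_identical(same$faces, mesh$faces)
  expect_equal(same$vertices, mesh$vertices, tolerance = 1e-12)
  set.seed(36)
  tf <- random_transform()
  moved <- apply_pose(mesh, tf)
  # rigidity: pairwise distances preserved on 50 sampled vertex pairs
  pairs <- cbind(sample(nrow(mesh$vertices), 50),
                 sample(nrow(mesh$vertices), 50))
  d0 <- sqrt(rowSums((mesh$vertices[pairs[, 1], ] -
                        mesh$vertices[pairs[, 2], ])^2))
  d1 <- sqrt(rowSums((moved$vertices[pairs[, 1], ] -
                        moved$vertices[pairs[, 2], ])^2))
  expect_lt(max(abs(d1 - d0)), 1e-6)
  back <- apply_pose(moved, rebase_anchor(tf))
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-9)
})

test_that("registration round-trip recovers trajectory endpoints", {
  mesh <- generate_arch_mesh(300, 37)
  rec <- generate_pose_records(mesh, excursion_params(seed = 37))
  ps <- estimate_pose_set(rec$meshes)
  # materialize each endpoint (t = 1) and re-register from scratch
  remeshes <- lapply(ps$poses, function(tf) apply_pose(mesh, tf))
  ps2 <- estimate_pose_set(remeshes)
  for (lb in pose_labels()) {
    expect_lt(rot_error(ps2$poses[[lb]], ps$poses[[lb]]), 1e-9)
    expect_lt(trans_error(ps2$poses[[lb]], ps$poses[[lb]]), 1e-9)
  }
})

test_that("validate_trajectory flags unsmooth or unanchored trajectories", {
  ps <- manual_pose_set(list(
    MIP = identity_transform(),
    PROTRUSIVE = rigid_transform(c(1, 0, 0, 0), c(0, 30, 0)),
    RIGHT_LATEROTRUSIVE = identity_transform(),
    LEFT_LATEROTRUSIVE = identity_transform()
  ))
  tr <- build_trajectory(ps, 2, c("MIP", "PROTRUSIVE", "MIP"))
  expect_error(validate_trajectory(tr), "translation step")
  expect_true(validate_trajectory(build_trajectory(
    ps, 30, c("MIP", "PROTRUSIVE", "MIP"))))
})
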