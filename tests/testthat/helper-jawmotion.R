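# Shared fixtures and independent oracles.  Everything here is built in
# code; no binary fixtures are stored.

# Four non-coplanar points (unit tetrahedron).
tetra_points <- function() {
  matrix(c(0, 0, 0,
           1, 0, 0,
           0, 1, 0,
           0, 0, 1), ncol = 3, byrow = TRUE)
}

# Uniform random unit quaternion (canonical sign) under the current RNG.
random_quat <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

random_transform <- function(max_trans = 10) {
  rigid_transform(random_quat(), stats::runif(3, -max_trans, max_trans))
}

# Rotation angle separating two transforms, radians.
rot_error <- function(a, b) rotation_angle(compose_transform(a, rebase_anchor(b)))

trans_error <- function(a, b) sqrt(sum((a$t - b$t)^2))

# Unit-cube mesh: 8 vertices, 12 facets.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  f <- matrix(c(
    1, 3, 4,  1, 4, 2,   # z = 0
    5, 6, 8,  5, 8, 7,   # z = 1
    1, 2, 6,  1, 6, 5,   # y = 0
    3, 7, 8,  3, 8, 4,   # y = 1
    1, 5, 7,  1, 7, 3,   # x = 0
    2, 4, 8,  2, 8, 6    # x = 1
  ), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

# Independent counting oracle for build_trajectory: naive enumeration of the
# assembled frame list (keyframes shared at junctions emitted once).
oracle_frame_count <- function(sequence, n_per_segment) {
  frames <- 1L                             # opening keyframe
  for (s in seq_len(length(sequence) - 1)) {
    frames <- frames + n_per_segment + 1L  # intermediates + closing keyframe
  }
  frames
}

# Build a pose_set directly from known transforms (bypasses registration).
manual_pose_set <- function(poses, mesh = NULL) {
  labels <- pose_labels()
  stopifnot(all(labels %in% names(poses)))
  structure(
    list(
      reference_mesh = mesh,
      poses = poses[labels],
      provenance = stats::setNames(
        rep(list(list(method = "manual", rms = 0, degenerate = FALSE,
                      converged = TRUE)), length(labels)),
        labels
      )
    ),
    class = "pose_set"
  )
}

# Sum of squared residuals of the best translation-only alignment after
# rotating centered source points by R: the brute-force inner objective for
# the Kabsch optimality oracle.
centered_residual <- function(R, source, target) {
  Pc <- sweep(source, 2, colMeans(source))
  Qc <- sweep(target, 2, colMeans(target))
  sum((Pc %*% t(R) - Qc)^2)
}
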