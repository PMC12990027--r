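# Pose interpolation and trajectory assembly.  Rotations interpolate along
# the shortest arc at constant angular speed (quaternion SLERP); translations
# interpolate linearly and independently.  Excursive rotations are a few
# degrees, far from the 180-degree SLERP ambiguity, but quaternion signs are
# aligned anyway.

#' Interpolate between two rigid poses
#'
#' Rotation: shortest-arc spherical linear interpolation of the two unit
#' quaternions (sign-aligned so their dot product is non-negative).
#' Translation: linear interpolation.  `t = 0` and `t = 1` return `a` and
#' `b` exactly (same stored values).
#'
#' @param a,b `rigid_transform` objects.
#' @param t Interpolation fraction in `[0, 1]`.
#' @return A `rigid_transform`.
#' @export
interpolate_pose <- function(a, b, t) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0 || t > 1) {
    stop("interpolation fraction t must be a number in [0, 1]")
  }
  if (t == 0) return(a)
  if (t == 1) return(b)
  qa <- a$q
  qb <- b$q
  d <- sum(qa * qb)
  if (d < 0) {
    qb <- -qb
    d <- -d
  }
  if (d > 1 - 1e-12) {
    q <- (1 - t) * qa + t * qb            # arcs this short: lerp, renormalize
  } else {
    omega <- acos(min(1, d))
    q <- (sin((1 - t) * omega) * qa + sin(t * omega) * qb) / sin(omega)
  }
  rigid_transform(q, (1 - t) * a$t + t * b$t)
}

#' Interpolate the quantified points of one motion segment
#'
#' Emits exactly `n` strictly intermediate poses at fractions
#' `t_k = k / (n + 1)`, `k = 1..n`.  The endpoints are excluded: the static
#' records themselves are emitted separately as trajectory keyframes, so `n`
#' is the user-defined count of transitional frames ("quantified points")
#' between each pair of static records.
#'
#' @param a,b `rigid_transform` endpoints.
#' @param n Number of intermediate poses, `n >= 1`.
#' @return List of `n` `rigid_transform` objects.
#' @export
interpolate_segment <- function(a, b, n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 ||
      n != floor(n)) {
    stop("n (quantified points per segment) must be an integer >= 1")
  }
  n <- as.integer(n)
  lapply(seq_len(n), function(k) interpolate_pose(a, b, k / (n + 1)))
}

#' Default playback sequence of the excursive envelope
#'
#' MIP to protrusive and back, then right laterotrusive and back, then left
#' laterotrusive and back -- a closed loop anchored at MIP.
#'
#' @return Character vector of pose labels.
#' @export
default_sequence <- function() {
  c("MIP", "PROTRUSIVE", "MIP", "RIGHT_LATEROTRUSIVE", "MIP",
    "LEFT_LATEROTRUSIVE", "MIP")
}

#' Build the continuous motion trajectory
#'
#' Concatenates the static records (keyframes) and the interpolated
#' quantified points of every segment into one time-sequenced trajectory.
#' Keyframes shared by adjacent segments (the MIP returns) are emitted once
#' at the junction, so the total frame count is
#' `length(sequence) + n_per_segment * (length(sequence) - 1)`.
#' Keyframe poses are the stored pose-set transforms, bit for bit.
#'
#' @param poses A `pose_set` from [estimate_pose_set()] (or built manually).
#' @param n_per_segment Quantified points per segment (default 100).
#' @param sequence Ordered label sequence; must start and end at MIP.
#' @param frame_interval Seconds between consecutive frames (default 0.01).
#' @return A `motion_trajectory`: list with `times` (s), `poses` (list of
#'   `rigid_transform`), `segment_labels`, `keyframe_indices`,
#'   `keyframe_labels`, `frames_per_segment`, `frame_interval`.
#' @export
build_trajectory <- function(poses, n_per_segment = 100L,
                             sequence = default_sequence(),
                             frame_interval = 0.01) {
  if (!is_pose_set(poses)) stop("poses must be a pose_set")
  if (!is.numeric(n_per_segment) || n_per_segment < 1 ||
      n_per_segment != floor(n_per_segment)) {
    stop("n_per_segment must be an integer >= 1")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  if (length(sequence) < 2) stop("sequence needs at least two labels")
  if (sequence[1] != "MIP" || sequence[length(sequence)] != "MIP") {
    stop("sequence must start and end at MIP")
  }
  unknown <- setdiff(sequence, names(poses$poses))
  if (length(unknown)) {
    stop("unknown pose label(s) in sequence: ",
         paste(unknown, collapse = ", "))
  }
  n_per_segment <- as.integer(n_per_segment)
  frames <- list(poses$poses[[sequence[1]]])
  seg_lab <- sequence[1]
  kf_idx <- 1L
  for (s in seq_len(length(sequence) - 1)) {
    from <- sequence[s]
    to <- sequence[s + 1]
    mids <- interpolate_segment(poses$poses[[from]], poses$poses[[to]],
                                n_per_segment)
    frames <- c(frames, mids, list(poses$poses[[to]]))
    seg_lab <- c(seg_lab, rep(paste0(from, "->", to), n_per_segment), to)
    kf_idx <- c(kf_idx, length(frames))
  }
  structure(
    list(
      times = (seq_along(frames) - 1) * frame_interval,
      poses = frames,
      segment_labels = seg_lab,
      keyframe_indices = kf_idx,
      keyframe_labels = sequence,
      frames_per_segment = n_per_segment,
      frame_interval = frame_interval
    ),
    class = "motion_trajectory"
  )
}

is_motion_trajectory <- function(x) inherits(x, "motion_trajectory")

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf(
    "<motion_trajectory> %d frames (%d keyframes, %d per segment), %.2f s\n",
    length(x$poses), length(x$keyframe_indices), x$frames_per_segment,
    max(x$times)
  ))
  invisible(x)
}

#' Validate a motion trajectory's smoothness and anchoring invariants
#'
#' Checks that times are strictly increasing, that the trajectory is a
#' closed loop anchored at MIP (identity pose first and last), and that
#' consecutive frames differ by bounded motion (default: rotation step below
#' 5 degrees and translation step below 2 mm, a smoothness witness at the
#' default frame density).
#'
#' @param trajectory A `motion_trajectory`.
#' @param max_rotation_step_deg,max_translation_step_mm Bounds per frame.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_trajectory <- function(trajectory, max_rotation_step_deg = 5,
                                max_translation_step_mm = 2) {
  stopifnot(is_motion_trajectory(trajectory))
  if (any(diff(trajectory$times) <= 0)) {
    stop("frame times are not strictly increasing")
  }
  first <- trajectory$poses[[1]]
  last <- trajectory$poses[[length(trajectory$poses)]]
  if (!is_identity_transform(first, 1e-9, 1e-9) ||
      !is_identity_transform(last, 1e-9, 1e-9)) {
    stop("trajectory must start and end at the MIP (identity) pose")
  }
  for (i in seq_len(length(trajectory$poses) - 1)) {
    a <- trajectory$poses[[i]]
    b <- trajectory$poses[[i + 1]]
    step <- compose_transform(b, rebase_anchor(a))
    if (rotation_angle(step) * 180 / pi > max_rotation_step_deg) {
      stop("rotation step exceeds ", max_rotation_step_deg,
           " degrees at frame ", i)
    }
    if (sqrt(sum((b$t - a$t)^2)) > max_translation_step_mm) {
      stop("translation step exceeds ", max_translation_step_mm,
           " mm at frame ", i)
    }
  }
  invisible(TRUE)
}

#' Materialize a pose as a transformed mesh
#'
#' Maps every vertex `v` to `rotate(v) + translation`; topology (facet
#' indices) is unchanged, so correspondence with the input mesh is kept.
#'
#' @param mesh A `triangle_mesh`.
#' @param t A `rigid_transform`.
#' @return The transformed `triangle_mesh`.
#' @export
apply_pose <- function(mesh, t) {
  stopifnot(is_triangle_mesh(mesh), is_rigid_transform(t))
  normals <- mesh$normals
  if (!is.null(normals)) {
    normals <- normals %*% t(quat_to_matrix(t$q))
  }
  triangle_mesh(transform_points(t, mesh$vertices), mesh$faces, normals)
}
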