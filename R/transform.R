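# Rigid transforms on SE(3): unit quaternion (w, x, y, z) plus a millimetre
# translation vector.  A transform maps a point v to rotate(v) + translation.

#' Construct a rigid transform
#'
#' A rigid (SE(3)) transform stores a rotation as a unit quaternion
#' `(w, x, y, z)` and a translation as a 3-vector in millimetres.  The
#' quaternion is normalized and sign-canonicalized (first nonzero component
#' positive, so `w >= 0` away from the 180-degree locus) on construction.
#'
#' @param quaternion Numeric length-4 `(w, x, y, z)`; need not be unit length.
#' @param translation Numeric length-3, millimetres.
#' @return An object of class `rigid_transform` with fields `q` and `t`.
#' @examples
#' rigid_transform()                                  # identity
#' rigid_transform(c(cos(pi / 8), 0, 0, sin(pi / 8)), c(1, 2, 3))
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0),
                            translation = c(0, 0, 0)) {
  quaternion <- as.numeric(quaternion)
  translation <- as.numeric(translation)
  if (length(quaternion) != 4 || any(!is.finite(quaternion))) {
    stop("quaternion must be 4 finite numbers (w, x, y, z)")
  }
  if (length(translation) != 3 || any(!is.finite(translation))) {
    stop("translation must be 3 finite numbers")
  }
  nrm <- sqrt(sum(quaternion^2))
  if (nrm < 1e-12) stop("quaternion has (near-)zero norm")
  q <- quat_canonical(quaternion / nrm)
  structure(list(q = q, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angle %.6g deg, axis (%s), translation (%s) mm\n",
    rotation_angle(x) * 180 / pi,
    paste(sprintf("%.4g", rotation_axis(x)), collapse = ", "),
    paste(sprintf("%.4g", x$t), collapse = ", ")
  ))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform()

# --- quaternion primitives ---------------------------------------------------

quat_canonical <- function(q) {
  nz <- which(abs(q) > 0)
  if (length(nz) && q[nz[1]] < 0) q <- -q
  q
}

quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Convert a unit quaternion to a 3x3 rotation matrix
#' @param q Numeric length-4 unit quaternion `(w, x, y, z)`.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a 3x3 rotation matrix to a unit quaternion
#'
#' Uses the numerically stable variant that branches on the largest diagonal
#' combination (Shepperd's method); the result is sign-canonicalized.
#'
#' @param R 3x3 proper rotation matrix.
#' @return Unit quaternion `(w, x, y, z)`.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  quat_canonical(q / sqrt(sum(q^2)))
}

# --- group operations --------------------------------------------------------

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`:
#' `x -> a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(
    quat_multiply(a$q, b$q),
    as.numeric(quat_to_matrix(a$q) %*% b$t) + a$t
  )
}

#' Invert a rigid transform (re-base the registration anchor)
#'
#' Returns the group inverse: the rotation is conjugated and the translation
#' negated and rotated back.  In the scanning workflow this converts a pose
#' expressed as "maxilla relative to mandible" (scanners often anchor on the
#' mandibular arch) into "mandible relative to maxilla", which is the frame
#' the motion file must use -- otherwise the exported motion appears as
#' movement of the maxilla.
#'
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rebase_anchor <- function(t) {
  stopifnot(is_rigid_transform(t))
  qi <- quat_conjugate(t$q)
  rigid_transform(qi, as.numeric(-(quat_to_matrix(qi) %*% t$t)))
}

#' Apply a rigid transform to a matrix of points
#' @param tf A `rigid_transform`.
#' @param points n x 3 numeric matrix.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(tf, points) {
  stopifnot(is_rigid_transform(tf))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  sweep(points %*% t(quat_to_matrix(tf$q)), 2, tf$t, "+")
}

#' Rotation angle of a rigid transform
#' @param tf A `rigid_transform`.
#' @return Rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(tf) {
  w <- abs(tf$q[1])
  2 * acos(min(1, w))
}

#' Rotation axis of a rigid transform
#' @param tf A `rigid_transform`.
#' @return Unit 3-vector; `(0, 0, 1)` by convention for the identity.
#' @export
rotation_axis <- function(tf) {
  v <- tf$q[2:4]
  n <- sqrt(sum(v^2))
  if (n < 1e-15) return(c(0, 0, 1))
  v / n
}

#' Convert a rigid transform to a 4x4 homogeneous matrix
#' @param tf A `rigid_transform`.
#' @return 4x4 matrix; upper-left 3x3 rotation, last column translation,
#'   bottom row `(0, 0, 0, 1)`.
#' @export
transform_to_matrix4 <- function(tf) {
  stopifnot(is_rigid_transform(tf))
  m <- diag(4)
  m[1:3, 1:3] <- quat_to_matrix(tf$q)
  m[1:3, 4] <- tf$t
  m
}

#' Convert a 4x4 homogeneous matrix to a rigid transform
#' @param m 4x4 homogeneous matrix with orthonormal rotation block.
#' @param tol Orthonormality tolerance on the 3x3 block (default `1e-6`).
#' @return A `rigid_transform`.
#' @export
matrix4_to_transform <- function(m, tol = 1e-6) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("rotation block is not orthonormal")
  }
  if (det(R) < 0) stop("rotation block has determinant -1 (reflection)")
  rigid_transform(matrix_to_quat(R), m[1:3, 4])
}

# True when a transform is the identity to within the given tolerances.
is_identity_transform <- function(tf, rot_tol = 1e-12, trans_tol = 1e-12) {
  rotation_angle(tf) <= rot_tol && sqrt(sum(tf$t^2)) <= trans_tol
}
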