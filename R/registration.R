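# Rigid registration: closed-form Kabsch fit on corresponded vertices, with
# an iterative-closest-point fallback when the scanner export broke vertex
# correspondence.  All poses are expressed in the common maxillary-anchored
# frame, so excursive records start near-aligned (millimetre-scale motion)
# and ICP needs no global initialization.

#' Closed-form least-squares rigid fit (Kabsch)
#'
#' Estimates the rigid transform minimizing the sum of squared distances
#' between `transform(source_points)` and `target_points` over corresponding
#' rows.  Rotation is recovered from the SVD of the centered cross-covariance
#' with a sign flip of the smallest singular direction whenever the raw
#' solution would be a reflection, so the result always has determinant +1;
#' translation follows from the centroids.
#'
#' @param source_points,target_points n x 3 matrices, equal n >= 3.
#' @return A `rigid_transform`.  A rank-deficient (collinear or coincident
#'   beyond repair) configuration is still solved but carries attribute
#'   `degenerate = TRUE`.
#' @export
kabsch <- function(source_points, target_points) {
  P <- as.matrix(source_points)
  Q <- as.matrix(target_points)
  if (nrow(P) != nrow(Q)) stop("point sets must have equal length")
  if (nrow(P) < 3) stop("at least 3 point pairs are required")
  if (ncol(P) != 3 || ncol(Q) != 3) stop("points must be 3D")
  if (any(!is.finite(P)) || any(!is.finite(Q))) {
    stop("non-finite coordinates")
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (max(abs(Pc)) < 1e-12) stop("source points are all coincident")
  H <- crossprod(Pc, Qc)                  # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tf <- rigid_transform(matrix_to_quat(R), cq - as.numeric(R %*% cp))
  # collinear configurations leave the rotation about the line unconstrained
  degenerate <- sv$d[2] < 1e-9 * max(sv$d[1], 1e-300) ||
    qr(Pc)$rank < 3
  attr(tf, "degenerate") <- degenerate
  tf
}

# Index of the nearest row of `ref` for every row of `query`, brute force.
# Arch meshes here are O(1000) vertices, so the n x m distance matrix is
# cheap and avoids a spatial-index dependency.
nearest_neighbor <- function(query, ref) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(ref))) -
    2 * tcrossprod(query, ref)
  # omitting rowSums(ref^2) per column shifts all distances in a row equally;
  # add it back so returned distances are usable
  d2 <- sweep(d2, 2, rowSums(ref^2), "+")
  j <- max.col(-d2, ties.method = "first")
  list(index = j, dist2 = d2[cbind(seq_len(nrow(query)), j)])
}

#' Iterative closest point registration
#'
#' Alternates nearest-neighbor pairing of source vertices against target
#' vertices with the closed-form Kabsch fit until the pairing RMS changes by
#' less than `convergence_tol` or `max_iterations` is reached.  Initializes
#' at the identity: in the maxillary-anchored frame the excursive records are
#' already near-aligned, so no global search is attempted.
#'
#' @param source,target `triangle_mesh` objects.
#' @param max_iterations Iteration cap (default 50).
#' @param convergence_tol RMS change threshold in mm (default `1e-10`).
#' @return A list with `transform` (`rigid_transform`), `rms` (residual RMS,
#'   mm), `converged` (logical), and `iterations`.
#' @export
icp <- function(source, target, max_iterations = 50L,
                convergence_tol = 1e-10) {
  stopifnot(is_triangle_mesh(source), is_triangle_mesh(target))
  if (any(!is.finite(source$vertices)) || any(!is.finite(target$vertices))) {
    stop("non-finite coordinates")
  }
  src <- source$vertices
  tgt <- target$vertices
  # centroid initialization: removes the bulk translation so the identity
  # rotation start only has to absorb the few degrees of excursive rotation
  tf <- rigid_transform(c(1, 0, 0, 0), colMeans(tgt) - colMeans(src))
  moved <- transform_points(tf, src)
  pair_rms <- function(moved, idx) {
    sqrt(mean(rowSums((moved - tgt[idx, , drop = FALSE])^2)))
  }
  rms_prev <- Inf
  rms <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    nn <- nearest_neighbor(moved, tgt)
    rms <- pair_rms(moved, nn$index)
    tf <- kabsch(src, tgt[nn$index, , drop = FALSE])
    moved <- transform_points(tf, src)
    if (abs(rms_prev - rms) < convergence_tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  nn <- nearest_neighbor(moved, tgt)
  list(
    transform = tf,
    rms = pair_rms(moved, nn$index),
    converged = converged,
    iterations = iter
  )
}

#' Estimate the pose set from four labelled occlusal records
#'
#' Given the four mandibular meshes (MIP, right laterotrusive, left
#' laterotrusive, protrusive) in the common maxillary-anchored frame, returns
#' the rigid transform carrying the MIP mesh onto each excursive mesh.  When
#' a record shares vertex correspondence with the MIP mesh (the duplicated
#' scanner-project case) the closed-form Kabsch fit on all shared vertices is
#' used; otherwise ICP.  MIP itself always maps to the identity.
#'
#' @param meshes Named list of `triangle_mesh` objects; names must cover
#'   [pose_labels()].
#' @param icp_enabled Allow the ICP fallback (default `TRUE`); if `FALSE`,
#'   an uncorresponded record is an error.
#' @param icp_max_iterations,icp_tol Passed to [icp()].
#' @param vertex_subset Optional integer vector of vertex indices to track
#'   on the corresponded path (default: all shared vertices).
#' @return A `pose_set`: list with `reference_mesh`, `poses` (named list of
#'   `rigid_transform`, MIP = identity) and `provenance` (per label: method,
#'   residual RMS in mm, degeneracy and convergence flags).
#' @export
estimate_pose_set <- function(meshes, icp_enabled = TRUE,
                              icp_max_iterations = 50L, icp_tol = 1e-10,
                              vertex_subset = NULL) {
  labels <- pose_labels()
  missing <- setdiff(labels, names(meshes))
  if (length(missing)) {
    stop("missing occlusal position(s): ", paste(missing, collapse = ", "))
  }
  for (lb in labels) {
    if (!is_triangle_mesh(meshes[[lb]])) {
      stop("record ", lb, " is not a triangle_mesh")
    }
  }
  ref <- meshes[["MIP"]]
  poses <- list(MIP = identity_transform())
  provenance <- list(MIP = list(method = "reference", rms = 0,
                                degenerate = FALSE, converged = TRUE))
  for (lb in setdiff(labels, "MIP")) {
    mesh <- meshes[[lb]]
    if (check_correspondence(ref, mesh) == "corresponded") {
      idx <- if (is.null(vertex_subset)) seq_len(nrow(ref$vertices)) else
        as.integer(vertex_subset)
      if (any(idx < 1 | idx > nrow(ref$vertices))) {
        stop("vertex_subset out of range")
      }
      tf <- kabsch(ref$vertices[idx, , drop = FALSE],
                   mesh$vertices[idx, , drop = FALSE])
      res <- transform_points(tf, ref$vertices[idx, , drop = FALSE]) -
        mesh$vertices[idx, , drop = FALSE]
      provenance[[lb]] <- list(
        method = "corresponded",
        rms = sqrt(mean(rowSums(res^2))),
        degenerate = isTRUE(attr(tf, "degenerate")),
        converged = TRUE
      )
      attr(tf, "degenerate") <- NULL
      poses[[lb]] <- tf
    } else {
      if (!icp_enabled) {
        stop("record ", lb, " is not vertex-corresponded with MIP and the ",
             "ICP fallback is disabled")
      }
      fit <- icp(ref, mesh, max_iterations = icp_max_iterations,
                 convergence_tol = icp_tol)
      tf <- fit$transform
      provenance[[lb]] <- list(
        method = "icp",
        rms = fit$rms,
        degenerate = isTRUE(attr(tf, "degenerate")),
        converged = fit$converged
      )
      attr(tf, "degenerate") <- NULL
      poses[[lb]] <- tf
    }
  }
  structure(
    list(reference_mesh = ref, poses = poses[labels],
         provenance = provenance[labels]),
    class = "pose_set"
  )
}

is_pose_set <- function(x) inherits(x, "pose_set")

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set>\n")
  for (lb in names(x$poses)) {
    tf <- x$poses[[lb]]
    cat(sprintf(
      "  %-20s %-13s rot %8.4f deg, |t| %8.4f mm, rms %.3g mm\n",
      lb, x$provenance[[lb]]$method,
      rotation_angle(tf) * 180 / pi, sqrt(sum(tf$t^2)),
      x$provenance[[lb]]$rms
    ))
  }
  invisible(x)
}
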