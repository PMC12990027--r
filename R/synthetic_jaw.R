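# Parametric synthetic mandibular arch and excursive records.  Stands in for
# the clinical scanning steps so the whole pipeline is testable without scan
# data.  Frame convention: +x lateral (patient right), +y anterior, +z
# superior, millimetres; the maxilla is the fixed frame.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Excursion parameters for the synthetic jaw generator
#'
#' Magnitudes are clinically plausible defaults at millimetre / degree
#' scale -- they are modelling choices of this package, not measured values:
#' 8 mm protrusive advance with a 2 mm inferior drop (incisal-guidance
#' proxy), 10 degrees of laterotrusive yaw about a vertical axis through a
#' condylar proxy placed 50 mm lateral of the midline at the posterior hinge
#' plane.
#'
#' @param protrusion_advance Anterior translation at protrusion, mm (>= 0).
#' @param protrusion_drop Inferior translation at protrusion, mm.
#' @param laterotrusion_angle Yaw at lateral excursion, degrees, in [0, 45).
#' @param condyle_offset Half inter-condylar width, mm: lateral placement of
#'   the vertical rotation axis.
#' @param noise_sigma Per-vertex Gaussian scan-noise standard deviation, mm
#'   (>= 0).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `excursion_params`.
#' @export
excursion_params <- function(protrusion_advance = 8, protrusion_drop = 2,
                             laterotrusion_angle = 10, condyle_offset = 50,
                             noise_sigma = 0, seed = 1L) {
  if (protrusion_advance < 0) stop("protrusion_advance must be >= 0")
  if (laterotrusion_angle < 0 || laterotrusion_angle >= 45) {
    stop("laterotrusion_angle must be in [0, 45) degrees")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(
    list(protrusion_advance = protrusion_advance,
         protrusion_drop = protrusion_drop,
         laterotrusion_angle = laterotrusion_angle,
         condyle_offset = condyle_offset,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "excursion_params"
  )
}

#' Generate a synthetic mandibular-arch mesh
#'
#' A horseshoe-shaped band: a parabolic arch (posterior ends at y = 0,
#' anterior apex about 45 mm forward, 56 mm wide) swept with a bumped
#' profile imitating cusps, plus small seeded vertex jitter.  Non-planar and
#' of full affine rank, so rigid registration on it is well posed.
#' Deterministic given the seed.
#'
#' @param n_vertices Minimum vertex count (>= 50); the actual count is
#'   rounded up to fill the sweep grid.
#' @param seed Integer seed.
#' @return A `triangle_mesh`.
#' @export
generate_arch_mesh <- function(n_vertices = 500L, seed = 1L) {
  if (!is.numeric(n_vertices) || n_vertices < 50) {
    stop("n_vertices must be >= 50")
  }
  n_profile <- 5L                          # rows across the band
  n_sweep <- as.integer(ceiling(n_vertices / n_profile))
  half_width <- 28                         # mm, arch half-width
  depth <- 45                              # mm, posterior-to-anterior depth
  band <- 9                                # mm, occlusal table width
  s <- seq(-1, 1, length.out = n_sweep)    # sweep parameter, right to left
  w <- seq(-1, 1, length.out = n_profile)  # across-band parameter
  cx <- half_width * s
  cy <- depth * (1 - s^2)
  # unit normal of the arch centerline in the occlusal plane
  dx <- rep(half_width, n_sweep) / half_width
  dy <- (-2 * depth * s) / half_width
  nl <- sqrt(dx^2 + dy^2)
  nx <- -dy / nl
  ny <- dx / nl
  verts <- matrix(0, nrow = n_sweep * n_profile, ncol = 3)
  cusp <- 1.8 * sin(7 * pi * (s + 1) / 2)^2          # cusp-like relief, mm
  jitter <- with_seed(seed, matrix(stats::rnorm(n_sweep * n_profile * 3,
                                                sd = 0.05),
                                   ncol = 3))
  k <- 0L
  for (j in seq_len(n_profile)) {
    off <- band / 2 * w[j]
    rows <- k + seq_len(n_sweep)
    verts[rows, 1] <- cx + off * nx
    verts[rows, 2] <- cy + off * ny
    # occlusal relief: cusps fade toward the band edges, plus a curved table
    verts[rows, 3] <- cusp * (1 - w[j]^2) + 2.5 * w[j]^2 + 4 * s^2
    k <- k + n_sweep
  }
  verts <- verts + jitter
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  faces <- matrix(0L, nrow = 2 * (n_sweep - 1) * (n_profile - 1), ncol = 3)
  f <- 0L
  for (j in seq_len(n_profile - 1)) {
    base <- (j - 1L) * n_sweep
    for (i in seq_len(n_sweep - 1)) {
      faces[f + 1:2, ] <- quad(base + i, base + i + 1L,
                               base + n_sweep + i + 1L, base + n_sweep + i)
      f <- f + 2L
    }
  }
  triangle_mesh(verts, faces)
}

# Ground-truth transforms for the four records under the given parameters.
excursion_truth <- function(params) {
  deg <- pi / 180
  yaw <- function(angle_rad, pivot_xy) {
    q <- c(cos(angle_rad / 2), 0, 0, sin(angle_rad / 2))
    R <- quat_to_matrix(q)
    p <- c(pivot_xy, 0)
    rigid_transform(q, p - as.numeric(R %*% p))
  }
  list(
    MIP = identity_transform(),
    # right excursion: clockwise yaw (viewed from above) about the right
    # (working-side) condylar axis moves the chin toward the patient's right
    RIGHT_LATEROTRUSIVE = yaw(-params$laterotrusion_angle * deg,
                              c(params$condyle_offset, 0)),
    LEFT_LATEROTRUSIVE = yaw(params$laterotrusion_angle * deg,
                             c(-params$condyle_offset, 0)),
    PROTRUSIVE = rigid_transform(
      c(1, 0, 0, 0),
      c(0, params$protrusion_advance, -params$protrusion_drop)
    )
  )
}

#' Generate the four occlusal records with ground truth
#'
#' MIP is the untransformed mesh; the protrusive record translates the arch
#' anteriorly (and inferiorly by the drop); the laterotrusive records yaw it
#' about a vertical axis through the working-side condylar proxy.  Optional
#' per-vertex Gaussian scan noise is added after transforming, seeded per
#' record.  The generating transforms are returned alongside, so at zero
#' noise `apply_pose(mesh, truth[[label]])` reproduces each record exactly.
#'
#' @param mesh The MIP `triangle_mesh` (e.g. from [generate_arch_mesh()]).
#' @param params An `excursion_params`.
#' @return List with `meshes` (named list of `triangle_mesh`) and `truth`
#'   (named list of `rigid_transform`), both covering [pose_labels()].
#' @export
generate_pose_records <- function(mesh, params = excursion_params()) {
  stopifnot(is_triangle_mesh(mesh), inherits(params, "excursion_params"))
  truth <- excursion_truth(params)
  meshes <- list()
  labels <- pose_labels()
  for (i in seq_along(labels)) {
    lb <- labels[i]
    posed <- apply_pose(mesh, truth[[lb]])
    if (params$noise_sigma > 0) {
      noise <- with_seed(params$seed * 8L + i,
                         matrix(stats::rnorm(length(posed$vertices),
                                             sd = params$noise_sigma),
                                ncol = 3))
      posed <- triangle_mesh(posed$vertices + noise, posed$faces)
    }
    meshes[[lb]] <- posed
  }
  list(meshes = meshes, truth = truth)
}

#' Break vertex correspondence by permuting the vertex table
#'
#' Permutes the vertex order and re-indexes facets consistently: the mesh is
#' geometrically identical as a point set but no longer vertex-corresponded,
#' which exercises the ICP fallback.
#'
#' @param mesh A `triangle_mesh`.
#' @param seed Integer seed for the permutation.
#' @return The permuted `triangle_mesh`.
#' @export
break_correspondence <- function(mesh, seed = 1L) {
  stopifnot(is_triangle_mesh(mesh))
  n <- nrow(mesh$vertices)
  perm <- with_seed(seed, sample.int(n))
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  triangle_mesh(mesh$vertices[perm, , drop = FALSE],
                matrix(inv[mesh$faces], ncol = 3))
}
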