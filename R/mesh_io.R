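# Triangle meshes and STL I/O.  STL is the only geometry format the pipeline
# consumes: scanner exports are STL and the motion script is STL-only.
# Coordinates are interpreted as millimetres (dental scanner convention);
# STL carries no unit metadata, so this is a documented assumption.

#' The four occlusal position labels
#'
#' The workflow consumes exactly four labelled interocclusal records:
#' maximum intercuspation (MIP; centric occlusion stands in for MIP in
#' edentulous cases), right laterotrusive, left laterotrusive, and full
#' protrusive.
#'
#' @return Character vector of the four labels, MIP first.
#' @export
pose_labels <- function() {
  c("MIP", "RIGHT_LATEROTRUSIVE", "LEFT_LATEROTRUSIVE", "PROTRUSIVE")
}

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals Optional m x 3 matrix of per-facet unit normals (or all
#'   zero, which STL permits); if `NULL` they are recomputed from winding
#'   on write.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || nrow(vertices) < 3) {
    stop("vertices must be an n x 3 matrix with n >= 3")
  }
  if (ncol(faces) != 3 || nrow(faces) < 1) {
    stop("faces must be an m x 3 matrix with m >= 1")
  }
  if (any(!is.finite(vertices))) stop("vertices contain non-finite values")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("facet indices out of range")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(faces))) {
      stop("normals must match facet count")
    }
    nn <- sqrt(rowSums(normals^2))
    if (any(nn > 1e-12 & abs(nn - 1) > 1e-6)) {
      stop("stored facet normals must be unit length or zero")
    }
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d facets, bbox %.2f x %.2f x %.2f mm\n",
    nrow(x$vertices), nrow(x$faces),
    bb[2, 1] - bb[1, 1], bb[2, 2] - bb[1, 2], bb[2, 3] - bb[1, 3]
  ))
  invisible(x)
}

# Per-facet normals from vertex winding; zero vector for degenerate facets.
facet_normals <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  n <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(n^2))
  keep <- len > 1e-30
  n[keep, ] <- n[keep, , drop = FALSE] / len[keep]
  n[!keep, ] <- 0
  n
}

# Exact (bit-level) coordinate key for vertex merging.  STL stores each facet
# as an independent vertex triple; merging by exact equality -- never by
# tolerance -- keeps duplicated scanner exports in identical vertex order,
# the property the corresponded registration fast path relies on.
vertex_keys <- function(coords) {
  paste(sprintf("%.17g", coords[, 1]),
        sprintf("%.17g", coords[, 2]),
        sprintf("%.17g", coords[, 3]))
}

# Build a triangle_mesh from the raw facet-triple soup of an STL file,
# merging duplicated vertices in first-occurrence order.
mesh_from_soup <- function(coords, normals = NULL) {
  keys <- vertex_keys(coords)
  idx <- match(keys, keys)                 # first occurrence of each key
  first <- !duplicated(idx)
  remap <- integer(nrow(coords))
  remap[which(first)] <- seq_len(sum(first))
  vert_idx <- remap[idx]
  vertices <- coords[first, , drop = FALSE]
  faces <- matrix(vert_idx, ncol = 3, byrow = TRUE)
  triangle_mesh(vertices, faces, normals)
}

#' Read a triangle mesh from an STL file
#'
#' Auto-detects the binary and ASCII dialects.  Duplicated vertices across
#' facet records are merged by exact coordinate equality into a shared vertex
#' table, preserving first-occurrence order.  Stored normals are discarded
#' and recomputed from vertex winding when needed, since scanner exports
#' frequently carry junk normals.
#'
#' @param path Path to an `.stl` file.
#' @return A `triangle_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (size == 0) stop("STL format error: empty file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 84))
  is_binary <- FALSE
  if (size >= 84) {
    count <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (count >= 0 && size == 84 + 50 * as.numeric(count)) is_binary <- TRUE
  }
  starts_solid <- length(head) >= 5 &&
    identical(rawToChar(head[1:5]), "solid")
  if (is_binary) {
    read_stl_binary(con, head, size)
  } else if (starts_solid) {
    read_stl_ascii(path)
  } else if (size >= 84) {
    stop("STL format error: truncated binary payload in ", path,
         " (expected 84 + 50 * facet_count bytes)")
  } else {
    stop("STL format error: not a recognizable STL file: ", path)
  }
}

read_stl_binary <- function(con, head, size) {
  count <- readBin(head[81:84], "integer", size = 4, endian = "little")
  payload <- readBin(con, "raw", n = size - 84)
  if (length(payload) != 50 * count) {
    stop("STL format error: truncated binary payload")
  }
  # each 50-byte record: 12 little-endian float32 then a 2-byte attribute
  float_idx <- as.vector(outer(1:48, (seq_len(count) - 1) * 50, "+"))
  floats <- readBin(payload[float_idx], "double", size = 4,
                    n = 12 * count, endian = "little")
  rec <- matrix(floats, nrow = 12)
  coords <- matrix(as.vector(rec[4:12, ]), ncol = 3, byrow = TRUE)
  mesh_from_soup(coords)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vtx_lines <- grep("^\\s*vertex\\s", lines)
  if (length(vtx_lines) == 0 || length(vtx_lines) %% 3 != 0) {
    stop("STL format error in ", path, ": expected vertex lines in triples, ",
         "found ", length(vtx_lines))
  }
  coords <- matrix(0, nrow = length(vtx_lines), ncol = 3)
  for (i in seq_along(vtx_lines)) {
    ln <- vtx_lines[i]
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (length(vals) != 3 || any(is.na(vals))) {
      stop("STL format error in ", path, " at line ", ln,
           ": cannot parse vertex coordinates")
    }
    coords[i, ] <- vals
  }
  n_facets <- length(grep("^\\s*facet\\s", lines))
  if (n_facets != nrow(coords) / 3) {
    stop("STL format error in ", path, ": ", n_facets,
         " facet headers but ", nrow(coords) / 3, " vertex triples")
  }
  mesh_from_soup(coords)
}

#' Write a triangle mesh to an STL file
#'
#' Binary STL stores coordinates as 32-bit floats, so a write/read round trip
#' preserves coordinates only to float32 precision; ASCII output prints 9
#' significant digits, which exceeds float32 precision.  Facet normals are
#' recomputed from vertex winding.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(is_triangle_mesh(mesh))
  dialect <- match.arg(dialect)
  normals <- facet_normals(mesh)
  m <- nrow(mesh$faces)
  tri <- function(k) mesh$vertices[mesh$faces[, k], , drop = FALSE]
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "jawmotion binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    # 12 float32 per facet: normal, v1, v2, v3 (row-major per record)
    rec <- rbind(t(normals), t(tri(1)), t(tri(2)), t(tri(3)))
    float_raw <- writeBin(as.vector(rec), raw(), size = 4, endian = "little")
    payload <- raw(50 * m)
    float_idx <- as.vector(outer(1:48, (seq_len(m) - 1) * 50, "+"))
    payload[float_idx] <- float_raw
    writeBin(payload, con)
  } else {
    v1 <- tri(1); v2 <- tri(2); v3 <- tri(3)
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    blocks <- paste0(
      "  facet normal ", fmt(normals), "\n",
      "    outer loop\n",
      "      vertex ", fmt(v1), "\n",
      "      vertex ", fmt(v2), "\n",
      "      vertex ", fmt(v3), "\n",
      "    endloop\n",
      "  endfacet"
    )
    writeLines(c("solid jawmotion", blocks, "endsolid jawmotion"), path)
  }
  invisible(path)
}

#' Check vertex correspondence between two meshes
#'
#' Two meshes are corresponded when they have equal vertex and facet counts
#' and bit-identical facet index triples -- the situation produced by
#' duplicating a scanner project and re-exporting the same mandibular mesh in
#' different poses.  Corresponded meshes admit the closed-form Kabsch fit on
#' shared vertices; anything else needs ICP.
#'
#' @param a,b `triangle_mesh` objects.
#' @return `"corresponded"` or `"uncorresponded"`.
#' @export
check_correspondence <- function(a, b) {
  stopifnot(is_triangle_mesh(a), is_triangle_mesh(b))
  ok <- nrow(a$vertices) == nrow(b$vertices) &&
    nrow(a$faces) == nrow(b$faces) &&
    all(a$faces == b$faces)
  if (ok) "corresponded" else "uncorresponded"
}
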