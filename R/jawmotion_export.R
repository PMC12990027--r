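# XML jaw-motion serialization.  The vendor (.jawMotion) schema is not
# published, so the package defines an open, documented dialect: per-frame
# 4x4 homogeneous matrices (row-major, millimetre translation column) plus
# frame times and free-form metadata.  CAD ecosystems consume 4x4 matrices,
# so quaternions stay internal.  See inst/extdata/jawmotion-schema.md.

JAWMOTION_SCHEMA_VERSION <- "1.0"

#' Construct a motion document
#'
#' The serializable form of a trajectory: one 4x4 homogeneous matrix and a
#' time stamp per frame, plus metadata.  Validates that every matrix is a
#' proper rigid motion (orthonormal rotation block, det +1, exact
#' `(0,0,0,1)` bottom row) and that times strictly increase.
#'
#' @param times Numeric vector of frame times, seconds, strictly increasing.
#' @param matrices List of 4x4 homogeneous matrices, one per frame.
#' @param metadata Named character vector or list of scalar metadata.
#' @param schema_version Schema version string.
#' @return An object of class `motion_document`.
#' @export
motion_document <- function(times, matrices,
                            metadata = list(),
                            schema_version = JAWMOTION_SCHEMA_VERSION) {
  times <- as.numeric(times)
  if (length(times) == 0) stop("a motion document needs at least one frame")
  if (length(matrices) != length(times)) {
    stop("times and matrices must have equal length")
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  for (i in seq_along(matrices)) {
    m <- as.matrix(matrices[[i]])
    if (!all(dim(m) == c(4, 4)) || any(!is.finite(m))) {
      stop("frame ", i, ": matrix is not a finite 4x4 matrix")
    }
    if (!identical(as.numeric(m[4, ]), c(0, 0, 0, 1))) {
      stop("frame ", i, ": bottom row must be exactly (0, 0, 0, 1)")
    }
    R <- m[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
      stop("frame ", i, ": rotation block is not orthonormal")
    }
    if (det(R) < 0) {
      stop("frame ", i, ": rotation block is a reflection (det -1)")
    }
    matrices[[i]] <- m
  }
  metadata <- lapply(metadata, function(v) as.character(v)[1])
  structure(
    list(schema_version = as.character(schema_version),
         times = times, matrices = matrices, metadata = metadata),
    class = "motion_document"
  )
}

is_motion_document <- function(x) inherits(x, "motion_document")

#' @export
print.motion_document <- function(x, ...) {
  cat(sprintf("<motion_document> schema %s, %d frames, %.2f s\n",
              x$schema_version, length(x$times), max(x$times)))
  invisible(x)
}

#' Convert a trajectory to a motion document
#'
#' One frame record per trajectory frame; each quaternion-plus-translation
#' pose becomes a 4x4 homogeneous matrix.  The conversion is bijective to
#' machine precision.
#'
#' @param trajectory A `motion_trajectory`.
#' @param generator Generator name recorded in the metadata.
#' @return A `motion_document`.
#' @export
as_motion_document <- function(trajectory, generator = "jawmotion") {
  stopifnot(is_motion_trajectory(trajectory))
  motion_document(
    times = trajectory$times,
    matrices = lapply(trajectory$poses, transform_to_matrix4),
    metadata = list(
      generator = generator,
      frames_per_segment = trajectory$frames_per_segment,
      frame_interval_s = format(trajectory$frame_interval, digits = 15),
      sequence = paste(trajectory$keyframe_labels, collapse = ",")
    )
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# 12 significant digits: keeps the write/read round trip within 1e-9 even
# for translations of tens of millimetres, without bloating 600-frame files.
fmt9 <- function(x) sprintf("%.12g", x)

#' Write a motion document as an XML jaw-motion file
#'
#' Emits well-formed UTF-8 XML with a declared schema version.  Numeric
#' fields are printed with 12 significant digits.  `extension_mode` selects
#' the file extension only: `"jawMotion"` writes a byte-identical payload
#' under the `.jawMotion` extension expected by some dental CAD versions.
#'
#' @param doc A `motion_document`.
#' @param path Output path; its extension is replaced according to
#'   `extension_mode`.
#' @param extension_mode `"xml"` (default) or `"jawMotion"`.
#' @return The path actually written, invisibly.
#' @export
write_motion_xml <- function(doc, path, extension_mode = c("xml", "jawMotion")) {
  stopifnot(is_motion_document(doc))
  extension_mode <- match.arg(extension_mode)
  if (length(doc$times) == 0) stop("refusing to write a zero-frame motion file")
  out <- sub("\\.(xml|jawMotion|jawmotion)$", "", path)
  out <- paste0(out, ".", extension_mode)
  meta_lines <- if (length(doc$metadata)) {
    sprintf('    <Entry key="%s">%s</Entry>',
            xml_escape(names(doc$metadata)),
            xml_escape(unlist(doc$metadata)))
  } else {
    character(0)
  }
  frame_lines <- vapply(seq_along(doc$times), function(i) {
    m <- doc$matrices[[i]]
    paste0(
      sprintf('    <Frame index="%d" time="%s">\n', i - 1L,
              fmt9(doc$times[i])),
      "      <Matrix>",
      paste(fmt9(as.vector(t(m))), collapse = " "),   # row-major
      "</Matrix>\n    </Frame>"
    )
  }, character(1))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<JawMotion schemaVersion="%s">', xml_escape(doc$schema_version)),
    "  <Metadata>",
    meta_lines,
    "  </Metadata>",
    sprintf('  <Frames count="%d">', length(doc$times)),
    frame_lines,
    "  </Frames>",
    "</JawMotion>"
  )
  con <- file(out, open = "wb")           # byte-stable across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(out)
}

#' Read and validate an XML jaw-motion file
#'
#' Parses a file produced by [write_motion_xml()] (or conforming to the
#' documented schema), re-validating every frame: orthonormal rotation block
#' with determinant +1, exact `(0,0,0,1)` bottom row, strictly increasing
#' times.  A missing schema version is a parse error, never a silent
#' default.
#'
#' @param path Path to a `.xml` or `.jawMotion` file.
#' @return A `motion_document`.
#' @export
read_motion_xml <- function(path) {
  if (!file.exists(path)) stop("motion file not found: ", path)
  x <- xml2::read_xml(path)               # stops on malformed XML
  if (xml2::xml_name(x) != "JawMotion") {
    stop("motion file parse error: root element must be <JawMotion>")
  }
  version <- xml2::xml_attr(x, "schemaVersion")
  if (is.na(version)) {
    stop("motion file parse error: missing schemaVersion attribute")
  }
  meta_nodes <- xml2::xml_find_all(x, "./Metadata/Entry")
  metadata <- as.list(xml2::xml_text(meta_nodes))
  names(metadata) <- xml2::xml_attr(meta_nodes, "key")
  frames <- xml2::xml_find_all(x, "./Frames/Frame")
  if (length(frames) == 0) {
    stop("motion file parse error: no <Frame> records")
  }
  times <- as.numeric(xml2::xml_attr(frames, "time"))
  if (any(is.na(times))) {
    stop("motion file parse error: unparsable frame time")
  }
  matrices <- lapply(seq_along(frames), function(i) {
    txt <- xml2::xml_text(xml2::xml_find_first(frames[[i]], "./Matrix"))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) != 16 || any(is.na(vals))) {
      stop("motion file validation error at frame ", i - 1L,
           ": expected 16 numeric matrix entries")
    }
    matrix(vals, nrow = 4, byrow = TRUE)
  })
  tryCatch(
    motion_document(times, matrices, metadata, version),
    error = function(e) {
      stop("motion file validation error: ", conditionMessage(e),
           call. = FALSE)
    }
  )
}
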