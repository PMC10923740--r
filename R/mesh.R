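## TriMesh container: indexed triangle surface in mm.

#' Construct a triangle mesh
#'
#' Builds a validated indexed triangle surface. Duplicate vertices within
#' `merge_tol` are merged (STL files store a triangle soup) and zero-area
#' faces are dropped.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param scalar optional per-vertex scalar channel (length n), carried
#'   through PLY export (used for deviation maps).
#' @param merge_tol duplicate-vertex merge tolerance in mm.
#' @return an object of class `hto_mesh` with elements `vertices`, `faces`
#'   and optionally `scalar`.
#' @export
tri_mesh <- function(vertices, faces, scalar = NULL, merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("validation error: vertices must be an n x 3 matrix", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) == 0L || ncol(faces) != 3L)
    stop("validation error: mesh has no faces", call. = FALSE)
  if (any(is.na(vertices)) || any(!is.finite(vertices)))
    stop("validation error: non-finite vertex coordinates", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("validation error: face indices out of range", call. = FALSE)

  if (!is.null(merge_tol) && merge_tol > 0) {
    key <- paste(round(vertices[, 1] / merge_tol),
                 round(vertices[, 2] / merge_tol),
                 round(vertices[, 3] / merge_tol))
    first <- !duplicated(key)
    map <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    if (!is.null(scalar)) scalar <- scalar[first]
    faces[] <- map[faces]
  }

  ## drop collapsed and zero-area faces
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  if (nrow(faces) > 0L) {
    e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-10, , drop = FALSE]
  }
  if (nrow(faces) == 0L)
    stop("validation error: mesh has no non-degenerate faces", call. = FALSE)
  if (nrow(vertices) < 4L)
    stop("validation error: mesh needs at least 4 vertices", call. = FALSE)
  if (!is.null(scalar) && length(scalar) != nrow(vertices))
    stop("validation error: scalar channel length mismatch", call. = FALSE)

  structure(list(vertices = vertices, faces = faces, scalar = scalar),
            class = "hto_mesh")
}

#' @export
print.hto_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("hto_mesh: %d vertices, %d faces%s\n", nrow(x$vertices),
              nrow(x$faces), if (is.null(x$scalar)) "" else ", scalar channel"))
  cat(sprintf("  bbox [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

## per-face unit normals (right-hand rule over vertex order)
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

## signed volume via divergence theorem; positive for outward-oriented closed meshes
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

## TRUE when every interior edge is shared by two faces with opposite direction
mesh_orientation_consistent <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  !any(duplicated(paste(from, to)))
}

## concatenate two meshes (disjoint vertex sets, no merging)
concat_meshes <- function(a, b) {
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)),
           scalar = if (!is.null(a$scalar) && !is.null(b$scalar))
             c(a$scalar, b$scalar) else NULL,
           merge_tol = 0)
}

mesh_bbox <- function(mesh) apply(mesh$vertices, 2, range)
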