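## Mesh file I/O: STL (binary and ASCII) and ASCII PLY with an optional
## per-vertex scalar channel. STL carries no units; this package fixes the
## convention to millimetres.

#' Read a surface mesh
#'
#' Reads binary STL, ASCII STL or ASCII PLY (format auto-detected). Duplicate
#' vertices within 1e-6 mm are merged into an indexed mesh.
#'
#' @param path file path.
#' @return an `hto_mesh`; PLY files with a `quality` property populate the
#'   scalar channel.
#' @export
read_surface_mesh <- function(path) {
  if (!file.exists(path))
    stop("I/O error: no such file: ", path, call. = FALSE)
  head <- readBin(path, "raw", n = 512L)
  if (length(head) >= 3 && identical(rawToChar(head[1:3]), "ply"))
    return(read_ply(path))
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84)
    stop(sprintf("format error: binary STL '%s' truncated at byte %d (header needs 84 bytes)",
                 path, size), call. = FALSE)
  raw <- readBin(path, "raw", n = size)
  ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (ntri <= 0L)
    stop("validation error: empty STL mesh: ", path, call. = FALSE)
  expected <- 84 + 50 * as.numeric(ntri)
  if (size < expected)
    stop(sprintf("format error: binary STL '%s' truncated at byte %.0f (expected %.0f bytes for %d triangles)",
                 path, size, expected, ntri), call. = FALSE)
  ## each 50-byte record: normal (3 floats), 3 vertices (9 floats), 2 attr bytes
  rec <- matrix(85:(84 + 50 * ntri), nrow = 50)
  dat <- readBin(raw[as.vector(rec[1:48, ])], "numeric", size = 4L,
                 n = 12L * ntri, endian = "little")
  dat <- matrix(dat, ncol = 12, byrow = TRUE)
  verts <- rbind(dat[, 4:6, drop = FALSE], dat[, 7:9, drop = FALSE],
                 dat[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L)
    stop("validation error: empty STL mesh: ", path, call. = FALSE)
  if (length(vl) %% 3L != 0L)
    stop("format error: ASCII STL '", path,
         "' has a vertex count not divisible by 3", call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(x) suppressWarnings(as.numeric(x[-1])))
  if (any(lengths(nums) != 3L) || any(vapply(nums, anyNA, TRUE)))
    stop("format error: unparseable vertex line in ASCII STL '", path, "'",
         call. = FALSE)
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Write a surface mesh
#'
#' @param mesh an `hto_mesh`.
#' @param path output file path.
#' @param format one of `"stl-binary"`, `"stl-ascii"`, `"ply"`. The PLY
#'   variant carries the per-vertex scalar channel (as `quality`) if present.
#' @export
write_surface_mesh <- function(mesh, path,
                               format = c("stl-binary", "stl-ascii", "ply")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "hto_mesh"))
  switch(format,
         "stl-binary" = write_stl_binary(mesh, path),
         "stl-ascii" = write_stl_ascii(mesh, path),
         "ply" = write_ply(mesh, path))
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error: cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  ntri <- nrow(mesh$faces)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  n <- face_normals(mesh)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  dat <- cbind(n, v1, v2, v3)          # ntri x 12
  for (i in seq_len(ntri)) {
    writeBin(as.numeric(dat[i, ]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  n <- face_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  fmt3 <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c("solid hto3d",
             as.vector(rbind(
               sprintf("  facet normal %s", fmt3(n)),
               "    outer loop",
               sprintf("      vertex %s", fmt3(v[f[, 1], , drop = FALSE])),
               sprintf("      vertex %s", fmt3(v[f[, 2], , drop = FALSE])),
               sprintf("      vertex %s", fmt3(v[f[, 3], , drop = FALSE])),
               "    endloop",
               "  endfacet")),
             "endsolid hto3d")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("I/O error: cannot write ", path,
                                    call. = FALSE))
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  has_scalar <- !is.null(mesh$scalar)
  header <- c("ply", "format ascii 1.0", "comment hto3d",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              if (has_scalar) "property float quality",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vlines <- if (has_scalar)
    sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3], mesh$scalar)
  else sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  flines <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  tryCatch(writeLines(c(header, vlines, flines), path),
           error = function(e) stop("I/O error: cannot write ", path,
                                    call. = FALSE))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end))
    stop("format error: PLY '", path, "' has no end_header", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format binary", header)))
    stop("format error: only ASCII PLY is supported: ", path, call. = FALSE)
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", header, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L || is.na(nv) || is.na(nf))
    stop("format error: PLY '", path, "' missing element counts", call. = FALSE)
  vprops <- sub("^property \\S+ ", "",
                grep("^property (float|double|float32|float64) ",
                     header[seq_len(which(grepl("^element face", header))[1])],
                     value = TRUE))
  body <- lines[(end + 1L):length(lines)]
  if (length(body) < nv + nf)
    stop(sprintf("format error: PLY '%s' truncated (needs %d body lines, has %d)",
                 path, nv + nf, length(body)), call. = FALSE)
  vdat <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  ixyz <- match(c("x", "y", "z"), vprops)
  if (anyNA(ixyz))
    stop("format error: PLY '", path, "' lacks x/y/z properties", call. = FALSE)
  verts <- vdat[, ixyz, drop = FALSE]
  iq <- match("quality", vprops)
  scalar <- if (!is.na(iq)) vdat[, iq] else NULL
  fdat <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE),
                 nrow = nf, byrow = TRUE)
  if (any(fdat[, 1] != 3))
    stop("format error: PLY '", path, "' contains non-triangle faces",
         call. = FALSE)
  faces <- fdat[, 2:4, drop = FALSE] + 1L
  tri_mesh(verts, faces, scalar = scalar, merge_tol = 0)
}
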