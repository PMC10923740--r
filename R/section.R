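## Planar cross-sections of a mesh: contour extraction and area centroids.
## Used to construct the anatomical shaft axis from mid-shaft section
## midpoints.

## Intersect a mesh with the plane {p : (p - point) . normal = 0}.
## Returns a list of contours, each a list(points = k x 3 matrix of ordered
## polyline vertices, closed = logical).
mesh_section <- function(mesh, point, normal) {
  n <- unit3(normal)
  s <- as.numeric(sweep(mesh$vertices, 2, point) %*% n)
  ## nudge vertices exactly on the plane to avoid degenerate crossings
  s[abs(s) < 1e-12] <- 1e-12
  f <- mesh$faces
  sf <- matrix(s[f], ncol = 3)
  crossing <- which((rowSums(sf > 0) %% 3L) != 0L)
  if (length(crossing) == 0L) return(list())

  ## each crossing face contributes one segment whose endpoints lie on two
  ## of its edges; intersection points are shared between faces via a
  ## canonical undirected edge key, which makes contour chaining exact
  seg_a <- character(0); seg_b <- character(0)
  pts <- new.env(parent = emptyenv())
  edge_point <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    if (is.null(pts[[key]])) {
      t <- s[i] / (s[i] - s[j])
      pts[[key]] <- mesh$vertices[i, ] + t * (mesh$vertices[j, ] - mesh$vertices[i, ])
    }
    key
  }
  for (fi in crossing) {
    vs <- f[fi, ]
    pos <- s[vs] > 0
    lone <- if (sum(pos) == 1L) which(pos) else which(!pos)
    o <- vs[lone]; r <- vs[-lone]
    k1 <- edge_point(o, r[1])
    k2 <- edge_point(o, r[2])
    seg_a <- c(seg_a, k1); seg_b <- c(seg_b, k2)
  }

  ## chain segments into contours by walking shared endpoint keys
  keys <- unique(c(seg_a, seg_b))
  ia <- match(seg_a, keys); ib <- match(seg_b, keys)
  nk <- length(keys)
  adj <- vector("list", nk)
  for (si in seq_along(ia)) {
    adj[[ia[si]]] <- c(adj[[ia[si]]], ib[si])
    adj[[ib[si]]] <- c(adj[[ib[si]]], ia[si])
  }
  visited <- logical(nk)
  contours <- list()
  deg <- lengths(adj)
  ## open chains are walked from a free end (degree 1) so they come out in
  ## order; loops have degree 2 everywhere and can start anywhere
  for (start in order(deg)) {
    if (visited[start]) next
    chain <- integer(0)
    node <- start
    repeat {
      visited[node] <- TRUE
      chain <- c(chain, node)
      nxt <- adj[[node]]
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      node <- nxt[1]
    }
    closed <- length(chain) > 2L && chain[1] %in% adj[[node]]
    pm <- do.call(rbind, lapply(keys[chain], function(k) pts[[k]]))
    contours[[length(contours) + 1L]] <- list(points = pm, closed = closed)
  }
  contours
}

## area and centroid of a closed planar polygon given in 3D
polygon_centroid3 <- function(points, normal) {
  n <- unit3(normal)
  e1 <- unit3(if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0)))
  e2 <- cross3(n, e1)
  x <- as.numeric(points %*% e1)
  y <- as.numeric(points %*% e2)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  area <- sum(cr) / 2
  if (abs(area) < 1e-9) return(list(area = 0, centroid = colMeans(points)))
  cx <- sum((x + x2) * cr) / (6 * area)
  cy <- sum((y + y2) * cr) / (6 * area)
  p0 <- colMeans(points)
  ## reconstruct 3D: centroid = cx*e1 + cy*e2 + (offset along n of the plane)
  off <- mean(as.numeric(points %*% n))
  list(area = abs(area), centroid = cx * e1 + cy * e2 + off * n)
}

#' Cross-section centroid of the tibial shaft
#'
#' Intersects the mesh with the plane at the given frame-z level and returns
#' the area centroid of the largest closed intersection contour. Open
#' contours fall back to the polyline vertex centroid with a warning.
#'
#' @param mesh an `hto_mesh`.
#' @param frame an `hto_frame`.
#' @param level signed distance along the frame z-axis from the origin (mm).
#' @return a length-3 point (world coordinates, mm).
#' @export
cross_section_centroid <- function(mesh, frame, level) {
  point <- frame$origin + level * frame$z_axis
  contours <- mesh_section(mesh, point, frame$z_axis)
  if (length(contours) == 0L)
    stop(sprintf("out-of-range error: plane z = %.2f does not intersect the mesh",
                 level), call. = FALSE)
  closed <- Filter(function(ct) ct$closed, contours)
  if (length(closed)) {
    stats <- lapply(closed, function(ct) polygon_centroid3(ct$points, frame$z_axis))
    best <- which.max(vapply(stats, function(s) s$area, 0))
    return(stats[[best]]$centroid)
  }
  warning(sprintf("open contour at z = %.2f; using polyline vertex centroid",
                  level), call. = FALSE)
  sizes <- vapply(contours, function(ct) nrow(ct$points), 0L)
  colMeans(contours[[which.max(sizes)]]$points)
}
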