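## Plan-vs-result evaluation: proximal best-fit registration, signed
## perpendicular surface deviations, tolerance bands (0.6 / 1.2 / 1.7 mm),
## specimen grading and cohort angle-deviation statistics.

#' Closest points on a mesh surface
#'
#' Exact closest point on the triangle surface for each query point.
#'
#' @param query n x 3 matrix of points (mm).
#' @param mesh an `hto_mesh`.
#' @return list with `points` (n x 3 closest surface points), `dist`
#'   (unsigned distances) and `face` (1-based face index).
#' @export
closest_points <- function(query, mesh) {
  if (!is.matrix(query)) query <- matrix(query, nrow = 1)
  storage.mode(query) <- "double"
  .cpp_closest_points(query, mesh$vertices, mesh$faces)
}

#' Crop a mesh above a frame-z level
#'
#' Keeps faces whose three vertices all have frame-z at or above `z_min`
#' (used to isolate the proximal region for registration).
#'
#' @param mesh an `hto_mesh`.
#' @param frame an `hto_frame`.
#' @param z_min level along the frame z-axis (mm, relative to the origin).
#' @return a cropped `hto_mesh`; the whole mesh if `z_min` is below it.
#' @export
crop_by_level <- function(mesh, frame, z_min) {
  zf <- frame_z(mesh$vertices, frame)
  keep_v <- zf >= z_min
  keep_f <- matrix(keep_v[mesh$faces], ncol = 3)
  faces <- mesh$faces[rowSums(keep_f) == 3L, , drop = FALSE]
  if (nrow(faces) == 0L)
    stop("range error: no faces at or above the crop level", call. = FALSE)
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3),
           scalar = mesh$scalar[used], merge_tol = 0)
}

## rigid least-squares fit (Kabsch) mapping P onto Q (n x 3 each)
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cq - as.numeric(R %*% cp))
}

#' Best-fit rigid registration (ICP)
#'
#' Aligns `moving` onto the surface of `fixed` by iterative closest-point
#' refinement from a centroid / principal-axes pre-alignment, minimizing the
#' mean squared point-to-surface distance.
#'
#' @param moving,fixed `hto_mesh` objects; `moving` may cover only part of
#'   `fixed` (e.g. a proximal crop against a full plan).
#' @param max_iter maximum ICP iterations.
#' @param tol convergence threshold on the RMS improvement (mm).
#' @param sample_n number of moving vertices used per iteration
#'   (deterministic subsample).
#' @return an `hto_transform` mapping `moving` onto `fixed`, with attributes
#'   `rms` (final RMS distance, mm), `iterations` and `converged`; a warning
#'   is raised when `max_iter` is hit without convergence.
#' @export
best_fit_register <- function(moving, fixed, max_iter = 100, tol = 1e-6,
                              sample_n = 1500) {
  vm <- moving$vertices
  idx <- if (nrow(vm) > sample_n)
    unique(round(seq(1, nrow(vm), length.out = sample_n))) else seq_len(nrow(vm))
  P <- vm[idx, , drop = FALSE]

  rms_of <- function(t) {
    q <- apply_transform(P, t)
    sqrt(mean(closest_points(q, fixed)$dist^2))
  }

  ## pre-alignment candidates: identity, centroid shift, centroid +
  ## principal axes (4 sign combinations with det +1); best RMS wins
  cm <- colMeans(vm); cf <- colMeans(fixed$vertices)
  cands <- list(transform_identity(),
                rigid_transform(diag(3), cf - cm))
  em <- eigen(stats::cov(vm), symmetric = TRUE)$vectors
  ef <- eigen(stats::cov(fixed$vertices), symmetric = TRUE)$vectors
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    Vm <- em %*% diag(c(s1, s2, 1))
    R <- ef %*% diag(c(1, 1, det(ef %*% t(Vm)))) %*% t(Vm)
    if (abs(det(R) - 1) < 1e-6)
      cands[[length(cands) + 1L]] <- rigid_transform(R, cf - as.numeric(R %*% cm))
  }
  rmss <- vapply(cands, rms_of, 0)
  t <- cands[[which.min(rmss)]]
  prev <- min(rmss)

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    q <- apply_transform(P, t)
    cp <- closest_points(q, fixed)
    t <- kabsch(P, cp$points)
    rms <- rms_of(t)
    if (prev - rms < tol) { converged <- TRUE; break }
    prev <- rms
  }
  if (!converged)
    warning(sprintf("best_fit_register did not converge in %d iterations (RMS %.4f mm)",
                    max_iter, rms), call. = FALSE)
  attr(t, "rms") <- rms
  attr(t, "iterations") <- it
  attr(t, "converged") <- converged
  t
}

#' Signed surface deviation of a realized against a planned anatomy
#'
#' Applies the registration (estimated on the common proximal region) to the
#' entire realized mesh, then computes for each realized vertex the signed
#' perpendicular distance to the closest point on the planned surface (sign
#' from the planned surface's outward normal: positive = outside the plan).
#'
#' @param realized,planned `hto_mesh` objects.
#' @param registration an `hto_transform` mapping realized onto planned
#'   (identity by default).
#' @return object of class `hto_deviation`: `distance` (signed mm per
#'   realized vertex), `mesh` (realized mesh, registered, with the distances
#'   as its scalar channel) and `registration`.
#' @export
surface_deviation <- function(realized, planned,
                              registration = transform_identity()) {
  if (!mesh_orientation_consistent(planned))
    stop("orientation error: planned mesh has inconsistently oriented faces",
         call. = FALSE)
  reg <- apply_transform(realized, registration)
  cp <- closest_points(reg$vertices, planned)
  n <- face_normals(planned)[cp$face, , drop = FALSE]
  sgn <- sign(rowSums((reg$vertices - cp$points) * n))
  sgn[sgn == 0] <- 1
  d <- sgn * cp$dist
  reg$scalar <- d
  structure(list(distance = d, mesh = reg, registration = registration),
            class = "hto_deviation")
}

#' @export
print.hto_deviation <- function(x, ...) {
  cat(sprintf("hto_deviation: %d vertices, |d| median %.3f / 95th %.3f / max %.3f mm\n",
              length(x$distance), stats::median(abs(x$distance)),
              stats::quantile(abs(x$distance), 0.95), max(abs(x$distance))))
  invisible(x)
}

HTO_BAND_LABELS <- c("very_good", "good", "acceptable", "unacceptable")

#' Classify a deviation map into tolerance bands
#'
#' Bands on absolute deviation, half-open: very good `[0, 0.6)`, good
#' `[0.6, 1.2)`, acceptable `[1.2, 1.7)`, unacceptable `[1.7, Inf)` mm.
#'
#' @param map an `hto_deviation` (or a numeric vector of signed distances).
#' @param edges band edges in mm.
#' @return object of class `hto_bands`: `fractions` (per band, summing to
#'   1), `worst_band` (band of the largest absolute deviation),
#'   `percentiles` (50th, 95th, max of absolute deviation) and `edges`.
#' @export
classify_bands <- function(map, edges = c(0.6, 1.2, 1.7)) {
  d <- if (inherits(map, "hto_deviation")) abs(map$distance) else abs(map)
  if (length(d) == 0L)
    stop("validation error: empty deviation map", call. = FALSE)
  stopifnot(length(edges) == 3L, !is.unsorted(edges))
  counts <- c(sum(d < edges[1]),
              sum(d >= edges[1] & d < edges[2]),
              sum(d >= edges[2] & d < edges[3]),
              sum(d >= edges[3]))
  fractions <- counts / length(d)
  names(fractions) <- HTO_BAND_LABELS
  pct <- c(p50 = unname(stats::quantile(d, 0.5, type = 7)),
           p95 = unname(stats::quantile(d, 0.95, type = 7)),
           max = max(d))
  structure(list(fractions = fractions,
                 worst_band = HTO_BAND_LABELS[findInterval(max(d), edges) + 1L],
                 percentiles = pct, edges = edges, n = length(d)),
            class = "hto_bands")
}

#' @export
print.hto_bands <- function(x, ...) {
  cat("hto_bands:", paste(sprintf("%s %.1f%%", names(x$fractions),
                                  100 * x$fractions), collapse = " | "), "\n")
  cat(sprintf("  |d| p50 %.3f / p95 %.3f / max %.3f mm -> grade %s\n",
              x$percentiles["p50"], x$percentiles["p95"], x$percentiles["max"],
              grade_specimen(x)))
  invisible(x)
}

#' Grade a specimen from its band summary
#'
#' The grade is the tolerance band containing the 95th percentile of the
#' absolute deviation (the per-specimen rule; the band scheme itself is the
#' 0.6 / 1.2 / 1.7 mm scale).
#'
#' @param summary an `hto_bands`.
#' @return one of `"very_good"`, `"good"`, `"acceptable"`, `"unacceptable"`.
#' @export
grade_specimen <- function(summary) {
  stopifnot(inherits(summary, "hto_bands"))
  HTO_BAND_LABELS[findInterval(summary$percentiles["p95"], summary$edges) + 1L]
}

#' Per-specimen absolute angle deviations
#'
#' @param planned,realized `hto_angles` objects.
#' @param id specimen identifier.
#' @return one-row data.frame: `specimen_id`, `mpta`, `medial_slope`,
#'   `lateral_slope`, `torsion` (absolute differences in degrees, 2
#'   decimals).
#' @export
angle_deviation_row <- function(planned, realized, id) {
  stopifnot(inherits(planned, "hto_angles"), inherits(realized, "hto_angles"))
  data.frame(specimen_id = id,
             mpta = round(abs(planned$mpta - realized$mpta), 2),
             medial_slope = round(abs(planned$medial_slope - realized$medial_slope), 2),
             lateral_slope = round(abs(planned$lateral_slope - realized$lateral_slope), 2),
             torsion = round(abs(planned$torsion - realized$torsion), 2))
}

#' Cohort summary of absolute angle deviations
#'
#' Arithmetic mean of the absolute per-specimen deviations and the sample
#' standard deviation (n - 1 denominator) per angle, reported to 2 decimals.
#'
#' @param rows data.frame of [angle_deviation_row()] rows (n >= 2).
#' @return list with `mean`, `sd` (named numeric, 2 decimals), `n` and the
#'   input `rows`.
#' @export
summarize_deviations <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) < 2L)
    stop("insufficient-data error: need at least 2 specimens for an SD",
         call. = FALSE)
  cols <- c("mpta", "medial_slope", "lateral_slope", "torsion")
  m <- round(vapply(rows[cols], mean, 0), 2)
  s <- round(vapply(rows[cols], stats::sd, 0), 2)
  list(mean = m, sd = s, n = nrow(rows), rows = rows)
}

#' Histogram of a deviation map with band coloring
#'
#' @param x an `hto_deviation`.
#' @param edges band edges in mm.
#' @param ... passed to [graphics::hist()].
#' @export
plot.hto_deviation <- function(x, edges = c(0.6, 1.2, 1.7), ...) {
  graphics::hist(x$distance, breaks = 50, col = "grey80", border = NA,
                 main = "surface deviation", xlab = "signed deviation [mm]", ...)
  graphics::abline(v = c(-rev(edges), edges),
                   col = rep(c("red", "orange", "gold"), 2)[c(3, 2, 1, 1, 2, 3)],
                   lty = 2)
  invisible(x)
}

#' Export a deviation map
#'
#' Writes a PLY with the signed distance as the per-vertex scalar and a CSV
#' (`vertex_id`, `d_mm`, `band`).
#'
#' @param dev an `hto_deviation`.
#' @param ply_path,csv_path output paths (NULL to skip either).
#' @param edges band edges in mm.
#' @export
write_deviation_map <- function(dev, ply_path = NULL, csv_path = NULL,
                                edges = c(0.6, 1.2, 1.7)) {
  if (!is.null(ply_path)) write_surface_mesh(dev$mesh, ply_path, "ply")
  if (!is.null(csv_path)) {
    band <- HTO_BAND_LABELS[findInterval(abs(dev$distance), edges) + 1L]
    utils::write.csv(data.frame(vertex_id = seq_along(dev$distance),
                                d_mm = dev$distance, band = band),
                     csv_path, row.names = FALSE)
  }
  invisible(dev)
}
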