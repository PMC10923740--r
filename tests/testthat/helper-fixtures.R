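# Fixtures are generated in code: small meshes with known geometry, a cached
# default phantom, and an independent brute-force closest-point oracle.

.fixture_cache <- new.env(parent = emptyenv())

# unit tetrahedron: the smallest closed mesh
make_tetra_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# closed (elliptical) cylinder along z from z0 to z1, axis through (cx, cy)
make_cylinder_mesh <- function(a = 10, b = a, z0 = 0, z1 = 100,
                               cx = 0, cy = 0, n = 48, nz = 20,
                               shear_x = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  zs <- seq(z0, z1, length.out = nz)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(cx + a * cos(th) + shear_x * (z - z0),
          cy + b * sin(th), z)))
  jn <- c(2:n, 1)
  faces <- do.call(rbind, lapply(seq_len(nz - 1), function(k) {
    base <- (k - 1) * n
    rbind(cbind(base + 1:n, base + jn, base + n + jn),
          cbind(base + 1:n, base + n + jn, base + n + 1:n))
  }))
  # cap with fans
  c0 <- nrow(verts) + 1L
  verts <- rbind(verts, c(cx, cy, z0), c(cx + shear_x * (z1 - z0), cy, z1))
  faces <- rbind(faces,
                 cbind(1:n, c0, jn),
                 cbind((nz - 1) * n + 1:n, (nz - 1) * n + jn, c0 + 1L))
  m <- tri_mesh(verts, faces, merge_tol = 0)
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# cached default phantom (mesh generation is deterministic)
default_specimen <- function() {
  if (is.null(.fixture_cache$spec))
    .fixture_cache$spec <- generate_tibia()
  .fixture_cache$spec
}

small_specimen <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_tibia(
      synthetic_tibia_params(..., mesh_resolution = c(32, 80)))
  .fixture_cache[[key]]
}

# executed default osteotomy (gap 8) plus planned composite mesh, cached
default_osteotomy <- function() {
  if (is.null(.fixture_cache$osteo)) {
    spec <- default_specimen()
    frame <- build_frame(spec$landmarks)
    plan <- plan_hto(spec$mesh, spec$landmarks, frame)
    res <- execute_hto(spec$mesh, spec$landmarks, plan)
    planned <- hto3d:::concat_meshes(res$proximal_fragment, res$distal_fragment)
    .fixture_cache$osteo <- list(spec = spec, frame = frame, plan = plan,
                                 res = res, planned = planned)
  }
  .fixture_cache$osteo
}

# independent brute-force closest point on a triangle mesh (barycentric
# clamping, plain R) — the oracle for the C++ kernel
bf_closest <- function(q, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  best <- Inf; bp <- NULL
  for (i in seq_len(nrow(f))) {
    A <- v[f[i, 1], ]; B <- v[f[i, 2], ]; C <- v[f[i, 3], ]
    E0 <- B - A; E1 <- C - A; D <- A - q
    a <- sum(E0 * E0); b <- sum(E0 * E1); c <- sum(E1 * E1)
    d <- sum(E0 * D); e <- sum(E1 * D)
    det <- a * c - b * b
    s <- b * e - c * d; t <- b * d - a * e
    if (s + t <= det) {
      if (s < 0) {
        if (t < 0) { # region 4
          if (d < 0) { t <- 0; s <- min(1, max(0, -d / a)) }
          else { s <- 0; t <- min(1, max(0, -e / c)) }
        } else { s <- 0; t <- min(1, max(0, -e / c)) }
      } else if (t < 0) { t <- 0; s <- min(1, max(0, -d / a)) }
      else { inv <- 1 / det; s <- s * inv; t <- t * inv }
    } else {
      if (s < 0) {
        tmp0 <- b + d; tmp1 <- c + e
        if (tmp1 > tmp0) {
          num <- tmp1 - tmp0
          s <- min(1, max(0, num / (a - 2 * b + c))); t <- 1 - s
        } else { s <- 0; t <- min(1, max(0, -e / c)) }
      } else if (t < 0) {
        tmp0 <- b + e; tmp1 <- a + d
        if (tmp1 > tmp0) {
          num <- tmp1 - tmp0
          t <- min(1, max(0, num / (a - 2 * b + c))); s <- 1 - t
        } else { t <- 0; s <- min(1, max(0, -d / a)) }
      } else {
        num <- (c + e) - (b + d)
        s <- min(1, max(0, num / (a - 2 * b + c))); t <- 1 - s
      }
    }
    p <- A + s * E0 + t * E1
    dd <- sqrt(sum((q - p)^2))
    if (dd < best) { best <- dd; bp <- p }
  }
  list(dist = best, point = bp)
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  t <- rotation_about_axis(rnorm(3, sd = 20), ax, runif(1, 10, 170))
  t$translation <- t$translation + rnorm(3, sd = 50)
  t
}

# the published per-tibia plan-vs-result absolute angle deviations (deg)
published_deviation_rows <- function() {
  data.frame(
    specimen_id = sprintf("tibia_%02d", 1:13),
    mpta = c(0.25, 0.46, 0.83, 0.28, 0.94, 0.85, 0.14, 0.85, 0.41, 0.31,
             0.84, 0.78, 0.63),
    medial_slope = c(1.42, 0.45, 0.97, 1.97, 0.4, 0.79, 1.19, 0.79, 0.98,
                     0.37, 1.69, 1.39, 0.35),
    lateral_slope = c(3.03, 0.89, 0.95, 0.02, 1.39, 0.61, 1.44, 0.61, 2.2,
                      0.63, 1.88, 1.52, 1.27),
    torsion = c(6.18, 6.81, 3.12, 5.64, 4.62, 5.66, 12.67, 4.89, 1.16,
                11.63, 2.84, 5.52, 3.91))
}
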