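test_that("crop_by_level keeps exactly the faces above the level", {
  f <- structure(list(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                      y_axis = c(0, 1, 0), z_axis = c(0, 0, 1),
                      side = "RIGHT"), class = "hto_frame")
  cyl <- make_cylinder_mesh(a = 10, z0 = 0, z1 = 100)
  whole <- crop_by_level(cyl, f, -10)
  expect_equal(nrow(whole$faces), nrow(cyl$faces))
  expect_error(crop_by_level(cyl, f, 200), "range error")
  half <- crop_by_level(cyl, f, 50)
  expect_true(all(half$vertices[, 3] >= 50))
  expect_equal(nrow(half$faces) / nrow(cyl$faces), 0.5, tolerance = 0.1)
})

test_that("registration recovers identity and known small perturbations", {
  ost <- default_osteotomy()
  planned <- ost$planned
  reg0 <- suppressWarnings(best_fit_register(planned, planned))
  expect_lt(attr(reg0, "rms"), 1e-6)
  rot_ang <- function(t) acos(pmin(1, (sum(diag(t$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(rot_ang(reg0), 1e-4)

  pert <- rotation_about_axis(c(0, 0, -50), c(0.3, 0.9, 0.3), 2)
  pert$translation <- pert$translation + c(2, 1, -2)
  mv <- apply_transform(planned, pert)
  reg <- suppressWarnings(best_fit_register(mv, planned))
  comp <- transform_compose(reg, pert)
  expect_lt(rot_ang(comp), 0.05)
  expect_lt(sqrt(sum(comp$translation^2)), 0.05)

  ## partial overlap: proximal crop against the full plan
  z_prox <- max(hto3d:::frame_z(ost$spec$landmarks$positions, ost$frame))
  prox <- crop_by_level(planned, ost$frame, z_prox - 60)
  mv2 <- apply_transform(prox, pert)
  reg2 <- suppressWarnings(best_fit_register(mv2, planned))
  comp2 <- transform_compose(reg2, pert)
  expect_lt(rot_ang(comp2), 0.1)
  expect_lt(sqrt(sum(comp2$translation^2)), 0.1)
})

test_that("surface deviation is exact for identical and offset surfaces", {
  m <- small_specimen()$mesh
  dev0 <- surface_deviation(m, m)
  expect_lt(max(abs(dev0$distance)), 1e-6)

  ## flat slab offset outward along its normal by 1 mm
  g <- expand.grid(x = seq(0, 40, by = 4), y = seq(0, 40, by = 4))
  nv <- nrow(g); nx <- 11
  fc <- do.call(rbind, lapply(seq_len(nx - 1), function(i)
    do.call(rbind, lapply(seq_len(nx - 1), function(j) {
      a <- (j - 1) * nx + i
      rbind(c(a, a + 1, a + nx + 1), c(a, a + nx + 1, a + nx))
    }))))
  slab <- tri_mesh(cbind(g$x, g$y, 0), fc, merge_tol = 0)
  nrm <- hto3d:::face_normals(slab)[1, ]
  moved <- slab
  moved$vertices <- sweep(moved$vertices, 2, -nrm)   # +1 along the normal
  dev1 <- surface_deviation(moved, slab)
  expect_equal(unname(dev1$distance), rep(1, nv), tolerance = 1e-3)
})

test_that("the C++ closest-point kernel matches a brute-force oracle", {
  mesh <- make_cylinder_mesh(a = 15, b = 9, z0 = 0, z1 = 40, n = 16, nz = 8)
  expect_lte(nrow(mesh$faces), 500)
  set.seed(31)
  q <- cbind(runif(40, -30, 30), runif(40, -30, 30), runif(40, -20, 60))
  fast <- closest_points(q, mesh)
  for (i in seq_len(nrow(q))) {
    slow <- bf_closest(q[i, ], mesh)
    expect_lt(abs(fast$dist[i] - slow$dist), 1e-9)
  }
})

test_that("band classification matches analytic bin masses", {
  b0 <- classify_bands(rep(0, 10))
  expect_equal(unname(b0$fractions["very_good"]), 1)
  expect_equal(sum(b0$fractions), 1, tolerance = 1e-9)

  b1 <- classify_bands(c(0.5, 0.9, 1.5, 2.0))
  expect_equal(unname(b1$fractions), c(0.25, 0.25, 0.25, 0.25))
  expect_identical(b1$worst_band, "unacceptable")

  set.seed(7)
  u <- runif(1e5, 0, 2)
  bu <- classify_bands(u)
  expect_equal(unname(bu$fractions["very_good"]), 0.3, tolerance = 0.01)
  expect_equal(unname(bu$fractions["good"]), 0.3, tolerance = 0.01)
})

test_that("grading follows the 95th percentile band and is monotone in error", {
  expect_identical(grade_specimen(classify_bands(runif(100, 0, 0.5))),
                   "very_good")
  expect_identical(grade_specimen(classify_bands(rep(1.0, 100))), "good")

  ost <- default_osteotomy()
  ideal <- simulate_surgical_error(ost$res, error_model())
  under <- simulate_surgical_error(ost$res,
                                   error_model(opening_angle_scale = 0.7))
  g_ideal <- grade_specimen(classify_bands(
    surface_deviation(ideal$mesh, ost$planned)))
  g_under <- grade_specimen(classify_bands(
    surface_deviation(under$mesh, ost$planned)))
  expect_identical(g_ideal, "very_good")
  expect_gt(match(g_under, hto3d:::HTO_BAND_LABELS),
            match(g_ideal, hto3d:::HTO_BAND_LABELS))
})

test_that("angle deviation rows report absolute symmetric differences", {
  a <- tibial_angles(87, 8, 7, 35)
  expect_true(all(angle_deviation_row(a, a, "s")[, -1] == 0))
  b <- tibial_angles(87.25, 8, 7, 35)
  expect_equal(angle_deviation_row(a, b, "t1")$mpta, 0.25)
  r1 <- angle_deviation_row(a, b, "x"); r2 <- angle_deviation_row(b, a, "x")
  expect_identical(r1, r2)
})

test_that("cohort summaries reproduce the published worked example", {
  rows <- published_deviation_rows()
  s <- summarize_deviations(rows)
  expect_identical(unname(s$mean["medial_slope"]), 0.98)
  expect_identical(unname(s$sd["medial_slope"]), 0.53)
  expect_identical(unname(s$mean["torsion"]), 5.74)
  expect_identical(unname(s$sd["torsion"]), 3.24)
  const <- rows; const[, -1] <- 1
  expect_true(all(summarize_deviations(const)$sd == 0))
  expect_error(summarize_deviations(rows[1, ]), "insufficient-data")
})

test_that("a perfectly executed plan evaluates to a null deviation", {
  ost <- default_osteotomy()
  real <- simulate_surgical_error(ost$res, error_model())
  z_prox <- max(hto3d:::frame_z(ost$spec$landmarks$positions, ost$frame))
  prox <- crop_by_level(real$mesh, ost$frame, z_prox - 60)
  reg <- suppressWarnings(best_fit_register(prox, ost$planned))
  dev <- surface_deviation(real$mesh, ost$planned, reg)
  expect_lt(max(abs(dev$distance)), 0.05)
  expect_identical(grade_specimen(classify_bands(dev)), "very_good")
  a_p <- measure_angles(ost$planned, ost$res$realized_landmarks)
  a_r <- measure_angles(real$mesh, real$landmarks)
  expect_true(all(angle_deviation_row(a_p, a_r, "null")[, -1] < 0.1))
})

test_that("reducing the opening angle shifts the MPTA deviation accordingly", {
  ost <- default_osteotomy()
  s <- 0.75
  delta <- (1 - s) * ost$plan$opening_angle
  real <- simulate_surgical_error(ost$res,
                                  error_model(opening_angle_scale = s))
  a_p <- measure_angles(ost$planned, ost$res$realized_landmarks)
  a_r <- measure_angles(real$mesh, real$landmarks)
  row <- angle_deviation_row(a_p, a_r, "under")
  expect_lt(abs(row$mpta - delta), 0.1)
})
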