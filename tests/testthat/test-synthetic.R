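test_that("generation is deterministic and landmarks lie on the surface", {
  p <- synthetic_tibia_params(mesh_resolution = c(32, 80))
  s1 <- generate_tibia(p); s2 <- generate_tibia(p)
  expect_identical(s1$mesh$vertices, s2$mesh$vertices)
  expect_identical(s1$mesh$faces, s2$mesh$faces)
  expect_identical(s1$landmarks$positions, s2$landmarks$positions)
  d <- closest_points(s1$landmarks$positions, s1$mesh)$dist
  expect_lt(max(d), 0.5)
  ## watertight and outward-oriented
  expect_true(hto3d:::mesh_orientation_consistent(s1$mesh))
  expect_gt(hto3d:::mesh_signed_volume(s1$mesh), 0)
})

test_that("ground truth recovery holds over a parameter grid", {
  for (mp in c(82, 87, 93)) for (sl in c(2, 8, 14)) for (tor in c(22, 35, 48)) {
    s <- generate_tibia(synthetic_tibia_params(
      target_mpta = mp, target_medial_slope = sl,
      target_lateral_slope = max(1, sl - 1), target_torsion = tor,
      mesh_resolution = c(32, 80)))
    a <- measure_angles(s$mesh, s$landmarks)
    expect_lt(abs(a$mpta - mp), 0.2)
    expect_lt(abs(a$medial_slope - sl), 0.2)
    expect_lt(abs(a$torsion - tor), 0.2)
  }
})

test_that("doubling the mesh resolution barely moves the measured angles", {
  a1 <- measure_angles(small_specimen()$mesh, small_specimen()$landmarks)
  hi <- generate_tibia(synthetic_tibia_params(mesh_resolution = c(64, 160)))
  a2 <- measure_angles(hi$mesh, hi$landmarks)
  for (nm in c("mpta", "medial_slope", "lateral_slope", "torsion"))
    expect_lt(abs(a1[[nm]] - a2[[nm]]), 0.05)
})

test_that("infeasible parameters are rejected", {
  expect_error(synthetic_tibia_params(target_mpta = 140), "infeasible")
  expect_error(synthetic_tibia_params(total_length = -1), "positive")
  expect_error(synthetic_tibia_params(mesh_resolution = c(12, 30)),
               "mesh_resolution")
})

test_that("the identity error model reproduces the ideal execution", {
  ost <- default_osteotomy()
  real <- simulate_surgical_error(ost$res, error_model())
  dev <- surface_deviation(real$mesh, ost$planned)
  expect_lt(max(abs(dev$distance)), 0.05)
})

test_that("scaling the opening angle rescales the realized gap linearly", {
  ost <- default_osteotomy()
  real <- simulate_surgical_error(ost$res,
                                  error_model(opening_angle_scale = 0.7))
  mp <- ost$plan$medial_point
  gap <- abs(hto3d:::frame_z(apply_transform(mp, real$transform), ost$frame) -
               hto3d:::frame_z(mp, ost$frame))
  expect_lt(abs(gap - 0.7 * 8), 0.1)
  a <- measure_angles(real$mesh, real$landmarks)
  a_p <- measure_angles(ost$planned, ost$res$realized_landmarks)
  expect_lt(abs((a_p$mpta - a$mpta) - 0.3 * ost$plan$opening_angle), 0.1)
})

test_that("landmark jitter is reproducible and honest about sigma", {
  lms <- default_specimen()$landmarks
  expect_identical(jitter_landmarks(lms, 0), lms)
  j1 <- jitter_landmarks(lms, 2, seed = 42)
  j2 <- jitter_landmarks(lms, 2, seed = 42)
  expect_identical(j1$positions, j2$positions)
  j3 <- jitter_landmarks(lms, 2, seed = 43)
  expect_false(identical(j1$positions, j3$positions))
  ## displacement scale matches sigma (chi distribution, 12 x 3 draws)
  disp <- sqrt(rowSums((j1$positions - lms$positions)^2))
  expect_lt(max(disp), 2 * 5)
  expect_gt(mean(disp), 0.5)
})

test_that("a two-observer protocol yields comparable per-angle differences", {
  spec <- default_specimen()
  frame <- build_frame(spec$landmarks)
  axis <- anatomical_axis(spec$mesh, frame, spec$landmarks)
  obs <- lapply(c(1, 2), function(o) {
    lj <- jitter_landmarks(spec$landmarks, 2, seed = 800 + o)
    hto3d:::angles_from_axis(lj, build_frame(lj), axis)
  })
  row <- angle_deviation_row(obs[[1]], obs[[2]], "observers")
  expect_true(all(is.finite(as.numeric(row[, -1]))))
  expect_true(all(row[, -1] >= 0))
})
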