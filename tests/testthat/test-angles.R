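world_frame <- function(side = "RIGHT") {
  structure(list(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                 y_axis = c(0, 1, 0), z_axis = c(0, 0, 1), side = side),
            class = "hto_frame")
}
z_axis_line <- function() {
  structure(list(point = c(0, 0, -100), direction = c(0, 0, 1)),
            class = "hto_axis")
}

test_that("cross-section centroids recover cylinder axes", {
  f <- world_frame()
  cyl <- make_cylinder_mesh(a = 10, z0 = -100, z1 = 0)
  expect_equal(cross_section_centroid(cyl, f, -50), c(0, 0, -50),
               tolerance = 1e-3)
  cyl2 <- make_cylinder_mesh(a = 10, z0 = -100, z1 = 0, cx = 5, cy = -3)
  expect_equal(cross_section_centroid(cyl2, f, -50), c(5, -3, -50),
               tolerance = 1e-3)
  ell <- make_cylinder_mesh(a = 20, b = 10, z0 = -100, z1 = 0)
  expect_equal(cross_section_centroid(ell, f, -30), c(0, 0, -30),
               tolerance = 1e-3)
  expect_error(cross_section_centroid(cyl, f, 50), "out-of-range")
})

test_that("the anatomical axis recovers straight and sheared shafts", {
  spec <- default_specimen()
  frame <- build_frame(spec$landmarks)
  ## the canonical phantom's true shaft axis is the world z-axis
  ax <- anatomical_axis(spec$mesh, frame, spec$landmarks)
  expect_lt(acos(min(1, ax$direction[3])) * 180 / pi, 0.05)

  ## shear the shaft 5 deg in the coronal plane below the plateau
  sheared <- spec$mesh
  shift <- pmin(0, sheared$vertices[, 3] + 20) * tan(5 * pi / 180)
  sheared$vertices[, 1] <- sheared$vertices[, 1] + shift
  ax2 <- anatomical_axis(sheared, frame, spec$landmarks)
  tilt <- acos(min(1, ax2$direction[3])) * 180 / pi
  expect_lt(abs(tilt - 5), 0.1)
})

test_that("orthogonal configurations give the textbook angles", {
  f <- world_frame()
  ax <- z_axis_line()
  lms <- landmark_set("RIGHT", rbind(
    MMPP = c(-40, 0, 0), MLPP = c(40, 0, 0),
    TMCA = c(-20, 15, 0), TMCP = c(-20, -15, 0),
    TLCA = c(20, 15, 0), TLCP = c(20, -15, 0),
    PMC = c(-20, -20, 0), PLC = c(20, -20, 0),
    IFT = c(15, -15, -300), MMAL = c(-25, -15, -300),
    TKC = c(0, 0, 0), TTV = c(0, 25, -40)))
  expect_equal(compute_mpta(lms, ax, f), 90, tolerance = 1e-9)
  expect_equal(compute_slope(lms, ax, "MEDIAL"), 0, tolerance = 1e-9)
  expect_equal(compute_slope(lms, ax, "LATERAL"), 0, tolerance = 1e-9)
  ## distal line parallel to the dorsal tangent in projection
  expect_equal(compute_torsion(lms, f), 0, tolerance = 1e-9)
})

test_that("generator ground truth is recovered within 0.2 degrees", {
  spec <- default_specimen()
  a <- measure_angles(spec$mesh, spec$landmarks)
  expect_lt(abs(a$mpta - spec$angles$mpta), 0.2)
  expect_lt(abs(a$medial_slope - spec$angles$medial_slope), 0.2)
  expect_lt(abs(a$lateral_slope - spec$angles$lateral_slope), 0.2)
  expect_lt(abs(a$torsion - spec$angles$torsion), 0.2)
})

test_that("angles are pose invariant and side normalized", {
  spec <- default_specimen()
  a0 <- measure_angles(spec$mesh, spec$landmarks)
  for (seed in c(3, 17)) {
    t <- random_rigid(seed)
    a1 <- measure_angles(apply_transform(spec$mesh, t),
                         apply_transform(spec$landmarks, t))
    for (nm in c("mpta", "medial_slope", "lateral_slope", "torsion"))
      expect_lt(abs(a1[[nm]] - a0[[nm]]), 1e-6)
  }
  ## mirrored LEFT specimen reports identical angle values
  left <- generate_tibia(synthetic_tibia_params(side = "LEFT",
                                                mesh_resolution = c(32, 80)))
  aL <- measure_angles(left$mesh, left$landmarks)
  right <- small_specimen()
  aR <- measure_angles(right$mesh, right$landmarks)
  for (nm in c("mpta", "medial_slope", "lateral_slope", "torsion"))
    expect_lt(abs(aL[[nm]] - aR[[nm]]), 1e-6)
})

test_that("measured MPTA responds monotonically to the generator target", {
  vals <- vapply(c(84, 87, 90), function(mp) {
    s <- small_specimen(target_mpta = mp)
    measure_angles(s$mesh, s$landmarks)$mpta
  }, 0)
  expect_true(all(diff(vals) > 2))
})

test_that("under equal landmark jitter torsion is the least reliable angle", {
  spec <- default_specimen()
  frame <- build_frame(spec$landmarks)
  axis <- anatomical_axis(spec$mesh, frame, spec$landmarks)
  draws <- vapply(1:100, function(s) {
    lj <- jitter_landmarks(spec$landmarks, 2, seed = 4000 + s)
    aj <- hto3d:::angles_from_axis(lj, build_frame(lj), axis)
    c(aj$mpta, aj$medial_slope, aj$lateral_slope, aj$torsion)
  }, numeric(4))
  sds <- apply(draws, 1, sd)
  expect_gt(sds[4], sds[1])            # torsion noisier than MPTA
  expect_gt(sds[4], max(sds[1:3]))     # torsion noisiest overall
})
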