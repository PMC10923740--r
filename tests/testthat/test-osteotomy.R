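## planar toy plan: hinge axis along world y through the origin, world frame
toy_plan <- function(hinge = c(0, 0, 0)) {
  structure(list(hinge_point = hinge, hinge_direction = c(0, 1, 0),
                 frame = structure(list(origin = c(0, 0, 0),
                                        x_axis = c(1, 0, 0),
                                        y_axis = c(0, 1, 0),
                                        z_axis = c(0, 0, 1), side = "RIGHT"),
                                   class = "hto_frame")),
            class = "hto_plan")
}

test_that("the opening angle solver matches a brute-force 1-D scan", {
  plan <- toy_plan()
  mp <- c(-70, 0, 0)
  theta <- as.numeric(solve_opening_angle(plan, mp, 8))
  ## oracle: scan theta in 0.001 deg steps for |dz| = 8 with dz = 70 sin(t)
  grid <- seq(0, 30, by = 0.001)
  oracle <- grid[which.min(abs(70 * sin(grid * pi / 180) - 8))]
  expect_lt(abs(theta - oracle), 2e-3)
  ## gap -> 0 limit
  expect_lt(as.numeric(solve_opening_angle(plan, mp, 1e-6)), 1e-4)
  ## doubling the lever approximately halves the angle (small-angle regime)
  theta2 <- as.numeric(solve_opening_angle(plan, c(-140, 0, 0), 8))
  expect_equal(theta2 / theta, 0.5, tolerance = 0.05)
  ## medial point on the hinge axis is degenerate
  expect_error(solve_opening_angle(plan, c(0, 5, 0), 8), "geometry error")
})

test_that("the plan realizes the published geometric constants", {
  ost <- default_osteotomy()
  plan <- ost$plan; frame <- ost$frame; spec <- ost$spec
  W <- sqrt(sum((hto3d:::lm_get(spec$landmarks, "MMPP") -
                   hto3d:::lm_get(spec$landmarks, "MLPP"))^2))
  ## medial entry: W/2 distal (frame z) to the medial plateau
  dz <- hto3d:::frame_z(hto3d:::lm_get(spec$landmarks, "MMPP"), frame) -
    hto3d:::frame_z(plan$medial_entry, frame)
  expect_lt(abs(dz - W / 2), 1e-6)
  ## entry lies on the cortex
  expect_lt(closest_points(plan$medial_entry, spec$mesh)$dist, 1e-6)
  ## lateral aim point 15 mm distal to the lateral plateau
  expect_equal(hto3d:::frame_z(hto3d:::lm_get(spec$landmarks, "MLPP"), frame) -
                 hto3d:::frame_z(plan$aim_point, frame), 15, tolerance = 1e-9)
  ## hinge on the lateral cortex, bridge 15 mm in-plane
  expect_lt(closest_points(plan$hinge_point, spec$mesh)$dist, 1)
  expect_equal(sqrt(sum((plan$hinge_point - plan$cut_end)^2)), 15,
               tolerance = 1e-9)
  ## main cut contains the medial slope direction
  v_slope <- hto3d:::unit3(hto3d:::lm_get(spec$landmarks, "TMCP") -
                             hto3d:::lm_get(spec$landmarks, "TMCA"))
  expect_lt(abs(sum(v_slope * plan$main_cut$normal)), 1e-9)
  expect_error(plan_hto(spec$mesh, spec$landmarks, frame, gap_target = 0),
               "precondition")
})

test_that("executed osteotomies conserve the prescribed gap across targets", {
  spec <- default_specimen()
  frame <- build_frame(spec$landmarks)
  for (g in c(4, 6, 8, 10, 12)) {
    plan <- plan_hto(spec$mesh, spec$landmarks, frame, gap_target = g)
    res <- execute_hto(spec$mesh, spec$landmarks, plan)
    expect_lt(abs(res$gap_measured - g), 0.05)
  }
})

test_that("an ideal hinge changes only the MPTA", {
  ost <- default_osteotomy()
  a0 <- default_specimen()$angles
  a1 <- measure_angles(ost$planned, ost$res$realized_landmarks)
  expect_lt(abs((a1$mpta - a0$mpta) - ost$plan$opening_angle), 0.1)
  expect_lt(abs(a1$medial_slope - a0$medial_slope), 0.2)
  expect_lt(abs(a1$lateral_slope - a0$lateral_slope), 0.2)
  expect_lt(abs(a1$torsion - a0$torsion), 0.2)
})

test_that("a zero opening reassembles the original bone", {
  ost <- default_osteotomy()
  plan0 <- ost$plan
  plan0$opening_angle <- 0
  res0 <- execute_hto(ost$spec$mesh, ost$spec$landmarks, plan0)
  whole <- hto3d:::concat_meshes(res0$proximal_fragment, res0$distal_fragment)
  ## every reassembled vertex lies on the original surface
  expect_lt(max(closest_points(whole$vertices, ost$spec$mesh)$dist), 1e-9)
  a0 <- measure_angles(ost$spec$mesh, ost$spec$landmarks)
  a1 <- measure_angles(whole, res0$realized_landmarks)
  for (nm in c("mpta", "medial_slope", "lateral_slope", "torsion"))
    expect_lt(abs(a1[[nm]] - a0[[nm]]), 1e-6)
})

test_that("landmarks ride with the correct fragment", {
  ost <- default_osteotomy()
  t <- ost$res$fragment_transform
  src <- ost$spec$landmarks
  out <- ost$res$realized_landmarks
  expect_equal(out$positions["TKC", ], src$positions["TKC", ])
  expect_equal(out$positions["MMPP", ], src$positions["MMPP", ])
  expect_equal(out$positions["MMAL", ],
               apply_transform(src$positions["MMAL", ], t), tolerance = 1e-12)
  ## tuberosity flange (anterior of the ascending cut) moves distally
  expect_equal(out$positions["TTV", ],
               apply_transform(src$positions["TTV", ], t), tolerance = 1e-12)
  expect_true(all(c("MMAL", "TTV", "IFT") %in% attr(out, "moved")))
  expect_false("TKC" %in% attr(out, "moved"))
})

test_that("a posterolaterally tilted hinge couples into the slope", {
  ost <- default_osteotomy()
  real <- simulate_surgical_error(ost$res, error_model(hinge_tilt_axial = 20))
  a <- measure_angles(real$mesh, real$landmarks)
  a_plan <- measure_angles(ost$planned, ost$res$realized_landmarks)
  expect_gt(abs(a$medial_slope - a_plan$medial_slope), 0.5)
})

test_that("the moved fragment is rigid", {
  ost <- default_osteotomy()
  t <- ost$res$fragment_transform
  moved <- ost$res$distal_fragment$vertices
  orig <- apply_transform(moved, transform_invert(t))
  set.seed(5)
  idx <- sample(nrow(moved), 40)
  d0 <- dist(orig[idx, ]); d1 <- dist(moved[idx, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})
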