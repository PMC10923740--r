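test_that("binary STL of a tetrahedron has the canonical layout and re-reads", {
  m <- make_tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_surface_mesh(m, path, "stl-binary")
  expect_identical(file.info(path)$size, 84 + 4 * 50)
  r <- read_surface_mesh(path)
  expect_equal(nrow(r$vertices), 4L)   # soup merged back to 4 vertices
  expect_equal(nrow(r$faces), 4L)
})

test_that("ASCII and binary STL dialects read identically", {
  m <- make_tetra_mesh()
  pb <- withr::local_tempfile(fileext = ".stl")
  pa <- withr::local_tempfile(fileext = ".stl")
  write_surface_mesh(m, pb, "stl-binary")
  write_surface_mesh(m, pa, "stl-ascii")
  rb <- read_surface_mesh(pb)
  ra <- read_surface_mesh(pa)
  expect_equal(ra$vertices, rb$vertices, tolerance = 1e-6)
  expect_identical(ra$faces, rb$faces)
})

test_that("a synthetic tibia survives an STL round-trip within format precision", {
  mesh <- small_specimen()$mesh
  ## ASCII STL carries 9 significant digits: 1e-5 mm on a 360 mm bone;
  ## binary STL stores float32, whose half-ulp at 360 mm is 1.6e-5 mm
  tol <- c("stl-ascii" = 1e-5, "stl-binary" = 1.6e-5)
  for (fmt in names(tol)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_surface_mesh(mesh, path, fmt)
    r <- read_surface_mesh(path)
    ## STL stores a triangle soup; compare via per-face corner coordinates
    orig <- mesh$vertices[t(mesh$faces), ]
    back <- r$vertices[t(r$faces), ]
    expect_equal(dim(back), dim(orig))
    expect_lt(max(abs(back - orig)), tol[[fmt]])
  }
  ## PLY round-trips at full double precision of its 9-digit output
  pp <- withr::local_tempfile(fileext = ".ply")
  write_surface_mesh(mesh, pp, "ply")
  rp <- read_surface_mesh(pp)
  expect_lt(max(abs(rp$vertices - mesh$vertices)), 1e-5)
})

test_that("PLY carries the per-vertex scalar channel through a round-trip", {
  m <- make_tetra_mesh()
  m$scalar <- c(-1.25, 0, 0.5, 2.75)
  path <- withr::local_tempfile(fileext = ".ply")
  write_surface_mesh(m, path, "ply")
  r <- read_surface_mesh(path)
  expect_equal(r$scalar, m$scalar, tolerance = 1e-6)
  expect_equal(r$vertices, m$vertices, tolerance = 1e-6)
})

test_that("truncated binary STL raises a format error naming the byte offset", {
  m <- make_tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_surface_mesh(m, path, "stl-binary")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(raw[1:150], path)
  expect_error(read_surface_mesh(path), "byte 150")
})

test_that("degenerate meshes are rejected at construction", {
  expect_error(tri_mesh(matrix(0, 4, 3), rbind(c(1, 2, 3))), "validation")
  expect_error(tri_mesh(diag(3), matrix(integer(0), 0, 3)), "no faces")
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(tri_mesh(v, rbind(c(1, 2, 5))), "out of range")
})

test_that("landmark JSON round-trips and flags unknown or missing names", {
  spec <- small_specimen()
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(spec$landmarks, path)
  r <- read_landmarks(path)
  expect_identical(r$side, spec$landmarks$side)
  expect_equal(r$positions[rownames(spec$landmarks$positions), ],
               spec$landmarks$positions, tolerance = 1e-12)

  pos <- spec$landmarks$positions
  rownames(pos)[rownames(pos) == "IFT"] <- "XXX"
  expect_warning(ls2 <- landmark_set("RIGHT", pos), "XXX")
  expect_error(compute_torsion(ls2, build_frame(ls2)), "IFT")
  expect_error(read_landmarks(withr::local_tempfile(fileext = ".json")), "no such file")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_landmarks(bad), "format error")
})
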