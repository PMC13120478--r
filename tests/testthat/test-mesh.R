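test_that("grid planning snaps ideal cuts to the lattice", {
  roi <- roi_frame(c(0, 8, 0, 8), c(3, 5, 3, 5))
  cuts <- plan_square_grid(roi, fraction = 1 / 16, s = 4)
  expect_equal(cuts$x_cuts, c(0L, 4L, 8L))

  roi10 <- roi_frame(c(0, 10, 0, 10), c(4, 6, 4, 6))
  cuts10 <- plan_square_grid(roi10, fraction = 0.04, s = 4.92)
  expect_equal(cuts10$x_cuts, c(0L, 5L, 10L))

  expect_error(plan_square_grid(roi, 1.5), "fraction")
  expect_error(plan_square_grid(roi, 0.5), "cell side")
})

test_that("a full 8x8 rectangle at s=4 gives 9 vertices and 8 right triangles", {
  roi <- roi_frame(c(0, 8, 0, 8), c(3, 5, 3, 5))
  surf <- thickness_grid(matrix(0, 9, 9), pixel_pitch = 1,
                         layer_tag = "ILM_elevation")
  m <- build_tri_mesh(roi, surf, 1 / 16, s = 4, exclude_inner = FALSE)
  expect_equal(nrow(m$vertices), 9L)
  expect_equal(nrow(m$faces), 8L)
  expect_equal(mesh_euler(m), 1L)  # disc
  # flat surface: all face normals parallel (z only)
  fg <- macfshape:::face_geometry(fshape(m, numeric(9)))
  expect_true(all(abs(fg$N[, 1:2]) < 1e-12))
})

test_that("the annular ROI mesh has the full-resolution face inventory", {
  roi <- roi_frame()  # needs a grid of at least 396 x 361
  surf <- thickness_grid(matrix(0, 361, 396), pixel_pitch = 6 / 396,
                         layer_tag = "ILM_elevation")
  m <- build_tri_mesh(roi, surf, 0.04)
  expect_equal(mesh_euler(m), 0L)  # annulus

  # all projected faces are right triangles with axis-aligned legs in {4,5}
  for (corner in 1:3) {
    a <- m$vertices[m$faces[, corner], 1:2]
    b <- m$vertices[m$faces[, corner %% 3 + 1], 1:2]
    d <- abs(a - b)
    leg <- pmax(d[, 1], d[, 2])
    axis_aligned <- pmin(d[, 1], d[, 2]) == 0
    diag_edge <- d[, 1] > 0 & d[, 2] > 0
    expect_true(all(axis_aligned | diag_edge))
    expect_true(all(leg[axis_aligned] %in% c(4, 5)))
  }

  # vertex count within +-10% of fraction x ROI point count
  target <- 0.04 * roi_point_count(roi)
  expect_gt(nrow(m$vertices), 0.9 * target)
  expect_lt(nrow(m$vertices), 1.1 * target)

  # no vertex strictly inside the inner rectangle
  i <- roi$inner
  inside <- m$lattice[, 1] > i[1] & m$lattice[, 1] < i[2] &
    m$lattice[, 2] > i[3] & m$lattice[, 2] < i[4]
  expect_false(any(inside))

  # total projected area equals the area of retained cells: each face
  # contributes leg_a * leg_b / 2 exactly
  fg <- macfshape:::face_geometry(fshape(m, numeric(nrow(m$vertices))))
  proj_area <- abs(fg$N[, 3]) / 2
  expect_true(all(proj_area %in% c(8, 10, 12.5)))  # {4,5} leg products / 2
})

test_that("template density also keeps legs in {4,5} on the default ROI", {
  roi <- roi_frame()
  surf <- thickness_grid(matrix(0, 361, 396), pixel_pitch = 6 / 396,
                         layer_tag = "ILM_elevation")
  m <- build_tri_mesh(roi, surf, 0.045)
  d1 <- abs(m$vertices[m$faces[, 1], 1:2] - m$vertices[m$faces[, 2], 1:2])
  leg <- pmax(d1[, 1], d1[, 2])[pmin(d1[, 1], d1[, 2]) == 0]
  expect_true(all(leg %in% c(4, 5)))
  target <- 0.045 * roi_point_count(roi)
  expect_gt(nrow(m$vertices), 0.9 * target)
  expect_lt(nrow(m$vertices), 1.1 * target)
})

test_that("fshape assembly maps subject fields onto shared connectivity", {
  rec1 <- tiny_record(thick_fun = function(x, y) 75.9 + 0 * x)
  roi <- roi_frame(c(0, 10, 0, 10), c(4, 7, 4, 7))
  mesh <- build_tri_mesh(roi, rec1$ilm, 0.25, s = 2)
  fs1 <- assemble_fshape(rec1, mesh)
  expect_true(all(fs1$signal == 75.9))

  rec2 <- tiny_record(thick_fun = function(x, y) 60 + y,
                      ilm_fun = function(x, y) 80 + 3 * y)
  fs2 <- assemble_fshape(rec2, mesh)
  expect_identical(fs1$mesh$faces, fs2$mesh$faces)
  expect_identical(fs1$mesh$lattice, fs2$mesh$lattice)
  # z comes from each subject's own ILM
  expect_equal(fs2$mesh$vertices[, 3], 80 + 3 * fs2$mesh$lattice[, 2])

  # a NaN at a mesh vertex is reported with its lattice point
  rec3 <- rec1
  rec3$thickness$values[1, 1] <- NaN  # lattice (0, 0) is a mesh vertex
  expect_error(assemble_fshape(rec3, mesh), "\\(0, 0\\)")

  # lattice outside the subject grid
  small <- tiny_record(m = 8)
  expect_error(assemble_fshape(small, mesh), "out of the subject")
})

test_that("meshes and signals export to PLY and VTK", {
  fs <- grid_fshape(4)
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(fs, ply)
  back <- read_ply(ply, pixel_pitch = 1)
  expect_equal(back$mesh$vertices, unname(fs$mesh$vertices), tolerance = 1e-8)
  expect_equal(back$signal, fs$signal, tolerance = 1e-8)
  expect_identical(back$mesh$faces, unname(fs$mesh$faces))

  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(fs, vtk)
  lines <- readLines(vtk)
  expect_true(any(grepl("POINTS 16 double", lines)))
  expect_true(any(grepl("SCALARS signal double 1", lines)))
})
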