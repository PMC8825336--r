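test_that("sphere mesh estimators converge to the closed forms", {
  m <- mesh_spheroid(1, 1, 64)
  expect_true(mesh_is_watertight(m))
  expect_rel_equal(mesh_area(m), 4 * pi, 5e-3)
  expect_rel_equal(mesh_volume(m), 4 / 3 * pi, 5e-3)
  # angle defects are exact for closed meshes
  expect_rel_equal(mesh_gauss_total(m), 4 * pi, 1e-9)
  m2 <- mesh_spheroid(1, 1, 128)
  expect_rel_equal(mesh_bending_integral(m2, 0), 16 * pi, 0.02)
})

test_that("mesh error shrinks under refinement", {
  errs <- vapply(c(16, 32, 64), function(n) {
    abs(mesh_area(mesh_spheroid(30, 30, n)) - 4 * pi * 900) / (4 * pi * 900)
  }, numeric(1))
  # error at least halves per doubling of resolution
  expect_lt(errs[2], errs[1] / 2)
  expect_lt(errs[3], errs[2] / 2)
})

test_that("topology fixtures reproduce 2 pi chi by angle defect", {
  expect_rel_equal(mesh_gauss_total(mesh_spheroid(50, 20, 32)), 4 * pi, 1e-9)
  tor <- mesh_torus(3, 1, 32)
  expect_true(mesh_is_watertight(tor))
  expect_lt(abs(mesh_gauss_total(tor)), 1e-8)        # chi = 0
  g2 <- mesh_genus2(3, 1, 32)
  expect_true(mesh_is_watertight(g2))
  expect_rel_equal(mesh_gauss_total(g2), -4 * pi, 1e-9)  # chi = -2
})

test_that("oblate spheroid: mesh estimators agree with quadrature within 1%", {
  a <- 50; c <- 20
  m <- mesh_spheroid(a, c, 128)
  expect_rel_equal(mesh_area(m), spheroid_area(a, c), 0.01)
  expect_rel_equal(mesh_volume(m), spheroid_volume(a, c), 0.01)
  expect_rel_equal(mesh_bending_integral(m, 0),
                   spheroid_bending_integral(a, c, 0), 0.01)
  expect_rel_equal(mesh_bending_integral(m, 0.02),
                   spheroid_bending_integral(a, c, 0.02), 0.01)
})

test_that("open tube mesh agrees with tube quadrature", {
  tj <- solve_tube_junction(60, 25, 15, 40)
  m <- mesh_tube(tj, 96)
  expect_false(mesh_is_watertight(m))
  expect_gt(length(mesh_boundary_vertices(m)), 0)
  expect_rel_equal(mesh_area(m), tube_area(tj), 0.01)
})

test_that("mesh volume refuses open meshes", {
  tj <- solve_tube_junction(60, 25, 15, 40)
  expect_error(mesh_volume(mesh_tube(tj, 16)), class = "cellplate_mesh_error")
})

test_that("degenerate mesh dimensions are rejected", {
  expect_error(mesh_spheroid(1, 1, 4), class = "cellplate_validation_error")
  expect_error(mesh_torus(1, 2, 32), class = "cellplate_validation_error")
})

test_that("OBJ and PLY writers emit valid plain-text meshes", {
  m <- mesh_spheroid(10, 5, 16)
  obj <- tempfile(fileext = ".obj")
  ply <- tempfile(fileext = ".ply")
  write_obj(m, obj)
  write_ply(m, ply)
  lines <- readLines(obj)
  expect_equal(sum(grepl("^v ", lines)), nrow(m$vertices))
  expect_equal(sum(grepl("^f ", lines)), nrow(m$faces))
  ply_lines <- readLines(ply)
  expect_equal(ply_lines[1], "ply")
  expect_equal(sum(ply_lines == "end_header"), 1)
  unlink(c(obj, ply))
})

test_that("composite meshes merge primitives for export", {
  s <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  m <- composite_mesh(s, n = 24)
  expect_s3_class(m, "cp_mesh")
  expect_gt(nrow(m$faces), 1000)
  # the x-extent spans both vesicles
  expect_gt(diff(range(m$vertices[, 1])), s$spacing)
})
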