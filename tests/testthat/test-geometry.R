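test_that("spheroid closed forms match quadrature for random oblate shapes", {
  set.seed(42)
  for (i in 1:8) {
    a <- runif(1, 10, 300)
    c <- runif(1, 0.2, 1) * a
    # quadrature route: surface-of-revolution area element in the polar angle
    quad <- spheroid_moments(a, c, 200)$area
    expect_rel_equal(quad, spheroid_area(a, c), 1e-6)
    expect_equal(spheroid_volume(a, c), 4 / 3 * pi * a^2 * c)
  }
})

test_that("sphere special values are exact", {
  expect_rel_equal(spheroid_area(30, 30), 4 * pi * 900, 1e-12)
  expect_rel_equal(spheroid_volume(30, 30), 113097.3355, 1e-9)
  # radius giving single-vesicle area 1e4 nm^2
  r <- uniroot(function(r) spheroid_area(r, r) - 1e4, c(1, 100),
               tol = 1e-12)$root
  expect_rel_equal(r, 28.20948, 1e-5)
})

test_that("invalid spheroid shapes are rejected", {
  expect_error(spheroid_area(-1, 1), class = "cellplate_validation_error")
  expect_error(spheroid_area(10, 20), class = "cellplate_validation_error")
  expect_error(spheroid_volume(10, 0), class = "cellplate_validation_error")
})

test_that("spheroid bending integral reproduces the Willmore sphere values", {
  for (r in c(5, 30, 400)) {
    expect_rel_equal(spheroid_bending_integral(r, r, 0), 16 * pi, 1e-6)
    expect_lt(spheroid_bending_integral(r, r, 2 / r), 1e-8)
  }
})

test_that("junction solver honors C0 and C1 continuity", {
  tj <- solve_tube_junction(60, 25, 15, 40)
  expect_equal(tj$bh, 15 * 25 / 60)
  expect_lt(tj$residual, 1e-6 * 60)
  # C0: tube end semi-axis equals the cut-ellipse semi-axis
  a_end <- tj$ah * sqrt(1 + (tj$l / 2)^2 / tj$asym^2)
  expect_rel_equal(a_end, sqrt(60^2 - tj$xj^2), 1e-9)
  # spherical vesicle: aspect rule collapses to bh = ah
  tjs <- solve_tube_junction(40, 40, 12, 30)
  expect_equal(tjs$bh, tjs$ah)
  # no junction plane when the waist exceeds the vesicle radius
  expect_error(solve_tube_junction(30, 30, 30, 40),
               class = "cellplate_geometry_error")
})

test_that("tube integrals recover the circular-cylinder limit", {
  cyl <- structure(list(l = 50, ah = 10, bh = 10, asym = 1e9, a = NA, c = NA),
                   class = "cp_tube")
  expect_rel_equal(tube_area(cyl), 2 * pi * 10 * 50, 1e-6)
  expect_rel_equal(tube_volume(cyl), pi * 100 * 50, 1e-6)
  expect_rel_equal(tube_bending_integral(cyl, 0), 2 * pi * 50 / 10, 1e-6)
  # with c0 matching the cylinder curvature 1/r the integrand vanishes
  expect_lt(tube_bending_integral(cyl, 1 / 10), 1e-8)
})

test_that("quadrature is converged: grid doubling changes results < 1e-5", {
  tj <- solve_tube_junction(60, 25, 15, 40)
  for (n in c(64L)) {
    t1 <- tube_integrals(tj, n, n)
    t2 <- tube_integrals(tj, 2L * n, 2L * n)
    for (f in c("area", "volume", "i1", "i2")) {
      expect_rel_equal(t1[[f]], t2[[f]], 1e-5)
    }
  }
  c1 <- cap_integrals(60, 25, tj$xj, 48, 48)
  c2 <- cap_integrals(60, 25, tj$xj, 96, 96)
  for (f in c("area", "volume", "i1", "i2")) {
    expect_rel_equal(c1[[f]], c2[[f]], 1e-5)
  }
})

test_that("the 2D integrator agrees with the 1D spheroid route", {
  # a full spheroid assembled from two half-caps, integrated about an
  # equatorial axis, must match the polar-angle quadrature
  a <- 50; c <- 20
  m <- spheroid_moments(a, c, 400)
  half <- cap_integrals(a, c, 1e-9, 200, 200)
  expect_rel_equal(2 * half$area, m$area, 1e-5)
  expect_rel_equal(2 * half$volume, m$volume, 1e-5)
  expect_rel_equal(2 * half$i1, m$i1, 1e-5)
  expect_rel_equal(2 * half$i2, m$i2, 1e-5)
})

test_that("assembly removes junction caps and keeps continuity", {
  s1 <- assemble(conformation("1x0x0"), 30, 30)
  expect_rel_equal(s1$area, spheroid_area(30, 30), 1e-9)

  s2 <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  tj <- s2$tube
  expect_lt(s2$area,
            2 * spheroid_area(60, 25) + tube_area(tj))
  expect_gt(s2$area, spheroid_area(60, 25))  # more than one vesicle remains
  expect_lt(tj$residual, 1e-6 * 60)
  # center spacing equals tube length plus the two cut distances
  expect_equal(s2$spacing, s2$l + 2 * tj$xj)
})

test_that("infeasible assemblies raise geometry errors", {
  expect_error(assemble(conformation("2x1x0"), 30, 30, ah = 40, l = 30),
               class = "cellplate_geometry_error")
  # ring with caps overlapping at the vesicles (waist too fat for the corner)
  expect_error(assemble(conformation("4x4x1"), 40, 16, ah = 30, l = 60),
               class = "cellplate_geometry_error")
})

test_that("single-spheroid footprint is the equatorial disk", {
  s <- assemble(conformation("1x0x0"), 75, 30)
  fp <- footprint_area(s)
  expect_equal(fp$a_eq, pi * 75^2)
  expect_equal(fp$gap_area, 0)
})

test_that("chain footprint matches an independent rasterization", {
  s <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  # force the raster route with a fine grid as the independent oracle
  r <- cellplate:::raster_footprint(s$conf, s$a, s$tube, s$centers,
                                    resolution = 0.35)
  expect_rel_equal(s$a_eq, r$a_eq, 5e-3)
})

test_that("fenestrated footprint has gaps that close as the waist grows", {
  conf <- conformation("4x4x1")
  s1 <- assemble(conf, 30, 12, ah = 6, l = 30)
  s2 <- assemble(conf, 30, 12, ah = 10, l = 30)
  fp1 <- footprint_area(s1)
  fp2 <- footprint_area(s2)
  expect_gt(fp1$gap_area, 0)
  expect_lt(fp2$gap_area, fp1$gap_area)
})

test_that("footprint rejects non-positive resolution", {
  s <- assemble(conformation("1x0x0"), 30, 30)
  expect_error(footprint_area(s, resolution = 0),
               class = "cellplate_validation_error")
})
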