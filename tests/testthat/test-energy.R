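test_that("energy terms reproduce their closed forms on a sphere", {
  sph <- assemble(conformation("1x0x0"), 30, 30)
  expect_rel_equal(bending_energy(sph, 100, 0), 8 * pi * 100, 1e-6)
  expect_lt(abs(bending_energy(sph, 100, 2 / 30)), 1e-4)
  # signed pressure convention: positive interior excess lowers the energy
  expect_rel_equal(pressure_energy(sph, 10), -0.01 * spheroid_volume(30, 30),
                   1e-12)
  expect_equal(pressure_energy(sph, 0), 0)
  expect_rel_equal(tension_energy(sph, 1.6), 1.6 * spheroid_area(30, 30),
                   1e-12)
  expect_equal(tension_energy(sph, 0), 0)
  expect_rel_equal(gaussian_energy(sph, -80), 4 * pi * (-80), 1e-12)
  expect_equal(spreading_energy(sph, 0), 0)
})

test_that("spreading energy is the footprint work", {
  s <- assemble(conformation("1x0x0"), 100, 40)
  expect_rel_equal(spreading_energy(s, 4), -4 * pi * 100^2, 1e-9)
})

test_that("the Gaussian term depends only on topology", {
  expect_rel_equal(gaussian_energy(conformation("1x0x0"), -80),
                   -4 * pi * 80, 1e-12)
  expect_equal(gaussian_energy(conformation("4x4x1"), -80), 0)  # genus 1
  expect_rel_equal(gaussian_energy(conformation("6x7x2"), -80),
                   4 * pi * 80, 1e-12)  # chi = -2
  # invariant under shape parameters at fixed topology
  s1 <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  s2 <- assemble(conformation("2x1x0"), 80, 30, ah = 10, l = 80)
  expect_equal(gaussian_energy(s1, -80), gaussian_energy(s2, -80))
  # disconnected ensemble copies each contribute one sphere topology
  expect_rel_equal(gaussian_energy(conformation("2x1x0*3"), -80),
                   3 * 4 * pi * (-80), 1e-12)
})

test_that("total energy is the exact sum of its five terms", {
  s <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  p <- model_params(kb = 150, c0 = 0.01, dp = 8, lambda = 3)
  br <- total_energy(s, p)
  expect_identical(br$e_total,
                   br$e_bending + br$e_pressure + br$e_tension +
                     br$e_gaussian + br$e_spreading)
  # breakdown echoes all six parameters for provenance
  expect_equal(unlist(br[c("kb", "c0", "dp", "gamma", "kg", "lambda")]),
               c(kb = 150, c0 = 0.01, dp = 8, gamma = 1.6, kg = -120,
                 lambda = 3))
})

test_that("sphere with only bending and Gaussian terms sums exactly", {
  sph <- assemble(conformation("1x0x0"), 30, 30)
  p <- quiet_params(kb = 100, c0 = 0, dp = 0, gamma = 0, kg = -80, lambda = 0)
  expect_rel_equal(total_energy(sph, p)$e_total, 8 * pi * 100 + 4 * pi * (-80),
                   1e-6)
})

test_that("total energy is linear in each modulus at fixed geometry", {
  s <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  base <- quiet_params(kb = 100, c0 = 0.01, dp = 4, gamma = 1.6, kg = -80,
                       lambda = 3)
  e0 <- total_energy(s, base)$e_total
  for (par in c("dp", "gamma", "lambda")) {
    up <- base; up[[par]] <- 2 * base[[par]]
    dn <- base; dn[[par]] <- 0
    eu <- total_energy(s, up)$e_total
    ed <- total_energy(s, dn)$e_total
    # linearity: midpoint of the doubled and zeroed parameter is the base
    expect_rel_equal((eu + ed) / 2, e0, 1e-9)
  }
  # kb linear with kg held fixed
  up <- base; up$kb <- 200
  dn <- base; dn$kb <- 1e-9
  expect_rel_equal((total_energy(s, up)$e_total +
                      total_energy(s, dn)$e_total) / 2, e0, 1e-6)
})

test_that("sign contracts: lambda never raises, gamma never lowers energy", {
  s <- assemble(conformation("4x4x1"), 30, 12, ah = 10, l = 30)
  p1 <- quiet_params(lambda = 2)
  p2 <- quiet_params(lambda = 5)
  expect_lte(total_energy(s, p2)$e_total, total_energy(s, p1)$e_total)
  g1 <- quiet_params(gamma = 0.5)
  g2 <- quiet_params(gamma = 1.6)
  expect_gte(total_energy(s, g2)$e_total, total_energy(s, g1)$e_total)
})

test_that("composite bending agrees with the mesh oracle", {
  # dumbbell bending = spheroids - caps + tube, each checked by the
  # cotan-Laplacian estimator at the oracle resolution
  s <- assemble(conformation("2x1x0"), 60, 25, ah = 15, l = 40)
  tj <- s$tube
  msph <- mesh_bending_integral(mesh_spheroid(60, 25, 128), 0)
  mtube <- mesh_bending_integral(mesh_tube(tj, 128), 0)
  cap <- cap_quantities(60, 25, tj$xj, 0)
  quad_total <- s$i2
  # open-mesh estimates omit a boundary strip, so the tolerance is looser
  mesh_total <- 2 * msph - 2 * cap$bending + mtube
  expect_rel_equal(bending_energy(s, 100, 0), 100 / 2 * quad_total, 1e-9)
  expect_rel_equal(mesh_total, quad_total, 0.025)
})

test_that("Willmore property: the sphere minimizes bending at fixed area", {
  area <- 4 * pi * 40^2
  i_sphere <- spheroid_bending_integral(40, 40, 0)
  for (ratio in c(0.3, 0.5, 0.8)) {
    # oblate spheroid of the same area
    a <- uniroot(function(a) spheroid_area(a, ratio * a) - area,
                 c(10, 500))$root
    expect_gt(spheroid_bending_integral(a, ratio * a, 0), i_sphere)
  }
})
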