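test_that("every feasible shape matches the target area within tolerance", {
  g <- small_grid()
  for (spec in c("1x0x0", "2x1x0")) {
    fs <- feasible_set(conformation(spec), 1e5, g)
    expect_gt(nrow(fs), 0)
    expect_true(all(abs(fs$area - 1e5) / 1e5 < g$area_rtol))
    # independent re-validation at doubled quadrature order
    for (i in seq_len(min(nrow(fs), 5))) {
      a2 <- cellplate:::composite_area(conformation(spec), fs$a[i], fs$c[i],
                                       fs$ah[i], fs$l[i],
                                       n_quad = 4 * g$n_quad)
      expect_rel_equal(a2, 1e5, 1e-4)
    }
  }
})

test_that("unreachable target areas raise an infeasibility error", {
  expect_error(feasible_set(conformation("1x0x0"), 1e-2, coarse_grid()),
               class = "cellplate_infeasible_error")
})

test_that("bending-only minimization recovers the sphere (Willmore)", {
  p <- quiet_params(kb = 100, c0 = 0, dp = 0, gamma = 0, kg = 0, lambda = 0)
  fit <- minimize_energy(conformation("1x0x0"), 4 * pi * 30^2, p,
                         grid_spec(n_single = 48))
  expect_rel_equal(fit$emin, 8 * pi * 100, 1e-4)
  expect_rel_equal(fit$best[["a"]], fit$best[["c"]], 2e-3)
})

test_that("tension-only degeneracy is broken toward the smallest a", {
  # all feasible shapes have identical energy gamma * A; the deterministic
  # tie-break must return the smallest equatorial radius (i.e. the sphere)
  p <- quiet_params(kb = 1e-12, c0 = 0, dp = 0, gamma = 1.6, kg = 0,
                    lambda = 0)
  g <- grid_spec(n_single = 24, refine = 0)
  fit <- minimize_energy(conformation("1x0x0"), 1e5, p, g)
  fs <- feasible_set(conformation("1x0x0"), 1e5, g)
  expect_rel_equal(fit$emin, 1.6 * 1e5, 1e-3)
  expect_equal(fit$best[["a"]], min(fs$a))
})

test_that("exhaustive enumeration reproduces the minimizer's optimum", {
  # independent oracle: loop over the same c-grid, solve the area constraint,
  # evaluate the five terms directly from assembled surfaces, take the min
  p <- model_params(kb = 100, c0 = 0.02, dp = 6, lambda = 4)
  g <- grid_spec(n_single = 16, refine = 0)
  a_target <- 5e4
  cs <- exp(seq(log(g$c_lim[1]), log(g$c_lim[2]), length.out = g$n_single))
  brute <- Inf
  for (cc in cs) {
    a <- tryCatch(uniroot(function(a) spheroid_area(a, cc) - a_target,
                          c(cc, g$a_lim[2]), tol = 1e-10)$root,
                  error = function(e) NA)
    if (is.na(a)) next
    s <- assemble(conformation("1x0x0"), a, cc)
    e <- total_energy(s, p)$e_total
    if (e < brute) brute <- e
  }
  fit <- minimize_energy(conformation("1x0x0"), a_target, p, g)
  # same optimum to well below any energy scale in the problem
  expect_lt(abs(fit$emin - brute), 0.01)
})

test_that("refinement is converged: denser grids change Emin < 0.5%", {
  p <- model_params(kb = 100, c0 = 0.02, dp = 6, lambda = 4)
  conf <- conformation("2x1x0")
  e1 <- minimize_energy(conf, 8e4, p, grid_spec(n = 8, n_refine = 5))$emin
  e2 <- minimize_energy(conf, 8e4, p, grid_spec(n = 16, n_refine = 7))$emin
  expect_rel_equal(e1, e2, 5e-3)
})

test_that("delta_emin of the single spheroid against itself is exactly zero", {
  p <- model_params()
  g <- coarse_grid()
  expect_identical(delta_emin(conformation("1x0x0"), 1e5, p, g), 0)
})

test_that("minimization is deterministic", {
  p <- model_params()
  g <- coarse_grid()
  f1 <- minimize_energy(conformation("2x1x0"), 6e4, p, g)
  f2 <- minimize_energy(conformation("2x1x0"), 6e4, p, g)
  expect_identical(f1$emin, f2$emin)
  expect_identical(f1$best, f2$best)
})

test_that("ensemble comparison at k = 1 matches delta_emin", {
  p <- params_spreading()
  g <- coarse_grid()
  d1 <- ensemble_delta(1, 1e5, p, g)
  d2 <- delta_emin(conformation("2x1x0"), 1e5, p, g)
  expect_rel_equal(d1, d2, 1e-9)
})

test_that("stability curves carry the time-proxy structure", {
  p <- params_no_spreading()
  g <- coarse_grid()
  areas <- c(6e4, 1.2e5)
  sc <- stability_curve(conformation("2x1x0"), areas, p, g)
  expect_s3_class(sc, "cp_stability")
  expect_equal(sc$area, areas)
  expect_equal(sc$delta_emin, sc$emin_ref - sc$emin)
  expect_error(stability_curve(conformation("2x1x0"), rev(areas), p, g),
               class = "cellplate_validation_error")
})

test_that("fit objects tidy and glance broom-style", {
  fit <- minimize_energy(conformation("2x1x0"), 6e4, model_params(),
                         coarse_grid())
  td <- tidy(fit)
  expect_equal(td$term, c("a", "c", "ah", "l"))
  gl <- glance(fit)
  expect_equal(gl$conformation, "2x1x0")
  expect_equal(gl$hos, 2 * fit$best[["c"]])
  expect_s3_class(autoplot(stability_curve(conformation("2x1x0"),
                                           c(5e4, 1e5), model_params(),
                                           coarse_grid())), "ggplot")
})

test_that("threshold scan reports a no-threshold outcome without an error", {
  # without a spreading force the tubular conformation stays favored over
  # the whole range: no sign change, no exception
  thr <- find_c0_threshold(list("2x1x0"), 1.2e5,
                           quiet_params(kb = 100, dp = 6, lambda = 0),
                           c0_range = c(0.01, 0.04), step = 0.01,
                           grid = coarse_grid())
  expect_true(is.na(thr))
  expect_equal(attr(thr, "outcome"), "no-threshold")
})

test_that("the stiffness/spreading-force map has the expected corners", {
  p <- params_no_spreading(c0 = 0.02)
  tab <- kb_lambda_sweep(conformation("2x1x0"), 1.2e5,
                         kb_values = c(62.5, 100, 200),
                         lambda_values = c(0, 2, 4, 6),
                         p = p, grid = coarse_grid())
  expect_equal(nrow(tab), 12L)
  # no spreading force: the network is favored at finite c0 for every KB
  expect_true(all(!tab$spheroid_favored[tab$lambda == 0]))
  # strong spreading force, softest membrane: the spheroid is favored
  expect_true(tab$spheroid_favored[tab$kb == 62.5 & tab$lambda == 6])
  # every sign comes from a finite energy difference
  expect_true(all(is.finite(tab$delta_emin)))
})
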