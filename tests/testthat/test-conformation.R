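test_that("genus formula reproduces every named conformation", {
  named <- list(c(1, 0, 0), c(2, 1, 0), c(5, 4, 0), c(7, 6, 0),
                c(4, 4, 1), c(6, 7, 2), c(8, 10, 3), c(10, 13, 4))
  for (vtg in named) {
    conf <- conformation(vtg[1], vtg[2], vtg[3])
    expect_equal(genus(conf), vtg[3])
    expect_equal(conf$n_components, 1L)
    expect_equal(conf$t - conf$v + conf$n_components, conf$g)
  }
})

test_that("spec strings parse with layout and ensemble suffixes", {
  conf <- conformation("6x7x2")
  expect_equal(conf$layout, "ladder")
  expect_equal(nrow(conf$edges), 7L)
  conf2 <- conformation("2x1x0*3")
  expect_equal(conf2$copies, 3L)
  conf3 <- conformation("5x4x0@layout=chain")
  expect_equal(conf3$layout, "chain")
  expect_error(conformation("2x1"), class = "cellplate_validation_error")
  expect_error(conformation("axbxc"), class = "cellplate_validation_error")
})

test_that("genus mismatches are rejected as specification errors", {
  # a connected 6-vesicle, 7-tube graph must have two gaps, not three
  expect_error(conformation("6x7x3"), class = "cellplate_spec_error")
  expect_error(conformation("2x1x1"), class = "cellplate_spec_error")
  expect_error(conformation("4x4x2"), class = "cellplate_spec_error")
})

test_that("conformations round-trip through JSON", {
  for (s in c("1x0x0", "2x1x0", "4x4x1", "8x10x3", "2x1x0*4")) {
    conf <- conformation(s)
    back <- conformation_from_json(conformation_json(conf))
    expect_equal(back$v, conf$v)
    expect_equal(back$t, conf$t)
    expect_equal(back$g, conf$g)
    expect_equal(back$layout, conf$layout)
    expect_equal(back$copies, conf$copies)
    expect_equal(back$edges, conf$edges)
  }
})

test_that("layouts place centers consistently with the graph", {
  d <- 100
  chain <- cellplate:::layout_centers(conformation("5x4x0"), d)
  expect_equal(dim(chain), c(5L, 2L))
  expect_true(all(abs(diff(chain[, 1]) - d) < 1e-12))
  ring <- cellplate:::layout_centers(conformation("4x4x1"), d)
  # adjacent ring centers separated by exactly d
  expect_rel_equal(sqrt(sum((ring[1, ] - ring[2, ])^2)), d, 1e-12)
  ladder <- cellplate:::layout_centers(conformation("6x7x2"), d)
  conf <- conformation("6x7x2")
  for (e in seq_len(nrow(conf$edges))) {
    dd <- sqrt(sum((ladder[conf$edges[e, 1], ] - ladder[conf$edges[e, 2], ])^2))
    expect_rel_equal(dd, d, 1e-12)
  }
})

test_that("model parameters validate and warn outside published ranges", {
  p <- model_params()
  expect_s3_class(p, "cp_params")
  expect_equal(p$kg, -0.8 * p$kb)
  expect_warning(model_params(kb = 500), class = "cellplate_range_warning")
  expect_warning(model_params(lambda = 10), class = "cellplate_range_warning")
  expect_error(model_params(kb = -5), class = "cellplate_validation_error")
  expect_error(model_params(c0 = -0.01), class = "cellplate_validation_error")
})
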