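test_that("the registry exposes every study condition", {
  sc <- list_scenarios()
  expect_true(all(c("fig2A", "fig2D", "fig2G", "fig2J", "fig3B", "fig3E",
                    "fig3H", "fig4B", "fig4D", "s1") %in% sc$id))
  expect_error(make_scenario("nope"), "unknown scenario")
  expect_error(make_scenario("fig2A", overrides = list(bogus = 1)), "bogus")
})

test_that("registered initial-condition formulas are sampled exactly", {
  a <- make_scenario("fig2A")
  expect_equal(a$ic$E, rep(2, 100))
  expect_equal(a$ic$S, rep(2, 100))
  expect_equal(a$ic$C, rep(0, 100))
  expect_equal(a$ic$P, rep(0, 100))
  g <- make_scenario("fig2G")
  expect_equal(g$ic$E, rep(400, 100))
  expect_equal(g$ic$S, rep(300, 100))
  d <- make_scenario("fig2D")
  x <- d$grid$x
  expect_equal(d$ic$E, 18.5 * (tanh(20 * x / 3 - 190) + 1) + 1e-4)
  b <- make_scenario("fig4B")
  expect_equal(b$ic$S[1, ],
               500 * tanh(3.3 * b$grid$y - 50) + 520)
  expect_equal(b$ic$E[, 1],
               10 * tanh(0.2 * b$grid$x - 3) + 20)
  expect_equal(b$ic$D, matrix(20, 30, 30))
})

test_that("heterogenized scenarios carry the averages their formulas imply", {
  # segregated tanh pair: averages match the homogeneous partner exactly
  j <- make_scenario("fig2J"); g <- make_scenario("fig2G")
  expect_equal(spatial_average(j$ic$E, j$grid),
               spatial_average(g$ic$E, g$grid), tolerance = 1e-6)
  expect_equal(spatial_average(j$ic$S, j$grid),
               spatial_average(g$ic$S, g$grid), tolerance = 1e-6)
  # co-localized tanh step: the registered formula's own mean is 1.8501 uM
  # (7.5% below the 2 uM homogeneous level, a property of the formula itself)
  d <- make_scenario("fig2D")
  expect_equal(spatial_average(d$ic$E, d$grid), 1.8501, tolerance = 5e-3)
  # Gaussian enzyme: mean held at the homogenized 5 uM level
  b3 <- make_scenario("fig3B"); e3 <- make_scenario("fig3E")
  expect_equal(spatial_average(b3$ic$E, b3$grid),
               spatial_average(e3$ic$E, e3$grid), tolerance = 1e-9)
})

test_that("localized enzyme profiles conserve mass across widths", {
  g <- grid_1d(30, 300)
  ints <- vapply(c(0.2, 0.79, 2.5, 7.9, 25),
                 function(sg) spatial_average(localized_enzyme_ic(sg, g), g),
                 0)
  expect_equal(ints, rep(5, 5), tolerance = 1e-6)
  # near-uniform at sigma = 25
  e25 <- localized_enzyme_ic(25, g)
  expect_lt(max(e25) / min(e25) - 1, 0.5)
  # sharply peaked at sigma = 0.2: mass concentrated within 1 um of center
  e02 <- localized_enzyme_ic(0.2, g)
  core <- abs(g$x - 15) < 1
  expect_gt(sum(e02[core]) / sum(e02), 0.999)
  expect_equal(g$x[which.max(e02)], 15, tolerance = g$dx)
  expect_error(localized_enzyme_ic(-1, g), "sigma")
})

test_that("the heterogeneity index is a base-10 decibel scale", {
  expect_equal(heterogeneity(25), 0)
  expect_equal(heterogeneity(2.5), 10)
  expect_equal(heterogeneity(25 / sqrt(10)), 5)
  expect_true(all(diff(heterogeneity(c(10, 5, 1))) > 0))
  expect_warning(heterogeneity(30), "exceeds")
})

test_that("scenario generation is bit-identical on repetition", {
  a <- make_scenario("fig3B")
  b <- make_scenario("fig3B")
  expect_identical(a$ic, b$ic)
  expect_identical(a$grid$x, b$grid$x)
})

test_that("the GK step scenario partitions into valid and invalid regions", {
  sc <- make_scenario("fig4B")
  vm <- validity_map(sc)
  top <- vm[, sc$grid$y > 25]      # high-substrate band
  bottom <- vm[, sc$grid$y < 10]   # low-substrate band
  expect_lt(max(top), 0.03)        # ~0.02, far below 1
  expect_gt(min(bottom), 0.8)      # ~1: reduction invalid
  expect_equal(vm[1, sc$grid$n_y], 20 / (1 + 500 * tanh(3.3 * 30 - 50) + 520),
               tolerance = 1e-12)
})
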