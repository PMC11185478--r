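rc_fig2 <- rate_constants(3.4, 60, 3.2)

test_that("nothing happens without substrate or complex", {
  g <- grid_1d(30, 50)
  D <- diffusion_coefficients(0.2)
  st <- state_1d(g, S = 0, E = 3, C = 0, P = 1)
  for (v in c("full", "sqssa", "tqssa")) {
    out <- step_1d(st, v, rc_fig2, D, 1e-3)
    expect_equal(out$P, st$P)
    expect_equal(out$S, st$S)
  }
})

test_that("a homogeneous step reduces to the explicit-Euler well-mixed update", {
  g <- grid_1d(30, 20)
  D <- diffusion_coefficients(5)   # diffusion is the identity on constants
  dt <- 1e-4
  st <- state_1d(g, S = 12, E = 7, C = 1.5, P = 0.3)
  out <- step_1d(st, "full", rc_fig2, D, dt)
  want <- euler_full_0d(12, 7, 1.5, 0.3, rc_fig2, dt)
  for (sp in c("S", "E", "C", "P"))
    expect_equal(out[[sp]], rep(want[[sp]], 20), tolerance = 1e-13)

  # reduced variants: hand-computed QSS updates
  K_M <- derived_constants(rc_fig2)$K_M
  outs <- step_1d(st, "sqssa", rc_fig2, D, dt)
  Cs <- 8.5 * 12 / (12 + K_M)
  S1 <- 12 - dt * 3.2 * Cs
  expect_equal(outs$S, rep(S1, 20), tolerance = 1e-13)
  expect_equal(outs$C, rep(8.5 * S1 / (S1 + K_M), 20), tolerance = 1e-13)
  expect_equal(outs$E + outs$C, rep(8.5, 20), tolerance = 1e-13)

  outt <- step_1d(st, "tqssa", rc_fig2, D, dt)
  Ct <- tqss_complex(13.5, 8.5, K_M)
  Sh1 <- 13.5 - dt * 3.2 * Ct
  expect_equal(outt$S + outt$C, rep(Sh1, 20), tolerance = 1e-13)
  expect_equal(outt$C, rep(tqss_complex(Sh1, 8.5, K_M), 20), tolerance = 1e-13)
})

test_that("equal diffusivity preserves the spatial totals through one step", {
  sc <- make_scenario("fig2D")
  st <- state_1d(sc$grid, sc$ic$S, sc$ic$E)
  out <- step_1d(st, "full", sc$rc, sc$D, sc$tg$dt)
  tot0 <- spatial_average(st$S + st$C + st$P, sc$grid)
  tot1 <- spatial_average(out$S + out$C + out$P, sc$grid)
  expect_equal(tot1, tot0, tolerance = 1e-10)
  e0 <- spatial_average(st$E + st$C, sc$grid)
  e1 <- spatial_average(out$E + out$C, sc$grid)
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("homogeneous PDE trajectories match the stiff ODE oracle pointwise", {
  sc <- make_scenario("fig2A")
  for (v in c("full", "sqssa", "tqssa")) {
    sim <- simulate_rd(sc, v, 50)
    ode <- simulate_ode(v, sc$rc, list(S = 2, E = 2), T = sc$tg$T,
                        times = sim$times)
    for (j in c(1, 50, 100)) {
      err <- max(abs(sim$data[, j, "P"] - ode$P)) / max(ode$P)
      expect_lt(err, 0.005)
    }
  }
})

test_that("the solution is converged at the registered discretization", {
  base <- simulate_rd(make_scenario("fig2D"), "full", 10)
  fine <- simulate_rd(make_scenario("fig2D",
                                    overrides = list(n_x = 200, n_t = 5460)),
                      "full", 10)
  p0 <- pbar_series(base); p1 <- pbar_series(fine)
  expect_lt(abs(p1$value[nrow(p1)] - p0$value[nrow(p0)]) / p0$value[nrow(p0)],
            0.01)
})

test_that("an oversized time step is reported as a stability failure", {
  sc <- make_scenario("fig2G", overrides = list(n_t = 10L))
  expect_error(simulate_rd(sc, "full", 5), "unstable")
})

test_that("simulation results are deterministic and tidy-exportable", {
  sc <- make_scenario("fig2A", overrides = list(T = 0.1, n_t = 220L))
  a <- simulate_rd(sc, "tqssa", 10)
  b <- simulate_rd(sc, "tqssa", 10)
  expect_identical(a$data, b$data)
  df <- as.data.frame(a)
  expect_named(df, c("time", "x", "species", "value"))
  expect_equal(nrow(df), length(a$times) * sc$grid$n_x * 4)
  expect_equal(df$value[df$species == "P" & df$time == 0], rep(0, 100))
})
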