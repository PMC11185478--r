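rc_gk <- gk_rate_constants(2.22, 1.84, 0.38)

test_that("the cycle is quiescent without substrate", {
  g <- grid_2d(30, 8)
  st <- gk_state(g, S = 0, Sp = 0, E = 5, D = 5)
  for (v in c("full", "sqssa", "tqssa")) {
    out <- gk_step(st, v, rc_gk, gk_diffusion(0.2), 0.01)
    for (sp in c("S", "Sp", "E", "D", "ES", "DSp"))
      expect_equal(out[[sp]], st[[sp]])
  }
})

test_that("a homogeneous step matches the hand-written well-mixed update", {
  g <- grid_2d(30, 4)
  dt <- 1e-3
  st <- gk_state(g, S = 10, Sp = 3, E = 5, D = 4, ES = 1, DSp = 0.5)
  out <- gk_step(st, "full", rc_gk, gk_diffusion(0.2), dt)
  bindE <- 2.22 * 10 * 5; bindD <- 2.22 * 3 * 4
  expect_equal(out$S[2, 3], 10 + dt * (-bindE + 1.84 * 1 + 0.38 * 0.5))
  expect_equal(out$Sp[1, 1], 3 + dt * (-bindD + 1.84 * 0.5 + 0.38 * 1))
  expect_equal(out$E[2, 2], 5 + dt * (-bindE + (1.84 + 0.38) * 1))
  expect_equal(out$ES[3, 1], 1 + dt * (bindE - (1.84 + 0.38) * 1))
  expect_equal(out$DSp[2, 4], 0.5 + dt * (bindD - (1.84 + 0.38) * 0.5))
})

test_that("symmetric kinase and phosphatase arms balance at one half", {
  g <- grid_2d(30, 4)
  st <- gk_state(g, S = 10, Sp = 10, E = 5, D = 5)
  dd <- gk_diffusion(0.2)
  for (v in c("full", "sqssa", "tqssa")) {
    s <- st
    for (n in 1:15000) s <- gk_step(s, v, rc_gk, dd, 0.01)
    raw_frac <- (s$Sp + s$DSp) / (s$S + s$Sp + s$ES + s$DSp)
    expect_equal(as.vector(raw_frac), rep(0.5, 16), tolerance = 1e-8)
  }
})

test_that("phosphorylated-fraction conventions follow each reduction", {
  g <- grid_2d(30, 4)
  sc <- list(times = c(0, 1), grid = g, model = "gk2d", variant = "full")
  mk <- function(S, Sp, ES, DSp, variant) {
    data <- array(0, dim = c(1, 4, 4, 6),
                  dimnames = list(NULL, NULL, NULL,
                                  c("S", "Sp", "E", "D", "ES", "DSp")))
    data[1, , , "S"] <- S; data[1, , , "Sp"] <- Sp
    data[1, , , "ES"] <- ES; data[1, , , "DSp"] <- DSp
    structure(list(times = 0, data = data, grid = g, variant = variant,
                   model = "gk2d"), class = "rd_sim")
  }
  expect_equal(phospho_fraction(mk(0, 5, 0, 0, "full")),
               matrix(1, 4, 4))
  expect_equal(phospho_fraction(mk(5, 0, 2, 0, "tqssa")),
               matrix(0, 4, 4))
  # sqssa convention drops the phosphatase complex from the numerator
  expect_equal(phospho_fraction(mk(2, 2, 0, 4, "full"))[1, 1], 6 / 8)
  expect_equal(phospho_fraction(mk(2, 2, 0, 4, "sqssa"))[1, 1], 2 / 8)
  expect_error(phospho_fraction(mk(0, 0, 0, 0, "full")), "zero")
})

test_that("enzyme totals are pointwise invariant when complexes are immobile", {
  sc <- make_scenario("fig4B",
                      overrides = list(n_x = 12, n_y = 12, T = 2, n_t = 5000,
                                       D = gk_diffusion(d_S = 0.2, d_Sp = 0.2,
                                                        d_ES = 0, d_DSp = 0)))
  for (v in c("full", "sqssa", "tqssa")) {
    s <- gk_simulate(sc, v, 4)
    i <- length(s$times)
    ET0 <- s$data[1, , , "E"] + s$data[1, , , "ES"]
    ETn <- s$data[i, , , "E"] + s$data[i, , , "ES"]
    DT0 <- s$data[1, , , "D"] + s$data[1, , , "DSp"]
    DTn <- s$data[i, , , "D"] + s$data[i, , , "DSp"]
    expect_lt(max(abs(ETn - ET0)) / max(ET0), 1e-10)
    expect_lt(max(abs(DTn - DT0)) / max(DT0), 1e-10)
  }
})

test_that("spatially averaged totals are conserved with mobile complexes", {
  sc <- make_scenario("fig4D", overrides = list(T = 0.5, n_t = 600L))
  s <- gk_simulate(sc, "full", 4)
  i <- length(s$times)
  for (tot in list(c("E", "ES"), c("D", "DSp"),
                   c("S", "Sp", "ES", "DSp"))) {
    v0 <- spatial_average(Reduce(`+`, lapply(tot, function(sp) s$data[1, , , sp])),
                          s$grid)
    vn <- spatial_average(Reduce(`+`, lapply(tot, function(sp) s$data[i, , , sp])),
                          s$grid)
    expect_equal(vn, v0, tolerance = 1e-6)
  }
})

test_that("the full model rejects the unstable coarse time step", {
  sc <- make_scenario("fig4B", overrides = list(T = 1, n_t = 91L))
  expect_error(gk_simulate(sc, "full", 4), "unstable")
})
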