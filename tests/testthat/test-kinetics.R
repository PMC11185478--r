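test_that("derived constants match the registered parameter sets", {
  rc <- rate_constants(k_f = 3.4, k_b = 60, k_cat = 3.2)
  dc <- derived_constants(rc)
  expect_equal(dc$K_M, (60 + 3.2) / 3.4)
  expect_lt(abs(dc$K_M - 18.5), 0.1)  # quoted-precision agreement
  expect_equal(dc$K, 3.2 / 3.4)

  gk <- gk_rate_constants(k_fe = 2.22, k_be = 1.84, k_e = 0.38)
  expect_equal(gk$K_ME, 1)
  expect_equal(gk$K_MD, 1)

  expect_equal(derived_constants(rate_constants(1, 0, 0))$K_M, 0)
  expect_error(rate_constants(0, 1, 1), "k_f")
  expect_error(rate_constants(1, -1, 1), "non-negative")
})

test_that("standard-QSS complex matches its defining root", {
  # frozen from the bisection oracle: root of S(E_T - C) = K_M C
  expect_equal(sqss_complex(2, 2, 18.5), 0.1951219512195122, tolerance = 1e-12)
  expect_equal(sqss_complex(2, 2, 18.5), sqss_root_oracle(2, 2, 18.5),
               tolerance = 1e-10)
  expect_equal(sqss_complex(0, 7, 3), 0)
  expect_equal(sqss_complex(5, 7, 0), 7)   # saturation limit
  expect_equal(sqss_complex(0, 7, 0), 0)   # defined by continuity
})

test_that("total-QSS complex equals the bracketed quadratic root", {
  # frozen from the root-finder oracle
  expect_equal(tqss_complex(2, 2, 18.5), 0.1792050872577357, tolerance = 1e-12)
  expect_equal(tqss_complex(0, 5, 2), 0)
  expect_equal(tqss_complex(5, 0, 2), 0)
  expect_equal(tqss_complex(1, 1, 0), 1)   # tight-binding, zero discriminant

  vals <- c(0, 0.37, 2, 18.5, 120, 1000)
  for (S_hat in vals) for (E_T in vals) for (K_M in vals) {
    got <- tqss_complex(S_hat, E_T, K_M)
    want <- tqss_root_oracle(S_hat, E_T, K_M)
    expect_lt(abs(got - want), 1e-10 * max(want, 1e-3))
    expect_lte(got, min(E_T, S_hat) + 1e-12)
  }
})

test_that("total-QSS complex reduces to the MM complex at low enzyme", {
  set.seed(11)
  for (i in 1:50) {
    S_hat <- 10^stats::runif(1, -1, 2)
    K_M <- 10^stats::runif(1, 0, 2)
    E_T <- 1e-4 * (S_hat + K_M)  # eps_sqssa = 1e-4 < 1e-3
    tq <- tqss_complex(S_hat, E_T, K_M)
    sq <- sqss_complex(S_hat, E_T, K_M)
    expect_lt(abs(tq - sq) / sq, 0.01)
  }
})

test_that("validity factors take their analytic values and bounds", {
  rc <- rate_constants(3.4, 60, 3.2)
  vr <- validity_factors(E_T = 2, S_T = 2, K_M = 18.5, rc = rc)
  expect_equal(vr$eps_sqssa, 2 / 20.5)
  expect_equal(vr$eps_es, 3.2 * 2 / (3.4 * 20.5^2))
  vr0 <- validity_factors(0, 2, 18.5, rc)
  expect_equal(vr0$eps_sqssa, 0)
  expect_equal(vr0$eps_tqssa, 0)
  expect_equal(vr0$eps_es, 0)
  expect_error(validity_factors(1, 0, 1, rc), "S_T")

  # scale consistency: doubling concentrations and K_M leaves eps_sqssa alone
  expect_equal(validity_factors(4, 4, 37, rc)$eps_sqssa, vr$eps_sqssa)

  set.seed(7)
  for (i in 1:1000) {
    E_T <- 10^stats::runif(1, -3, 3); S_T <- 10^stats::runif(1, -3, 3)
    K_M <- 10^stats::runif(1, -3, 3); K <- stats::runif(1, 0, 1) * K_M
    kf <- 10^stats::runif(1, -2, 2)
    rci <- rate_constants(kf, kf * (K_M - K), kf * K)
    expect_lt(validity_factors(E_T, S_T, K_M, rci)$eps_tqssa, 0.25)
  }
})

test_that("well-mixed trajectories conserve totals and deplete substrate", {
  rc <- rate_constants(3.4, 60, 3.2)
  sim <- simulate_ode("full", rc, list(S = 300, E = 400), T = 1.25)
  expect_equal(max(abs(sim$E + sim$C - 400)) / 400, 0, tolerance = 1e-8)
  expect_equal(max(abs(sim$S + sim$C + sim$P - 300)) / 300, 0, tolerance = 1e-8)
  expect_true(all(diff(sim$P) >= -1e-10))

  # no enzyme -> no product, in every variant
  for (v in c("full", "sqssa", "tqssa")) {
    s0 <- simulate_ode(v, rc, list(S = 10, E = 0), T = 1)
    expect_equal(max(abs(s0$P)), 0)
  }

  # complete irreversible conversion at long times
  slong <- simulate_ode("full", rc, list(S = 2, E = 2), T = 200)
  expect_equal(slong$P[nrow(slong)], 2, tolerance = 1e-4)
})

test_that("at high enzyme the total-QSSA tracks the full model, the MM law does not", {
  rc <- rate_constants(3.4, 60, 3.2)
  ic <- list(S = 300, E = 400)
  full <- simulate_ode("full", rc, ic, T = 1.25)
  sq <- simulate_ode("sqssa", rc, ic, T = 1.25)
  tq <- simulate_ode("tqssa", rc, ic, T = 1.25)
  err_sq <- max(abs(sq$P - full$P))
  err_tq <- max(abs(tq$P - full$P))
  expect_lt(err_tq, err_sq / 5)
})
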