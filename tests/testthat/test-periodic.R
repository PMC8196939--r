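# Semi-trivial periodic solution: period, closed-form orbit, Floquet
# multiplier (three routes), and the stability theorem.

test_that("the period takes its closed-form value and is transmission-free", {
  expect_equal(sis_period(fig1), 1.25 * log(1.88), tolerance = 1e-14)
  expect_equal(sis_period(fig2b), sis_period(fig1))   # beta-free formula
  expect_lt(sis_period(sis_preset("fig1", q = 1e-9)), 1e-7)   # q -> 0
  expect_error(sis_period(sis_params(A = 7, d = 0.7, beta = 1, v = 4,
                                     theta = 0.1, c = 2.5, b = 1,
                                     q = 0.22, S_T = 9.999999999)), NA)
})

test_that("the closed-form disease-free orbit solves the pulsed subsystem", {
  p <- fig1
  T <- sis_period(p)
  expect_equal(sis_xi(0, p), 6.24)
  expect_equal(sis_xi(T, p), 8, tolerance = 1e-10)
  expect_equal(sis_xi(T / 2, p), 10 - 3.76 * exp(-0.8 * T / 2),
               tolerance = 1e-12)
  # independent check: integrate dS/dt = (d+theta)(A/d - S) numerically
  grid <- seq(0, T, length.out = 41)
  num <- deSolve::lsoda(c(S = 6.24), grid,
                        function(t, y, q) list(0.8 * (10 - y[1])),
                        parms = NULL, rtol = 1e-12, atol = 1e-13)
  expect_equal(sis_xi(grid[-1], p), num[-1, 2], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("closed-form, decomposed, quadrature and simulated multipliers agree", {
  # hand-transcribed closed forms
  expect_equal(sis_mu2(fig1), 1.88^3.5 * exp(-2.2), tolerance = 1e-14)
  expect_equal(sis_mu2(fig2b), 1.88 * exp(-1.76), tolerance = 1e-14)
  for (p in list(fig1, fig2a, fig2b)) {
    mu2 <- sis_mu2(p)
    expect_equal(sis_mu2(p, route = "decomposed"), mu2, tolerance = 1e-12)
    expect_equal(mu2_quadrature_oracle(p), mu2, tolerance = 1e-10)
  }
  # simulation route: transversal perturbation growth over one cycle
  eps <- 1e-6
  for (p in list(fig1, fig2b)) {
    tr <- sis_simulate(p, c(S = (1 - p$q) * p$S_T, I = eps),
                       horizon = 2 * sis_period(p))
    expect_gte(length(tr$impulse_times), 1L)
    expect_equal(unname(tr$pre_states[1, "I"]) / eps, sis_mu2(p),
                 tolerance = 1e-3)
  }
})

test_that("the multiplier limits at q = 0 and S_T = 0 are exactly one", {
  expect_identical(sis_mu2_limit(fig1, q = 0), 1)
  expect_identical(sis_mu2_limit(fig1, S_T = 0), 1)
  expect_equal(sis_mu2_limit(fig1, q = 1e-12), 1, tolerance = 1e-8)
  expect_equal(sis_mu2_limit(fig1, S_T = 1e-12), 1, tolerance = 1e-8)
})

test_that("the multiplier exponent is negative exactly when R0 < 1", {
  for (p in random_params(15, seed = 41)) {
    expo <- -p$d - p$v - p$c / p$b + p$beta * p$A / p$d
    # algebraic identity: exponent numerator = (d+v+c/b)(R0 - 1)
    expect_equal(expo, (p$d + p$v + p$c / p$b) * (sis_R0(p) - 1),
                 tolerance = 1e-10)
    expect_equal(expo < 0, sis_R0(p) < 1)
  }
})

test_that("the semi-trivial solution is stable whenever R0 < 1, and the verdicts match mu2", {
  st1 <- sis_semitrivial(fig1)
  expect_false(st1$stable)
  expect_equal(st1$Delta1, 1.88, tolerance = 1e-14)
  st2 <- sis_semitrivial(fig2b)
  expect_true(st2$stable)       # stable while a stable endemic coexists
  expect_gt(nrow(sis_equilibria(fig2b)$endemics), 0)
  for (p in random_params(20, seed = 53)) {
    if (sis_R0(p) < 1) expect_lt(sis_mu2(p), 1)
  }
  # C1 parameters get the global verdict
  st3 <- sis_semitrivial(sis_preset("fig1", beta = 0.1))
  expect_true(st3$stable)
  expect_true(st3$global)
})
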