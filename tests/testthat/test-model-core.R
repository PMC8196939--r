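# Planar ODE core: vector field, thresholds, equilibria, stability.

test_that("vector field matches hand-evaluated rates and vanishes at equilibria", {
  p <- fig1
  expect_equal(sis_vector_field(c(p$A / p$d, 0), p),
               c(dS = 0, dI = 0))
  # term-by-term hand evaluation at (6.24, 1):
  # dS = 7 - 4.368 - 6.24 + 4 + 0.1*(10 - 7.24) + 2.5/2 = 1.918
  # dI = 6.24 - 4.7 - 1.25 = 0.29
  expect_equal(sis_vector_field(c(6.24, 1), p),
               c(dS = 1.918, dI = 0.29), tolerance = 1e-12)
  # fig2b endemic from the equilibrium quadratic, substituted back
  eq <- sis_equilibria(fig2b)$endemics
  expect_equal(nrow(eq), 1L)
  F <- sis_vector_field(c(eq$S, eq$I), fig2b)
  expect_lt(max(abs(F)), 1e-8)
  expect_error(sis_vector_field(c(8, 5), p), "invariant region")
})

test_that("reproduction number and thresholds take their closed-form values", {
  expect_equal(sis_R0(fig1), 7 / 5.04, tolerance = 1e-14)
  expect_equal(sis_R0(fig2b), 5.6 / 5.04, tolerance = 1e-14)
  expect_lt(sis_R0(sis_preset("fig1", beta = 1e-9, S_T = 5)), 1e-8)

  th1 <- sis_thresholds(fig1)
  expect_equal(th1$A1, 3.99, tolerance = 1e-14)
  expect_equal(th1$Rhat0, 19.6 / (19.6 + 3.01^2), tolerance = 1e-12)
  th2 <- sis_thresholds(fig2b)
  expect_equal(th2$A1, 4.8125, tolerance = 1e-12)
  expect_equal(th2$Rhat0, 12.544 / (12.544 + 1.75^2), tolerance = 1e-12)
  # d^2 + dv + bd*beta = A*beta makes the squared term vanish: Rhat0 = 1
  p_deg <- sis_params(A = 3.99, d = 0.7, beta = 1, v = 4, theta = 0.1,
                      c = 2.5, b = 1, q = 0.22, S_T = 3)
  expect_equal(sis_thresholds(p_deg)$Rhat0, 1, tolerance = 1e-12)
})

test_that("H equals minus the Jacobian trace on the equilibrium line", {
  expect_equal(sis_H(0, fig1), fig1$theta + fig1$d)
  # fig2b endemic: H = 0.8 + 0.8 I* - 2.5 I*/(1+I*)^2 with I* from the quadratic
  Istar <- (3.125 + sqrt(3.125^2 + 4)) / 2
  expect_equal(sis_H(Istar, fig2b),
               0.8 + 0.8 * Istar - 2.5 * Istar / (1 + Istar)^2,
               tolerance = 1e-14)
  expect_equal(sis_H(Istar, fig2b), 3.0963, tolerance = 1e-4)
  expect_equal(sis_H(2, fig1, paper_literal = TRUE) - sis_H(2, fig1),
               fig1$q)
  # -trace(J) at states solving F2 = 0 on S + I = A/d, against a numeric
  # Jacobian of the vector field
  for (p in random_params(6, seed = 11)) {
    roots <- brute_force_endemics(p, n_grid = 4001L)
    for (I in roots) {
      J <- numeric_jacobian(p$A / p$d - I, I, p)
      expect_equal(sis_H(I, p), -(J[1, 1] + J[2, 2]), tolerance = 1e-5)
    }
  }
})

test_that("endemic equilibria follow the quadratic case structure", {
  eq1 <- sis_equilibria(fig1)
  expect_equal(eq1$a1, -4.3, tolerance = 1e-12)
  expect_equal(eq1$a2, -2.8, tolerance = 1e-12)
  expect_equal(eq1$endemics$I, (4.3 + sqrt(4.3^2 + 4 * 2.8)) / 2,
               tolerance = 1e-12)
  expect_match(eq1$endemics$stability, "stable")
  expect_gt(eq1$endemics$H, 0)

  eq2 <- sis_equilibria(fig2b)
  expect_equal(eq2$a1, -3.125, tolerance = 1e-12)
  expect_equal(eq2$a2, -1, tolerance = 1e-12)
  expect_equal(eq2$endemics$I, (3.125 + sqrt(3.125^2 + 4)) / 2,
               tolerance = 1e-12)
  expect_equal(eq2$endemics$S, 10 - eq2$endemics$I, tolerance = 1e-12)

  # R0 < 1 with A <= A1: no endemic equilibrium
  p_low <- sis_preset("fig1", beta = 0.1, S_T = 8)
  eq_low <- sis_equilibria(p_low)
  expect_equal(nrow(eq_low$endemics), 0L)
  expect_identical(eq_low$case, "C1")
})

test_that("case classification matches the printed conditions", {
  expect_identical(sis_classify_case(fig1), "C2")
  expect_identical(sis_classify_case(fig2b), "C2")
  expect_identical(sis_classify_case(sis_preset("fig1", beta = 0.1)), "C1")
  # exact R0 = 1 flagged as boundary, not forced into a branch
  p_b <- sis_preset("fig1", beta = 0.72)
  expect_equal(sis_R0(p_b), 1, tolerance = 1e-15)
  expect_identical(sis_equilibria(p_b)$case, "boundary")
})

test_that("DFE eigenvalues are negative exactly when R0 < 1", {
  for (p in random_params(12, seed = 23)) {
    J <- numeric_jacobian(p$A / p$d, 0, p)
    lam <- eigen(J, only.values = TRUE)$values
    expect_equal(all(Re(lam) < 0), sis_R0(p) < 1)
  }
})

test_that("quadratic roots agree with a brute-force two-equation scan", {
  for (p in c(list(fig1, fig2b, sis_preset("fig1", beta = 0.1)),
              random_params(6, seed = 37))) {
    bf <- brute_force_endemics(p)
    eq <- sis_equilibria(p)$endemics
    expect_equal(sum(eq$multiplicity), length(bf))
    if (length(bf))
      expect_equal(sort(eq$I), sort(bf), tolerance = 1e-8)
  }
})

test_that("a beta sweep through the backward-bifurcation window gives 0 -> 2 -> 1 equilibria", {
  counts <- vapply(c(0.6, 0.7, 0.8), function(beta) {
    p <- sis_preset("fig1", beta = beta)
    th <- sis_thresholds(p)
    expect_gt(p$A, th$A1)
    eq <- sis_equilibria(p)
    expect_equal(sum(eq$endemics$multiplicity),
                 length(brute_force_endemics(p)))
    nrow(eq$endemics)
  }, 0L)
  expect_equal(counts, c(0L, 2L, 1L))
  # in the two-equilibrium window the smaller one is a saddle
  eqw <- sis_equilibria(sis_preset("fig1", beta = 0.7))$endemics
  expect_identical(eqw$stability[which.min(eqw$I)], "saddle")
})

test_that("the invariant region D is forward invariant under the flow", {
  p <- fig2b
  for (init in list(c(S = 6, I = 3.9), c(S = 0.5, I = 0.5),
                    c(S = 2, I = 7.9))) {
    tr <- sis_simulate(p, init, horizon = 15)
    df <- as.data.frame(tr)
    expect_gt(min(df$S), -1e-6)
    expect_gt(min(df$I), -1e-6)
    expect_lt(max(df$S + df$I), p$A / p$d + 1e-6)
  }
})
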