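# Critical parameter values where the Floquet multiplier crosses one, and
# bifurcation classification of the Poincare map.

test_that("closed-form multiplier derivatives match central finite differences", {
  fd <- function(p, wrt, h) {
    f <- switch(wrt,
                q = function(x) sis_mu2_limit(p, q = x),
                S_T = function(x) sis_mu2_limit(p, S_T = x),
                A = function(x) sis_mu2_limit(p, A = x))
    x0 <- p[[wrt]]
    (f(x0 + h) - f(x0 - h)) / (2 * h)
  }
  for (p in c(list(fig1, fig2b), random_params(4, seed = 61))) {
    for (wrt in c("q", "S_T", "A")) {
      expect_equal(sis_mu2_partial(p, wrt), fd(p, wrt, 1e-6),
                   tolerance = 1e-6)
    }
  }
  # sign at the fig1 baseline: beta(1-q)S_T - d - v - c/b = 6.24 - 7.2 < 0
  expect_lt(sis_mu2_partial(fig1, "q"), 0)
})

test_that("the q-derivative vanishes at q_tilde, the turning point of mu2(q)", {
  expect_equal(sis_q_tilde(fig1), 1 - 7.2 / 8, tolerance = 1e-14)
  p_at <- sis_preset("fig1", q = sis_q_tilde(fig1))
  expect_equal(sis_mu2_partial(p_at, "q"), 0, tolerance = 1e-12)
  # mu2(q) increases before q_tilde and decreases after
  expect_gt(sis_mu2_limit(fig1, q = 0.09), sis_mu2_limit(fig1, q = 0.05))
  expect_gt(sis_mu2_limit(fig1, q = 0.15), sis_mu2_limit(fig1, q = 0.5))
})

test_that("critical vaccination fraction: existence branches and root contract", {
  res <- sis_critical_q(fig1)
  expect_equal(res$critical_value, 0.2236604, tolerance = 1e-6)
  expect_lt(abs(res$mu2_at_critical - 1), 1e-8)
  # stability flips across the root (mu2 decreasing there)
  expect_gt(sis_mu2_limit(fig1, q = res$critical_value - 1e-3), 1)
  expect_lt(sis_mu2_limit(fig1, q = res$critical_value + 1e-3), 1)

  # S_T below (b(d+v)+c)/(b beta) = 7.2: mu2 decreasing on (0,1), no root
  res2 <- sis_critical_q(sis_preset("fig1", S_T = 7))
  expect_true(is.na(res2$critical_value))
  expect_match(res2$existence_case, "decreasing")

  # weak recovery/treatment with mu2(1) >= 1: unstable for every q
  p_un <- sis_params(A = 7, d = 0.7, beta = 1, v = 0.5, theta = 0.1,
                     c = 0.5, b = 1, q = 0.5, S_T = 9.5)
  expect_gte(sis_mu2_limit(p_un, q = 1), 1)
  res3 <- sis_critical_q(p_un)
  expect_true(is.na(res3$critical_value))
  expect_match(res3$existence_case, "unstable for all q")
})

test_that("critical threshold: turning-point quadratic, ordering, and root", {
  res <- sis_critical_ST(fig1)
  # roots of 0.546 S^2 - 12.46 S + 50.4 = 0
  expect_equal(res$S_bar_T1, (12.46 - sqrt(12.46^2 - 4 * 0.546 * 50.4)) /
                 (2 * 0.546), tolerance = 1e-10)
  expect_equal(res$S_bar_T2, (12.46 + sqrt(12.46^2 - 4 * 0.546 * 50.4)) /
                 (2 * 0.546), tolerance = 1e-10)
  expect_true(0 < res$S_bar_T1 && res$S_bar_T1 < 10 && 10 < res$S_bar_T2)
  expect_gt(res$critical_value, 7.9)
  expect_lt(res$critical_value, 8.0)
  expect_lt(abs(res$mu2_at_critical - 1), 1e-8)
  expect_lt(sis_mu2_limit(fig1, S_T = res$critical_value - 1e-3), 1)
  expect_gt(sis_mu2_limit(fig1, S_T = res$critical_value + 1e-3), 1)
  expect_error(sis_critical_ST(sis_preset("fig1", beta = 0.1)), "R0 > 1")
})

test_that("K(q) bounds the turning-point discriminant", {
  expect_identical(sis_K(0), 1)
  qs <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(sis_K(qs) < 1))
  expect_true(all(diff(sis_K(qs)) < 0))
  # hence the discriminant (q-2)^2 - 4(1-q)/R0 is positive whenever R0 > 1
  R0 <- sis_R0(fig1)
  expect_true(all((qs - 2)^2 - 4 * (1 - qs) / R0 > 0))
})

test_that("critical recruitment rate: endpoint limits and root", {
  res <- sis_critical_A(fig1)
  expect_gt(res$critical_value, 7.2)
  expect_lt(res$critical_value, 7.4)
  expect_lt(abs(res$mu2_at_critical - 1), 1e-8)
  expect_equal(res$mu2_at_infinity, exp(-2.2), tolerance = 1e-12)
  # divergence at the left endpoint A -> d S_T
  expect_gt(sis_mu2_limit(fig1, A = fig1$d * fig1$S_T + 1e-6), 1e4)
  expect_gt(sis_mu2_limit(fig1, A = fig1$d * fig1$S_T + 1e-9), 1e7)
  # stability flips: unstable below A*, stable above
  expect_gt(sis_mu2_limit(fig1, A = res$critical_value - 1e-3), 1)
  expect_lt(sis_mu2_limit(fig1, A = res$critical_value + 1e-3), 1)
  expect_lt(res$B1_at_root, 0)   # mu2 decreasing through the root
})

test_that("g''(0) shrinks with the pulse and its two routes agree at criticality", {
  # vanishing pulse: zero-length integration interval
  expect_lt(abs(sis_g2(sis_preset("fig1", q = 1e-9))), 1e-6)
  res <- sis_classify_bifurcation(fig1, "q")
  expect_equal(sis_dP1(0, res$params, order = 2L), res$g2,
               tolerance = 1e-2)
  expect_identical(res$bif_type, "transcritical")
})

test_that("cross-derivative signs at the critical points are -, +, -", {
  res_q <- sis_classify_bifurcation(fig1, "q")
  expect_lt(res_q$cross_derivative, 0)
  res_s <- sis_classify_bifurcation(fig1, "S_T")
  expect_gt(res_s$cross_derivative, 0)
  res_a <- sis_classify_bifurcation(fig1, "A")
  expect_lt(res_a$cross_derivative, 0)
  # the three critical points straddle the baseline consistently with
  # mu2(baseline) barely above 1
  expect_gt(sis_mu2(fig1), 1)
  expect_gt(res_q$critical_value, fig1$q)     # raising q stabilises
  expect_lt(res_s$critical_value, fig1$S_T)   # lowering S_T stabilises
  expect_gt(res_a$critical_value, fig1$A)     # raising A stabilises
})

test_that("parameter scans localise the stability exchange", {
  sc <- sis_scan(fig1, "S_T", seq(6, 9.5, length.out = 141))
  flips <- which(diff(sign(sc$mu2 - 1)) != 0)
  expect_length(flips, 1L)
  expect_gt(sc$value[flips], 7.9)
  expect_lte(sc$value[flips + 1], 8.0)

  scq <- sis_scan(fig1, "q", seq(0.02, 0.98, length.out = 97))
  peak <- which.max(scq$mu2)
  expect_equal(scq$value[peak], sis_q_tilde(fig1), tolerance = 0.02)
  after <- scq$mu2[scq$value > sis_q_tilde(fig1) + 0.02]
  expect_true(all(diff(after) < 0))

  sca <- sis_scan(fig1, "A", seq(5.7, 12, length.out = 127))
  expect_length(which(diff(sign(sca$mu2 - 1)) != 0), 1L)
  expect_false(any(sca$status != "ok"))
})
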