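# Critical parameter values where the Floquet multiplier of the
# disease-free periodic solution crosses 1, the map-derivative
# coefficients g''(0), g'''(0), and transcritical-vs-pitchfork
# classification of the resulting bifurcation of the Poincare map.

# mu2 as a function of one varied parameter, others from p
.sis_mu2_of <- function(p, wrt) {
  switch(wrt,
    q = function(x) .sis_mu2_raw(p$A, p$d, p$beta, p$v, p$theta, p$c, p$b,
                                 x, p$S_T),
    S_T = function(x) .sis_mu2_raw(p$A, p$d, p$beta, p$v, p$theta, p$c, p$b,
                                   p$q, x),
    A = function(x) .sis_mu2_raw(x, p$d, p$beta, p$v, p$theta, p$c, p$b,
                                 p$q, p$S_T))
}

.sis_with <- function(p, wrt, value) {
  q <- unclass(p); q[[wrt]] <- value
  class(q) <- "sis_params"
  q
}

#' Partial derivatives of the Floquet multiplier
#'
#' Closed-form \eqn{\partial\mu_2/\partial\alpha} for
#' \eqn{\alpha \in \{q, S_T, A\}}, obtained by differentiating
#' \eqn{\ln\mu_2}:
#' \deqn{\partial_q\mu_2 = \frac{\mu_2 d S_T (\beta(1-q)S_T - d - v - c/b)}
#'   {(d+\theta)(A - d(1-q)S_T)},}
#' \deqn{\partial_{S_T}\mu_2 = \frac{q\mu_2}{d+\theta}
#'   \Big(\frac{dA(\beta A/d - d - v - c/b)}{(A-dS_T)(A-d(1-q)S_T)} - \beta\Big),}
#' \deqn{\partial_A\mu_2 = \frac{\beta\mu_2}{d+\theta}
#'   \Big(\frac{1}{d}\ln\Delta_1 -
#'   \frac{(A/d - (d+v+c/b)/\beta)\,d q S_T}{(A-d(1-q)S_T)(A-dS_T)}\Big).}
#'
#' The A-derivative's log term carries the \eqn{1/d} factor required for
#' consistency with the finite difference of the closed-form \eqn{\mu_2};
#' \code{paper_literal = TRUE} drops it (a variant circulating in the
#' literature), for comparison only.
#'
#' @param params a [sis_params()] object.
#' @param wrt one of \code{"q"}, \code{"S_T"}, \code{"A"}.
#' @param paper_literal use the literal (inconsistent) A-derivative.
#' @return Scalar derivative.
#' @export
sis_mu2_partial <- function(params, wrt = c("q", "S_T", "A"),
                            paper_literal = FALSE) {
  p <- params
  wrt <- match.arg(wrt)
  mu2 <- .sis_mu2_params(p)
  u <- p$A - p$d * (1 - p$q) * p$S_T
  w <- p$A - p$d * p$S_T
  k <- p$d + p$v + p$c / p$b
  switch(wrt,
    q = mu2 * p$d * p$S_T * (p$beta * (1 - p$q) * p$S_T - k) /
      ((p$d + p$theta) * u),
    S_T = p$q * mu2 / (p$d + p$theta) *
      (p$d * p$A * (p$beta * p$A / p$d - k) / (w * u) - p$beta),
    A = {
      logterm <- if (paper_literal) log(u / w) else log(u / w) / p$d
      p$beta * mu2 / (p$d + p$theta) *
        (logterm - (p$A / p$d - k / p$beta) * p$d * p$q * p$S_T / (u * w))
    })
}

#' Vaccination-fraction turning point of the multiplier
#'
#' \eqn{\tilde q = 1 - (b(d+v)+c)/(b\beta S_T)}: the zero in \eqn{q} of
#' the factor \eqn{\beta(1-q)S_T - d - v - c/b} that fixes the sign of
#' \eqn{\partial\mu_2/\partial q}.  When \eqn{\tilde q \in (0,1)} (i.e.
#' \eqn{S_T > (b(d+v)+c)/(b\beta)}), \eqn{\mu_2(q)} increases on
#' \eqn{(0,\tilde q)} and decreases on \eqn{(\tilde q, 1)}.
#' \code{paper_literal = TRUE} uses \eqn{b(b+v)+c} in place of
#' \eqn{b(d+v)+c} (a variant inconsistent with the derivative factor),
#' for comparison only.
#'
#' @param params a [sis_params()] object.
#' @param paper_literal use the literal variant.
#' @return \eqn{\tilde q} (may fall outside (0,1), meaning \eqn{\mu_2(q)}
#'   is monotone on (0,1)).
#' @export
sis_q_tilde <- function(params, paper_literal = FALSE) {
  p <- params
  num <- if (paper_literal) p$b * (p$b + p$v) + p$c
         else p$b * (p$d + p$v) + p$c
  1 - num / (p$b * p$beta * p$S_T)
}

#' K(q) discriminant bound for the threshold bifurcation
#'
#' \eqn{K(q) = 4(1-q)/(q-2)^2}.  The quadratic locating the turning
#' points of \eqn{\mu_2(S_T)} has positive discriminant iff
#' \eqn{R_0 > K(q)}; since \eqn{K(0) = 1} and \eqn{K} is strictly
#' decreasing on (0,1), \eqn{R_0 > 1} always suffices.
#'
#' @param q vaccination fraction(s) in \eqn{[0, 1)}; vectorised.
#' @return Value(s) of K.
#' @export
sis_K <- function(q) {
  stopifnot(all(q >= 0), all(q < 1))
  4 * (1 - q) / (q - 2)^2
}

.sis_bif_result <- function(parameter, critical_value, p_crit,
                            existence_case, compute_g = TRUE,
                            tol_g = 1e-4) {
  mu2_slope <- sis_mu2_partial(p_crit, parameter)
  g2 <- g3 <- NA_real_
  bif_type <- NA_character_
  if (compute_g) {
    g2 <- sis_g2(p_crit)
    if (abs(g2) > tol_g) {
      bif_type <- "transcritical"
    } else {
      g3 <- sis_dP1(0, p_crit, order = 3L)
      bif_type <- if (abs(g3) > tol_g) "pitchfork" else "inconclusive"
    }
  }
  structure(list(parameter = parameter, critical_value = critical_value,
                 mu2_at_critical = .sis_mu2_params(p_crit),
                 mu2_cross_slope = sign(mu2_slope),
                 cross_derivative = mu2_slope,
                 g2 = g2, g3 = g3, bif_type = bif_type,
                 existence_case = existence_case, params = p_crit),
            class = "sis_bifurcation")
}

#' @export
print.sis_bifurcation <- function(x, ...) {
  cat("Bifurcation of the semi-trivial solution in ", x$parameter, "\n",
      sep = "")
  if (is.na(x$critical_value)) {
    cat("  no critical value:", x$existence_case, "\n")
    return(invisible(x))
  }
  cat(sprintf("  critical value: %s* = %.10g (mu2 = %.12g there)\n",
              x$parameter, x$critical_value, x$mu2_at_critical))
  cat(sprintf("  d(mu2)/d%s at critical = %.6g (sign %+d)\n",
              x$parameter, x$cross_derivative, x$mu2_cross_slope))
  if (!is.na(x$g2))
    cat(sprintf("  g''(0) = %.6g%s -> %s\n", x$g2,
                if (!is.na(x$g3)) sprintf(", g'''(0) = %.6g", x$g3) else "",
                x$bif_type))
  cat("  existence branch:", x$existence_case, "\n")
  invisible(x)
}

#' Critical vaccination fraction
#'
#' Finds \eqn{q_1^* \in (0,1)} with \eqn{\mu_2(q_1^*) = 1}, treating
#' \code{params$q} as the varied coordinate.  Since \eqn{\mu_2(0^+) = 1}
#' and \eqn{\mu_2(q)} rises to a maximum at \eqn{\tilde q} and then
#' falls, the three existence branches are: no root when
#' \eqn{S_T < (b(d+v)+c)/(b\beta)} (multiplier decreasing on (0,1), so
#' below 1 throughout); no root when \eqn{\mu_2(1) \ge 1}; otherwise a
#' unique root in \eqn{(\tilde q, 1)}, located by bisection to
#' \eqn{|\mu_2 - 1| < 10^{-8}}.
#'
#' @param params a [sis_params()] object (its \code{q} is ignored).
#' @param classify also estimate \eqn{g''(0)}, \eqn{g'''(0)} and the
#'   bifurcation type at the critical point (costs ODE integrations).
#' @return A \code{"sis_bifurcation"} object; \code{critical_value} is
#'   \code{NA} when no root exists (the branch label says why).
#' @export
#' @examples
#' sis_critical_q(sis_preset("fig1"), classify = FALSE)
sis_critical_q <- function(params, classify = FALSE) {
  p <- params
  qt <- sis_q_tilde(p)
  mu2_of_q <- .sis_mu2_of(p, "q")
  if (qt <= 0)
    return(.sis_bif_result("q", NA_real_, p,
      "mu2 decreasing on (0,1): S_T < (b(d+v)+c)/(b*beta), no root",
      compute_g = FALSE))
  if (mu2_of_q(1) >= 1)
    return(.sis_bif_result("q", NA_real_, p,
      "mu2(1) >= 1: semi-trivial solution unstable for all q, no root",
      compute_g = FALSE))
  r <- stats::uniroot(function(q) mu2_of_q(q) - 1, c(qt, 1 - 1e-12),
                      tol = 1e-14)
  .sis_bif_result("q", r$root, .sis_with(p, "q", r$root),
                  "root in (q_tilde, 1) with mu2(1) < 1",
                  compute_g = classify)
}

#' Critical susceptible threshold
#'
#' Finds \eqn{S_T^*} with \eqn{\mu_2(S_T^*) = 1}, treating
#' \code{params$S_T} as the varied coordinate.  Requires \eqn{R_0 > 1}.
#' The turning points of \eqn{\mu_2(S_T)} solve
#' \eqn{\beta d(1-q)\bar S_T^2 + \beta A(q-2)\bar S_T + A(d+v+c/b) = 0},
#' whose discriminant is positive because \eqn{R_0 > 1 > K(q)}; the roots
#' straddle the carrying level, \eqn{0 < \bar S_{T1} < A/d < \bar S_{T2}},
#' so \eqn{\mu_2} decreases on \eqn{(0, \bar S_{T1})} and increases on
#' \eqn{(\bar S_{T1}, A/d)}, diverging as \eqn{S_T \to A/d}.  With
#' \eqn{\mu_2(0^+) = 1} this gives a unique root in
#' \eqn{(\bar S_{T1}, A/d)}.
#'
#' @inheritParams sis_critical_q
#' @return A \code{"sis_bifurcation"} object; also carries
#'   \code{S_bar_T1}, \code{S_bar_T2} and \code{K_q}.
#' @export
sis_critical_ST <- function(params, classify = FALSE) {
  p <- params
  R0 <- sis_R0(p)
  if (R0 <= 1)
    stop("critical S_T requires R0 > 1 (here R0 = ", format(R0), ")",
         call. = FALSE)
  Kq <- sis_K(p$q)
  disc <- (p$q - 2)^2 - 4 * (1 - p$q) / R0    # > 0 since R0 > 1 > K(q)
  Ad <- p$A / p$d
  S1 <- Ad * (-(p$q - 2) - sqrt(disc)) / (2 * (1 - p$q))
  S2 <- Ad * (-(p$q - 2) + sqrt(disc)) / (2 * (1 - p$q))
  mu2_of <- .sis_mu2_of(p, "S_T")
  r <- stats::uniroot(function(s) mu2_of(s) - 1,
                      c(S1, Ad * (1 - 1e-12)), tol = 1e-14)
  out <- .sis_bif_result("S_T", r$root, .sis_with(p, "S_T", r$root),
                         "unique root in (S_bar_T1, A/d), R0 > 1",
                         compute_g = classify)
  out$S_bar_T1 <- S1; out$S_bar_T2 <- S2; out$K_q <- Kq
  out
}

#' Critical recruitment rate
#'
#' Finds \eqn{A^*} with \eqn{\mu_2(A^*) = 1}, treating \code{params$A} as
#' the varied coordinate on \eqn{(dS_T, \infty)}.  The endpoint limits
#' \eqn{\mu_2(A) \to +\infty} as \eqn{A \downarrow dS_T} and
#' \eqn{\mu_2(A) \to e^{-\beta q S_T/(d+\theta)} < 1} as
#' \eqn{A \to \infty} guarantee a sign change, bracketed by doubling the
#' upper endpoint and refined by bisection.  The diagnostic
#' \eqn{B_1(A) = \ln(\Delta_1)/d - (A/d-(d+v+c/b)/\beta) dqS_T /
#' ((A-d(1-q)S_T)(A-dS_T))} (proportional to \eqn{\partial\mu_2/\partial A})
#' is reported at the root.
#'
#' @inheritParams sis_critical_q
#' @param A_cap give up if no sign change is found below this multiple of
#'   \eqn{dS_T}.
#' @return A \code{"sis_bifurcation"} object; also carries \code{B1_at_root}
#'   and the endpoint limit \code{mu2_at_infinity}.
#' @export
sis_critical_A <- function(params, classify = FALSE, A_cap = 2^20) {
  p <- params
  mu2_of <- .sis_mu2_of(p, "A")
  lo <- p$d * p$S_T * (1 + 1e-9)
  hi <- max(p$A, p$d * p$S_T * 2)
  while (mu2_of(hi) >= 1) {
    hi <- hi * 2
    if (hi > A_cap * p$d * p$S_T)
      stop("no sign change of mu2(A) - 1 found below the cap", call. = FALSE)
  }
  r <- stats::uniroot(function(a) mu2_of(a) - 1, c(lo, hi), tol = 1e-14)
  p_crit <- .sis_with(p, "A", r$root)
  out <- .sis_bif_result("A", r$root, p_crit,
                         "unique root in (d*S_T, Inf) by endpoint limits",
                         compute_g = classify)
  u <- r$root - p$d * (1 - p$q) * p$S_T
  w <- r$root - p$d * p$S_T
  k <- p$d + p$v + p$c / p$b
  out$B1_at_root <- log(u / w) / p$d -
    (r$root / p$d - k / p$beta) * p$d * p$q * p$S_T / (u * w)
  out$mu2_at_infinity <- exp(-p$beta * p$q * p$S_T / (p$d + p$theta))
  out
}

#' Second map derivative at the origin by quadrature
#'
#' Computes \eqn{g''(0) = \mu_2 \int_{(1-q)S_T}^{S_T} m(s)\,
#' \partial I(s,0)/\partial I_0 \, ds}, where
#' \eqn{m(s) = \partial^2 h/\partial I^2} at \eqn{I = 0} for the
#' phase-plane slope field \eqn{h = F_2/F_1}, and
#' \eqn{\partial I(s,0)/\partial I_0} is the closed-form linearisation of
#' the transit map along the disease-free orbit.  This is the quadrature
#' route to the same quantity that [sis_dP1()] with \code{order = 2}
#' estimates by finite differences; the two agreeing is a strong check on
#' both.
#'
#' @param params a [sis_params()] object.
#' @return Scalar \eqn{g''(0)}.
#' @export
sis_g2 <- function(params) {
  p <- params
  mu2 <- .sis_mu2_params(p)
  lo <- (1 - p$q) * p$S_T
  kk <- p$d + p$v + p$c / p$b
  E <- (p$beta * p$A / p$d - kk) / (p$d + p$theta)
  m <- function(s) {
    F10 <- (p$d + p$theta) * (p$A / p$d - s)
    phi0 <- p$beta * s - kk
    psi0 <- -p$beta * s + p$v - p$theta + p$c / p$b
    (2 * p$c / p$b^2 * F10 - 2 * phi0 * psi0) / F10^2
  }
  J <- function(s)
    ((p$A - p$d * lo) / (p$A - p$d * s))^E *
      exp(-p$beta * (s - lo) / (p$d + p$theta))
  int <- stats::integrate(function(s) m(s) * J(s), lo, p$S_T,
                          rel.tol = 1e-10)$value
  mu2 * int
}

#' Classify the bifurcation at a critical parameter value
#'
#' Locates the critical value of the chosen parameter (via
#' [sis_critical_q()], [sis_critical_ST()] or [sis_critical_A()]) and
#' classifies the bifurcation the Poincare map undergoes there from its
#' derivatives at the trivial fixed point: \code{transcritical} when
#' \eqn{|g''(0)|} exceeds a tolerance (default \eqn{10^{-4}\mu_2}, i.e.
#' \eqn{10^{-4}} at the critical point), else \code{pitchfork} when
#' \eqn{|g'''(0)|} does, else \code{inconclusive} (below the combined
#' quadrature/finite-difference noise floor the sign is not trustworthy).
#' The sign of the cross derivative
#' \eqn{\partial^2 P_1/\partial I_0 \partial\alpha =
#' \partial\mu_2/\partial\alpha} is recorded; it is negative at
#' \eqn{q_1^*} and \eqn{A^*} and positive at \eqn{S_T^*}.
#'
#' @param params a [sis_params()] object (baseline family).
#' @param wrt one of \code{"q"}, \code{"S_T"}, \code{"A"}.
#' @param tol_g tolerance separating transcritical from
#'   pitchfork/inconclusive.
#' @return A \code{"sis_bifurcation"} object with \code{g2}, \code{g3},
#'   \code{bif_type} filled in.
#' @export
sis_classify_bifurcation <- function(params, wrt = c("q", "S_T", "A"),
                                     tol_g = 1e-4) {
  wrt <- match.arg(wrt)
  res <- switch(wrt,
                q = sis_critical_q(params, classify = FALSE),
                S_T = sis_critical_ST(params, classify = FALSE),
                A = sis_critical_A(params, classify = FALSE))
  if (is.na(res$critical_value))
    stop("no critical value exists for ", wrt, ": ", res$existence_case,
         call. = FALSE)
  out <- .sis_bif_result(wrt, res$critical_value, res$params,
                         res$existence_case, compute_g = TRUE,
                         tol_g = tol_g)
  for (extra in setdiff(names(res), names(out))) out[[extra]] <- res[[extra]]
  out
}

#' One-parameter scan of the semi-trivial solution's stability
#'
#' Evaluates \eqn{\mu_2} (same code path as [sis_mu2()]) and the stability
#' verdict over a grid of one parameter, optionally locating the positive
#' Poincare-map fixed points at each grid point.  Per-point failures
#' (invalid parameters, unknown domain) are recorded in \code{status},
#' never aborting the scan.
#'
#' @param params a [sis_params()] baseline.
#' @param wrt one of \code{"q"}, \code{"S_T"}, \code{"A"}.
#' @param values grid of parameter values.
#' @param fixed_points also search for positive fixed points (slow: ODE
#'   integrations per grid point).
#' @return Data frame with columns \code{parameter}, \code{value},
#'   \code{mu2}, \code{stable}, \code{n_fixed}, \code{I_fix_max},
#'   \code{status}.
#' @export
sis_scan <- function(params, wrt = c("q", "S_T", "A"), values,
                     fixed_points = FALSE) {
  p <- params
  wrt <- match.arg(wrt)
  mu2_of <- .sis_mu2_of(p, wrt)
  rows <- lapply(values, function(x) {
    row <- data.frame(parameter = wrt, value = x, mu2 = NA_real_,
                      stable = NA, n_fixed = NA_integer_,
                      I_fix_max = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    mu2 <- tryCatch(mu2_of(x), error = function(e) NA_real_)
    if (is.na(mu2)) { row$status <- "invalid parameter value"; return(row) }
    row$mu2 <- mu2
    row$stable <- mu2 < 1
    if (fixed_points) {
      fp <- tryCatch(
        suppressWarnings(sis_fixed_points(.sis_with(p, wrt, x))),
        error = function(e) NULL)
      if (is.null(fp)) {
        row$status <- "fixed-point search failed"
      } else {
        row$n_fixed <- nrow(fp)
        if (nrow(fp)) row$I_fix_max <- max(fp$I_fix)
      }
    }
    row
  })
  do.call(rbind, rows)
}
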