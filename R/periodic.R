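# The semi-trivial (disease-free) periodic solution: closed-form orbit,
# period, and Floquet multiplier governing its orbital stability.

# raw closed-form evaluators on bare numerics: these accept the boundary
# values q = 0 and S_T = 0 (and are monotone limits there), which the
# sis_params invariants deliberately exclude.  Used by the bifurcation
# solvers and the limit-evaluation entry points.
.sis_period_raw <- function(A, d, theta, q, S_T) {
  if (S_T >= A / d) stop("period undefined: S_T >= A/d", call. = FALSE)
  log((A - d * (1 - q) * S_T) / (A - d * S_T)) / (d + theta)
}

.sis_mu2_raw <- function(A, d, beta, v, theta, c, b, q, S_T) {
  if (S_T >= A / d) stop("mu2 undefined: S_T >= A/d", call. = FALSE)
  Delta1 <- (A - d * (1 - q) * S_T) / (A - d * S_T)
  expo <- (-d - v - c / b + beta * A / d) / (d + theta)
  Delta1^expo * exp(-beta * q * S_T / (d + theta))
}

.sis_mu2_params <- function(p) {
  .sis_mu2_raw(p$A, p$d, p$beta, p$v, p$theta, p$c, p$b, p$q, p$S_T)
}

#' Period of the semi-trivial periodic solution
#'
#' On the disease-free manifold \eqn{I = 0} the susceptibles follow
#' \eqn{dS/dt = (d+\theta)(A/d - S)}; starting from \eqn{(1-q)S_T} the
#' threshold is reached after
#' \deqn{T = \frac{1}{d+\theta} \ln\frac{A - d(1-q)S_T}{A - d S_T},}
#' which is independent of \eqn{\beta, v, c, b}.
#'
#' @param params a [sis_params()] object.
#' @return Positive scalar.
#' @export
#' @examples
#' sis_period(sis_preset("fig1"))
sis_period <- function(params) {
  p <- params
  .sis_period_raw(p$A, p$d, p$theta, p$q, p$S_T)
}

#' Closed-form disease-free orbit
#'
#' Evaluates \eqn{\xi(t) = A/d - (A/d - (1-q)S_T) e^{-(d+\theta)t}}, the
#' S-component of the semi-trivial periodic solution, with \eqn{t} reduced
#' modulo the period so that \eqn{\xi(0^+) = (1-q)S_T} and
#' \eqn{\xi(T) = S_T}.
#'
#' @param t time(s), nonnegative; vectorised.
#' @param params a [sis_params()] object.
#' @return Susceptible level(s).
#' @export
sis_xi <- function(t, params) {
  p <- params
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  T <- sis_period(p)
  tm <- t %% T
  tm[tm == 0 & t > 0] <- T   # right endpoint of a cycle, not its restart
  p$A / p$d - (p$A / p$d - (1 - p$q) * p$S_T) * exp(-(p$d + p$theta) * tm)
}

#' Floquet multiplier of the semi-trivial periodic solution
#'
#' The multiplier governing transversal (infective-direction) stability of
#' the disease-free periodic orbit:
#' \deqn{\mu_2 = \Big(\frac{A-d(1-q)S_T}{A-dS_T}\Big)^{\frac{-d-v-c/b+\beta A/d}{d+\theta}}
#'   \exp\Big(-\frac{\beta q S_T}{d+\theta}\Big) > 0.}
#' The orbit is orbitally asymptotically stable iff \eqn{\mu_2 < 1}.  The
#' exponent's numerator equals \eqn{(d+v+c/b)(R_0-1)}, so for
#' \eqn{R_0 < 1} the power factor is below one and stability follows.
#'
#' \code{route = "decomposed"} recomputes \eqn{\mu_2} as the product of the
#' impulse jump factor
#' \eqn{\Delta_1 = (A-d(1-q)S_T)/(A-dS_T)} and
#' \eqn{\exp\int_0^T (\partial_S F_1 + \partial_I F_2)(\xi(t),0)\,dt}
#' with the integral done by adaptive quadrature — an independent code
#' path used for cross-checking.
#'
#' @param params a [sis_params()] object.
#' @param route \code{"closed"} (default) or \code{"decomposed"}.
#' @return Positive scalar.
#' @export
#' @examples
#' sis_mu2(sis_preset("fig2b"))   # < 1: stable disease-free cycle
sis_mu2 <- function(params, route = c("closed", "decomposed")) {
  p <- params
  route <- match.arg(route)
  if (route == "closed") return(.sis_mu2_params(p))
  Delta1 <- (p$A - p$d * (1 - p$q) * p$S_T) / (p$A - p$d * p$S_T)
  T <- sis_period(p)
  divergence <- function(t) {
    xi <- p$A / p$d -
      (p$A / p$d - (1 - p$q) * p$S_T) * exp(-(p$d + p$theta) * t)
    -2 * p$d - p$theta - p$v - p$c / p$b + p$beta * xi
  }
  int <- stats::integrate(divergence, 0, T, rel.tol = 1e-13,
                          abs.tol = 1e-14)$value
  Delta1 * exp(int)
}

#' Limit evaluation of the Floquet multiplier
#'
#' Evaluates the closed-form \eqn{\mu_2} with \code{q} and/or \code{S_T}
#' overridden, including the boundary values \eqn{q = 0} and
#' \eqn{S_T = 0} that the parameter-object invariants exclude (both limits
#' give \eqn{\mu_2 = 1}: with no pulse, or with the pulse at zero
#' susceptibles, the jump factor and the integral contribution cancel).
#' Also accepts an \code{A} override for recruitment-rate sweeps, where
#' the admissible range is \eqn{A > d\,S_T} rather than the constructor's
#' \eqn{S_T < A/d}.
#'
#' @param params a [sis_params()] object supplying the baseline.
#' @param q,S_T,A optional overrides.
#' @return Positive scalar.
#' @export
#' @examples
#' sis_mu2_limit(sis_preset("fig1"), q = 0)   # exactly 1
sis_mu2_limit <- function(params, q = NULL, S_T = NULL, A = NULL) {
  p <- params
  qq <- if (is.null(q)) p$q else q
  ss <- if (is.null(S_T)) p$S_T else S_T
  aa <- if (is.null(A)) p$A else A
  if (qq < 0 || qq > 1) stop("q must lie in [0, 1]", call. = FALSE)
  if (ss < 0) stop("S_T must be nonnegative", call. = FALSE)
  .sis_mu2_raw(aa, p$d, p$beta, p$v, p$theta, p$c, p$b, qq, ss)
}

#' Semi-trivial periodic solution summary
#'
#' Assembles the period, the impulse jump factor
#' \eqn{\Delta_1 = (A - d(1-q)S_T)/(A - dS_T) > 1}, the Floquet multiplier,
#' and the stability verdict.  When the parameters fall in the globally
#' disease-free regime (case C1 of [sis_classify_case()]) the verdict is
#' upgraded to globally stable: there the Poincare map is monotonically
#' decreasing, so the disease-free cycle attracts every orbit.
#'
#' @param params a [sis_params()] object.
#' @return Object of class \code{"sis_semitrivial"}: list with \code{T},
#'   \code{Delta1}, \code{mu2}, \code{stable}, \code{global}, \code{case}.
#' @export
sis_semitrivial <- function(params) {
  p <- params
  mu2 <- .sis_mu2_params(p)
  cs <- sis_classify_case(p)
  structure(list(
    T = sis_period(p),
    Delta1 = (p$A - p$d * (1 - p$q) * p$S_T) / (p$A - p$d * p$S_T),
    mu2 = mu2,
    stable = mu2 < 1,
    global = identical(cs, "C1"),
    case = cs,
    params = p), class = "sis_semitrivial")
}

#' @export
print.sis_semitrivial <- function(x, ...) {
  cat("Semi-trivial (disease-free) periodic solution\n")
  cat(sprintf("  period T = %.10g\n", x$T))
  cat(sprintf("  jump factor Delta1 = %.10g\n", x$Delta1))
  cat(sprintf("  Floquet multiplier mu2 = %.10g\n", x$mu2))
  verdict <- if (!x$stable) "unstable"
             else if (x$global) "globally stable (case C1)"
             else "orbitally asymptotically stable"
  cat("  verdict:", verdict, "\n")
  invisible(x)
}
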