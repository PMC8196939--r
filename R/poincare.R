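# Poincare map on the post-vaccination section S = (1-q)S_T: domain
# construction from the tangency quadratics, numerical evaluation by
# event-driven integration, finite-difference derivatives, and fixed-point
# (order-1 periodic solution) detection.

.sis_no_return <- function(msg) {
  stop(structure(class = c("sis_no_return", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# integrate from (S0, I0) until the first crossing of S = S_T (time cap in
# units of 50/(d+theta)); reverse = TRUE integrates the reversed field.
.sis_reach_ST <- function(S0, I0, p, reverse = FALSE,
                          target = p$S_T, cap = 50) {
  t_max <- cap / (p$d + p$theta)
  deriv <- if (reverse)
    function(t, y, q) list(-.sis_rhs(y[1], y[2], q))
  else
    function(t, y, q) list(.sis_rhs(y[1], y[2], q))
  root <- function(t, y, q) y[1] - target
  # absolute tolerance on I scaled to its starting level, so that orbits
  # probing the linearised (tiny-I) regime are integrated with relative
  # accuracy throughout
  atol_I <- if (I0 > 0) max(1e-30, p$atol * min(1, I0)) else p$atol
  out <- deSolve::lsodar(c(S0, I0), c(0, t_max), deriv, parms = p,
                         rootfunc = root, rtol = p$rtol,
                         atol = c(p$atol, atol_I), maxsteps = 1e6)
  if (attr(out, "istate")[1] != 3L)
    .sis_no_return(sprintf(
      "orbit from (%.6g, %.6g) did not reach S = %.6g within %.3g time units",
      S0, I0, target, t_max))
  list(t = unname(out[nrow(out), 1]), I = unname(out[nrow(out), 3]))
}

# unique positive root of  B x^2 + (D + B b + c) x + D b = 0  (negative
# branch of the quadratic formula, valid for B < 0), or NA when B >= 0.
.sis_tangency_root <- function(B, D, p) {
  if (B >= 0) return(NA_real_)
  co <- D + B * p$b + p$c
  (-co - sqrt(co^2 - 4 * B * D * p$b)) / (2 * B)
}

#' Poincare-map domain construction
#'
#' Builds the geometry of the impulsive and phase sets for the Poincare
#' map on the section \eqn{S = (1-q)S_T}.  The vector field is tangent to
#' a vertical section at heights where \eqn{F_1 = 0}; on the phase section
#' these satisfy \eqn{B I^2 + (D + Bb + c) I + Db = 0} with
#' \eqn{B = v - \theta - \beta(1-q)S_T},
#' \eqn{D = (d+\theta)(A/d - (1-q)S_T) > 0}, and on the impulsive section
#' the same with \eqn{B_1 = v - \theta - \beta S_T},
#' \eqn{D_1 = (d+\theta)(A/d - S_T) > 0}.  A negative leading coefficient
#' gives exactly one positive tangency height (\code{I_qST}, resp.
#' \code{I_ST}); otherwise the section is everywhere transversal.
#'
#' \code{I_max} is the search bound for fixed points: in the regimes where
#' every section orbit returns to the threshold (case C1, or case C2 with
#' \eqn{S_T \le S^*}) it is the top of the impulsive set, found by running
#' the tangency orbit forward to \eqn{S = S_T} (heights above the
#' invariant region are capped at its boundary \eqn{I = A/d - (1-q)S_T});
#' in case C2 with \eqn{S_T > S^*} it is the height \code{I_q} whose orbit
#' grazes the impulsive section, found by backward continuation from the
#' tangency point \eqn{(S_T, I_{S_T})} — orbits starting above \code{I_q}
#' are captured by the endemic equilibrium and never return.  For cases
#' C3/C4 the domain is not characterised and \code{I_max} is \code{NA}
#' with a warning.
#'
#' @param params a [sis_params()] object.
#' @return Object of class \code{"sis_domain"}: list with \code{case},
#'   \code{B}, \code{D}, \code{B1}, \code{D1}, \code{I_qST}, \code{I_ST},
#'   \code{I_max}, \code{S_star} (endemic S, or NA).
#' @export
#' @examples
#' sis_domain(sis_preset("fig2b"))
sis_domain <- function(params) {
  p <- params
  B <- p$v - p$theta - p$beta * (1 - p$q) * p$S_T
  D <- (p$d + p$theta) * (p$A / p$d - (1 - p$q) * p$S_T)
  B1 <- p$v - p$theta - p$beta * p$S_T
  D1 <- (p$d + p$theta) * (p$A / p$d - p$S_T)
  I_qST <- .sis_tangency_root(B, D, p)
  I_ST <- .sis_tangency_root(B1, D1, p)
  cs <- sis_classify_case(p)
  eq <- sis_equilibria(p)
  S_star <- if (nrow(eq$endemics)) min(eq$endemics$S) else NA_real_

  I_max <- NA_real_
  if (cs %in% c("C3", "C4")) {
    warning("cases C3/C4: phase portrait too complex for a guaranteed ",
            "return bound; I_max = NA", call. = FALSE)
  } else if (cs == "C1" || (cs == "C2" && !is.na(S_star) && p$S_T <= S_star)) {
    top <- p$A / p$d - (1 - p$q) * p$S_T       # D-boundary height
    start <- if (!is.na(I_qST)) min(I_qST, top) else top
    I_max <- tryCatch(.sis_reach_ST((1 - p$q) * p$S_T, start, p)$I,
                      sis_no_return = function(e) NA_real_)
  } else if (cs == "C2") {                      # S_T > S_star
    if (is.na(I_ST)) {
      warning("no tangency on the impulsive section (B1 >= 0); ",
              "I_max = NA", call. = FALSE)
    } else {
      I_max <- tryCatch(
        .sis_reach_ST(p$S_T, I_ST, p, reverse = TRUE,
                      target = (1 - p$q) * p$S_T)$I,
        sis_no_return = function(e) NA_real_)
    }
  }
  structure(list(case = cs, B = B, D = D, B1 = B1, D1 = D1,
                 I_qST = I_qST, I_ST = I_ST, I_max = I_max,
                 S_star = S_star, params = p),
            class = "sis_domain")
}

#' @export
print.sis_domain <- function(x, ...) {
  cat("Poincare-map domain (case ", x$case, ")\n", sep = "")
  cat(sprintf("  phase section S = %.6g: B = %.6g, D = %.6g, I_qST = %.6g\n",
              (1 - x$params$q) * x$params$S_T, x$B, x$D, x$I_qST))
  cat(sprintf("  impulsive section S = %.6g: B1 = %.6g, D1 = %.6g, I_ST = %.6g\n",
              x$params$S_T, x$B1, x$D1, x$I_ST))
  cat(sprintf("  fixed-point search bound I_max = %.6g\n", x$I_max))
  invisible(x)
}

#' Evaluate the Poincare map
#'
#' \eqn{P_1(I_0)} is the infective level at the first crossing of the
#' impulsive section \eqn{S = S_T} by the orbit started at
#' \eqn{((1-q)S_T, I_0)} on the phase section.  Since the post-pulse
#' infective level is unchanged, fixed points of \eqn{P_1} are order-1
#' periodic solutions of the impulsive system.  \eqn{P_1(0) = 0} exactly
#' (the disease-free manifold is invariant) and is handled analytically.
#'
#' Orbits that fail to reach the threshold within \eqn{50/(d+\theta)} time
#' units (captured by an interior equilibrium) raise a condition of class
#' \code{"sis_no_return"}.
#'
#' @param I0 starting infective level(s) on the phase section,
#'   nonnegative; vectorised.
#' @param params a [sis_params()] object.
#' @return Infective level(s) at the next threshold crossing.
#' @export
#' @examples
#' p <- sis_preset("fig2b")
#' sis_map_P1(0.5, p)
sis_map_P1 <- function(I0, params) {
  p <- params
  if (any(I0 < 0)) stop("I0 must be nonnegative", call. = FALSE)
  vapply(I0, function(i) {
    if (i == 0) return(0)
    .sis_reach_ST((1 - p$q) * p$S_T, i, p)$I
  }, 0)
}

#' Finite-difference derivatives of the Poincare map
#'
#' Estimates \eqn{d^k P_1 / dI_0^k} for \eqn{k \in \{1,2,3\}} by
#' Richardson-extrapolated finite differences.  At \eqn{I_0 = 0} one-sided
#' stencils exploiting \eqn{P_1(0) = 0} are used (the map is only defined
#' for \eqn{I_0 \ge 0}); in the interior, central stencils.  The order-1
#' derivative at 0 is the Floquet multiplier \eqn{\mu_2} of the
#' semi-trivial solution, which provides an independent cross-check on
#' the closed form.
#'
#' @param I0 evaluation point, in the domain interior or 0.
#' @param params a [sis_params()] object.
#' @param order derivative order, 1, 2 or 3.
#' @param h base step; defaults scale with the order (truncation versus
#'   integration-noise trade-off: the map is evaluated to ~1e-10 relative).
#' @return Scalar estimate.
#' @export
sis_dP1 <- function(I0, params, order = 1L, h = NULL) {
  p <- params
  order <- as.integer(order)
  stopifnot(order %in% 1:3, I0 >= 0)
  P <- function(x) sis_map_P1(x, p)
  if (is.null(h)) {
    h <- switch(order, max(1e-6, 1e-4 * I0), 1e-3, 1e-2)
    if (order == 1L && I0 == 0) {
      # keep the probe in the linear regime: the one-cycle growth factor
      # spans orders of magnitude across parameter space, so scale the
      # step to make the probe image ~1e-4
      h0 <- 1e-6
      pilot <- NULL
      for (try in 1:4) {
        pilot <- tryCatch(P(h0), sis_no_return = function(e) NULL)
        if (!is.null(pilot)) break
        h0 <- h0 / 100
      }
      if (is.null(pilot))
        .sis_no_return("pilot orbit for the map derivative did not return")
      slope <- pilot / h0
      h <- max(1e-9, min(1e-3, 1e-4 / slope))
    }
  }
  rich <- function(est, p_ord) {
    # est(hh) has error O(hh^p_ord); two-level Richardson
    e1 <- est(h); e2 <- est(h / 2)
    (2^p_ord * e2 - e1) / (2^p_ord - 1)
  }
  if (I0 == 0) {
    switch(order,
      { # the slope P(h)/h is a growth factor: extrapolate its logarithm,
        # whose h-expansion stays tame even for very large multipliers
        L <- function(hh) log(P(hh) / hh)                   # err O(h)
        a <- 2 * L(h / 2) - L(h)                            # -> O(h^2)
        b <- 2 * L(h / 4) - L(h / 2)
        exp((4 * b - a) / 3) },                             # -> O(h^3)
      rich(function(hh) (P(2 * hh) - 2 * P(hh)) / hh^2, 1),
      rich(function(hh) (3 * P(hh) - 3 * P(2 * hh) + P(3 * hh)) / hh^3, 1))
  } else {
    switch(order,
      rich(function(hh) (P(I0 + hh) - P(I0 - hh)) / (2 * hh), 2),
      rich(function(hh) (P(I0 + hh) - 2 * P(I0) + P(I0 - hh)) / hh^2, 2),
      rich(function(hh)
        (P(I0 + 2 * hh) - 2 * P(I0 + hh) + 2 * P(I0 - hh) -
           P(I0 - 2 * hh)) / (2 * hh^3), 2))
  }
}

#' Fixed points of the Poincare map
#'
#' Scans \eqn{P_1(I) - I} for sign changes on a grid over
#' \eqn{(0, I_{\max})} and refines each bracket by bisection
#' ([stats::uniroot()]); each positive fixed point is an order-1 periodic
#' solution of the impulsive system, with stability read off the numeric
#' multiplier \eqn{dP_1/dI_0} at the fixed point.  The trivial fixed point
#' \eqn{I = 0} (the semi-trivial solution) is reported separately by
#' [sis_semitrivial()], not here.
#'
#' @param params a [sis_params()] object.
#' @param grid_size number of scan points.
#' @param upper search upper bound; defaults to just below the domain's
#'   \code{I_max} (required when that is unknown, cases C3/C4).
#' @return Data frame with columns \code{I_fix}, \code{residual}
#'   (\eqn{|P_1(I)-I|}), \code{multiplier}, \code{stable}; zero rows when
#'   no positive fixed point exists.
#' @export
#' @examples
#' sis_fixed_points(sis_preset("fig2b"))   # one unstable fixed point
sis_fixed_points <- function(params, grid_size = 48L, upper = NULL) {
  p <- params
  if (is.null(upper)) {
    dom <- suppressWarnings(sis_domain(p))
    if (is.na(dom$I_max))
      stop("domain bound unknown (case ", dom$case,
           "); supply 'upper' explicitly", call. = FALSE)
    upper <- dom$I_max * (1 - 1e-6)
  }
  grid <- seq(upper / grid_size, upper, length.out = grid_size)
  fvals <- vapply(grid, function(i)
    tryCatch(sis_map_P1(i, p) - i, sis_no_return = function(e) NA_real_), 0)
  if (anyNA(fvals))
    warning(sum(is.na(fvals)), " grid point(s) hit the no-return region",
            call. = FALSE)
  ok <- which(!is.na(fvals))
  res <- data.frame(I_fix = numeric(0), residual = numeric(0),
                    multiplier = numeric(0), stable = logical(0))
  if (length(ok) < 2) return(res)
  f <- function(i) sis_map_P1(i, p) - i
  # a sign change can hide between the last returning grid point and the
  # no-return boundary (transit times diverge there): bisect on validity
  brackets <- list()
  for (j in which(is.na(fvals))) {
    if (j == 1L || is.na(fvals[j - 1L])) next
    lo <- grid[j - 1L]; flo <- fvals[j - 1L]; hi <- grid[j]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      fm <- tryCatch(f(mid), sis_no_return = function(e) NA_real_)
      if (is.na(fm)) { hi <- mid; next }
      if (sign(fm) != sign(flo)) { brackets <- c(brackets, list(c(lo, mid))); break }
      lo <- mid; flo <- fm
      if (hi - lo < 1e-10) break
    }
  }
  for (j in seq_len(length(ok) - 1)) {
    i1 <- ok[j]; i2 <- ok[j + 1]
    if (i2 != i1 + 1L) next                 # bracket spans a no-return gap
    if (sign(fvals[i1]) * sign(fvals[i2]) < 0) {
      r <- stats::uniroot(function(i) sis_map_P1(i, p) - i,
                          c(grid[i1], grid[i2]), tol = 1e-12)
      mult <- sis_dP1(r$root, p, order = 1L)
      res <- rbind(res, data.frame(
        I_fix = r$root, residual = abs(sis_map_P1(r$root, p) - r$root),
        multiplier = mult, stable = abs(mult) < 1))
    } else if (fvals[i1] == 0) {
      mult <- sis_dP1(grid[i1], p, order = 1L)
      res <- rbind(res, data.frame(I_fix = grid[i1], residual = 0,
                                   multiplier = mult,
                                   stable = abs(mult) < 1))
    }
  }
  for (br in brackets) {
    r <- stats::uniroot(f, br, tol = 1e-12)
    mult <- sis_dP1(r$root, p, order = 1L)
    res <- rbind(res, data.frame(
      I_fix = r$root, residual = abs(f(r$root)),
      multiplier = mult, stable = abs(mult) < 1))
  }
  res[order(res$I_fix), , drop = FALSE]
}
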