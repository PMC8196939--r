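# Planar ODE core: vector field, reproduction numbers, endemic equilibria,
# local stability, and the four-case classification used by the Poincare-map
# domain construction.

# raw right-hand side, no domain checks (also used inside the integrator)
.sis_rhs <- function(S, I, p) {
  treat <- p$c * I / (p$b + I)
  c(p$A - p$d * S - p$beta * S * I + p$v * I +
      p$theta * (p$A / p$d - S - I) + treat,
    p$beta * S * I - (p$d + p$v) * I - treat)
}

.sis_jacobian <- function(S, I, p) {
  dtreat <- p$c * p$b / (p$b + I)^2   # d/dI of cI/(b+I)
  matrix(c(-p$d - p$beta * I - p$theta,
           -p$beta * S + p$v - p$theta + dtreat,
           p$beta * I,
           p$beta * S - (p$d + p$v) - dtreat),
         2L, 2L, byrow = TRUE)
}

#' Vector field of the planar SIS core
#'
#' Evaluates the right-hand side of the reduced planar system (total
#' population at its equilibrium level \eqn{A/d}, vaccinated compartment
#' eliminated) at a state inside the invariant region
#' \eqn{D = \{S, I \ge 0,\ S + I \le A/d\}}.
#'
#' @param state numeric vector \code{c(S, I)}.
#' @param params a [sis_params()] object.
#' @param tol tolerance for the invariant-region check.
#' @return Numeric vector \code{c(dS, dI)}.
#' @export
#' @examples
#' p <- sis_preset("fig1")
#' sis_vector_field(c(p$A / p$d, 0), p)   # disease-free equilibrium
sis_vector_field <- function(state, params, tol = 1e-8) {
  stopifnot(inherits(params, "sis_params"), length(state) == 2L)
  S <- state[[1]]; I <- state[[2]]
  if (S < -tol || I < -tol || S + I > params$A / params$d + tol)
    stop("state (", S, ", ", I, ") lies outside the invariant region D",
         call. = FALSE)
  F <- .sis_rhs(S, I, params)
  names(F) <- c("dS", "dI")
  F
}

#' Basic reproduction number
#'
#' \eqn{R_0 = A b \beta / (d (c + b(d+v)))}.  The disease-free equilibrium
#' \eqn{(A/d, 0)} of the ODE core is locally asymptotically stable iff
#' \eqn{R_0 < 1}.
#'
#' @param params a [sis_params()] object.
#' @return Positive scalar.
#' @export
sis_R0 <- function(params) {
  params$A * params$b * params$beta /
    (params$d * (params$c + params$b * (params$d + params$v)))
}

#' Backward-bifurcation thresholds of the ODE core
#'
#' Returns the recruitment threshold
#' \eqn{A_1 = bd + d(d+v)/\beta} and the subthreshold
#' \eqn{\hat R_0 = 4Abd\beta^2 / (4Abd\beta^2 + (d^2+dv+bd\beta-A\beta)^2)}.
#' When \eqn{A > A_1}, two endemic equilibria coexist for
#' \eqn{\hat R_0 < R_0 < 1} (backward bifurcation), so pushing \eqn{R_0}
#' just below one need not eliminate the disease.
#'
#' @param params a [sis_params()] object.
#' @return Named list with \code{A1} and \code{Rhat0} (\eqn{0 < \hat R_0 \le 1}).
#' @export
sis_thresholds <- function(params) {
  p <- params
  A1 <- p$b * p$d + p$d * (p$d + p$v) / p$beta
  w <- p$d^2 + p$d * p$v + p$b * p$d * p$beta - p$A * p$beta
  x <- 4 * p$A * p$b * p$d * p$beta^2
  list(A1 = A1, Rhat0 = x / (x + w^2))
}

#' Stability index H(I) at an endemic equilibrium
#'
#' \eqn{H(I) = \theta + d + \beta I - cI/(b+I)^2} equals minus the trace of
#' the Jacobian of the planar core at an endemic equilibrium with
#' infective level \eqn{I} (the equilibria lie on the line
#' \eqn{S + I = A/d}).  The equilibrium is a stable node or focus when
#' \eqn{H > 0}, unstable when \eqn{H < 0}, and a linear center when
#' \eqn{H = 0}.
#'
#' With \code{paper_literal = TRUE} an extra \code{+ q} is included; that
#' variant corresponds to carrying the continuous-vaccination term of the
#' three-compartment model into the reduced planar system, and is provided
#' for comparison only (the planar system itself contains no q, and its
#' Jacobian trace matches the default form exactly).
#'
#' @param I infective level, nonnegative.
#' @param params a [sis_params()] object.
#' @param paper_literal include the extra \code{+ q} term.
#' @return Scalar (vectorised over \code{I}).
#' @export
sis_H <- function(I, params, paper_literal = FALSE) {
  p <- params
  H <- p$theta + p$d + p$beta * I - p$c * I / (p$b + I)^2
  if (paper_literal) H <- H + p$q
  H
}

# stability label from the Jacobian at (A/d - I, I)
.sis_stability_label <- function(I, p, tol = 1e-9) {
  J <- .sis_jacobian(p$A / p$d - I, I, p)
  tr <- J[1, 1] + J[2, 2]
  de <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (de < -tol) return("saddle")
  if (abs(tr) <= tol) return("center (linear)")
  kind <- if (tr^2 - 4 * de >= 0) "node" else "focus"
  paste(if (tr < 0) "stable" else "unstable", kind)
}

#' Equilibria of the planar SIS core
#'
#' Computes the disease-free equilibrium \eqn{(A/d, 0)} and the endemic
#' equilibria, which lie on the line \eqn{S + I = A/d} with \eqn{I} a
#' positive root of the quadratic \eqn{I^2 + a_1 I + a_2 = 0},
#' \eqn{a_1 = b + (d+v)/\beta - A/d},
#' \eqn{a_2 = (c + b(d+v))/\beta - bA/d}.  Depending on \eqn{R_0},
#' \eqn{\hat R_0} and \eqn{A_1} there are zero, one, or two endemic
#' equilibria (the two-equilibria window \eqn{\hat R_0 < R_0 < 1},
#' \eqn{A > A_1} is the backward bifurcation).  Each endemic point carries
#' its \eqn{H}-index and a node/focus/saddle stability label.
#'
#' Inputs sitting numerically on a case boundary (\eqn{R_0 = 1} or a
#' vanishing discriminant) are flagged \code{"boundary"} rather than forced
#' into a branch.
#'
#' @param params a [sis_params()] object.
#' @param tol relative tolerance for boundary detection.
#' @return An object of class \code{"sis_equilibria"}: list with scalars
#'   \code{R0}, \code{Rhat0}, \code{A1}, \code{a1}, \code{a2}, \code{Delta},
#'   \code{case}, the \code{dfe}, and a data frame \code{endemics} with
#'   columns \code{S}, \code{I}, \code{multiplicity}, \code{H},
#'   \code{stability}.
#' @export
#' @examples
#' sis_equilibria(sis_preset("fig2b"))
sis_equilibria <- function(params, tol = 1e-9) {
  p <- params
  a1 <- p$b + (p$d + p$v) / p$beta - p$A / p$d
  a2 <- (p$c + p$b * (p$d + p$v)) / p$beta - p$b * p$A / p$d
  Delta <- a1^2 - 4 * a2
  R0 <- sis_R0(p)
  th <- sis_thresholds(p)

  boundary <- abs(R0 - 1) < tol || abs(Delta) < tol * max(1, a1^2) ||
    (p$A > th$A1 && abs(R0 - th$Rhat0) < tol)

  roots <- numeric(0); mult <- integer(0)
  if (Delta > 0) {
    r <- c((-a1 - sqrt(Delta)) / 2, (-a1 + sqrt(Delta)) / 2)
    keep <- r > tol & r < p$A / p$d
    roots <- r[keep]; mult <- rep(1L, length(roots))
  } else if (abs(Delta) <= tol * max(1, a1^2)) {
    r <- -a1 / 2
    if (r > tol && r < p$A / p$d) { roots <- r; mult <- 2L }
  }

  endemics <- data.frame(
    S = p$A / p$d - roots, I = roots, multiplicity = mult,
    H = if (length(roots)) sis_H(roots, p) else numeric(0),
    stability = vapply(roots, .sis_stability_label, "", p = p),
    stringsAsFactors = FALSE)

  structure(list(
    R0 = R0, Rhat0 = th$Rhat0, A1 = th$A1,
    a1 = a1, a2 = a2, Delta = Delta,
    dfe = c(S = p$A / p$d, I = 0),
    endemics = endemics,
    case = if (boundary) "boundary" else sis_classify_case(p, tol = tol),
    params = p), class = "sis_equilibria")
}

#' @export
print.sis_equilibria <- function(x, ...) {
  cat("Equilibria of the planar SIS core (case ", x$case, ")\n", sep = "")
  cat(sprintf("  R0 = %.6g, Rhat0 = %.6g, A1 = %.6g\n", x$R0, x$Rhat0, x$A1))
  cat(sprintf("  quadratic I^2 + a1 I + a2: a1 = %.6g, a2 = %.6g, Delta = %.6g\n",
              x$a1, x$a2, x$Delta))
  cat(sprintf("  disease-free equilibrium: (%.6g, 0)\n", x$dfe[["S"]]))
  if (nrow(x$endemics) == 0) {
    cat("  no endemic equilibrium\n")
  } else {
    print(format(x$endemics, digits = 6), row.names = FALSE)
  }
  invisible(x)
}

#' Dynamical case classification of the ODE core
#'
#' Classifies the parameter set into the four regimes that determine the
#' geometry of the impulsive system's Poincare map:
#' \itemize{
#'   \item \code{C1}: \eqn{R_0 < 1, A \le A_1} or
#'     \eqn{R_0 < \hat R_0, A > A_1} — disease-free equilibrium globally
#'     stable, no endemic equilibrium;
#'   \item \code{C2}: \eqn{R_0 > 1} and \eqn{H(I^*) > 0} — unique stable
#'     endemic equilibrium;
#'   \item \code{C3}: \eqn{R_0 > 1} and \eqn{H(I^*) < 0} — unique unstable
#'     endemic equilibrium;
#'   \item \code{C4}: \eqn{\hat R_0 < R_0 < 1} and \eqn{A > A_1} — two
#'     endemic equilibria (backward bifurcation window).
#' }
#' Parameter sets on (or numerically indistinguishable from) a case
#' boundary return \code{"boundary"}.
#'
#' @param params a [sis_params()] object.
#' @param tol boundary tolerance.
#' @return One of \code{"C1"}, \code{"C2"}, \code{"C3"}, \code{"C4"},
#'   \code{"boundary"}.
#' @export
sis_classify_case <- function(params, tol = 1e-9) {
  p <- params
  R0 <- sis_R0(p)
  th <- sis_thresholds(p)
  if (abs(R0 - 1) < tol) return("boundary")
  if (R0 < 1) {
    if (p$A <= th$A1) return("C1")
    if (abs(R0 - th$Rhat0) < tol) return("boundary")
    if (R0 < th$Rhat0) return("C1")
    return("C4")
  }
  # R0 > 1: unique endemic equilibrium, larger quadratic root
  a1 <- p$b + (p$d + p$v) / p$beta - p$A / p$d
  a2 <- (p$c + p$b * (p$d + p$v)) / p$beta - p$b * p$A / p$d
  Delta <- a1^2 - 4 * a2
  Istar <- (-a1 + sqrt(Delta)) / 2
  H <- sis_H(Istar, p)
  if (abs(H) < tol) return("boundary")
  if (H > 0) "C2" else "C3"
}

#' Write an equilibrium report to CSV
#'
#' One row per equilibrium (disease-free first), preceded by a block of
#' \code{#}-prefixed header comments carrying the scalar summary
#' (parameters, R0, Rhat0, A1, a1, a2, Delta, case).
#'
#' @param x a \code{"sis_equilibria"} object.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
sis_write_equilibria <- function(x, path) {
  stopifnot(inherits(x, "sis_equilibria"))
  p <- x$params
  hdr <- c(
    .sis_csv_banner(p),
    sprintf("# R0 = %.12g, Rhat0 = %.12g, A1 = %.12g", x$R0, x$Rhat0, x$A1),
    sprintf("# a1 = %.12g, a2 = %.12g, Delta = %.12g", x$a1, x$a2, x$Delta),
    sprintf("# case = %s", x$case))
  df <- rbind(
    data.frame(type = "disease-free", S = x$dfe[["S"]], I = 0,
               multiplicity = 1L, H = NA_real_, stability = "see R0",
               stringsAsFactors = FALSE),
    if (nrow(x$endemics)) cbind(type = "endemic", x$endemics))
  .sis_write_csv(df, path, hdr)
}

# shared CSV helpers -------------------------------------------------------

.sis_csv_banner <- function(p) {
  c(sprintf("# impulseSIS %s",
            as.character(utils::packageVersion("impulseSIS"))),
    sprintf(paste0("# A = %.12g, d = %.12g, beta = %.12g, v = %.12g, ",
                   "theta = %.12g, c = %.12g, b = %.12g, q = %.12g, ",
                   "S_T = %.12g"),
            p$A, p$d, p$beta, p$v, p$theta, p$c, p$b, p$q, p$S_T))
}

.sis_write_csv <- function(df, path, header = character(0)) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
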