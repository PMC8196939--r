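#' Model parameters for the impulsive SIS system
#'
#' Bundles the nine constants of the SIS model with saturated treatment and
#' threshold pulse vaccination, together with the solver settings used by the
#' event-driven integrator.  The continuous part of the model is
#' \deqn{dS/dt = A - dS - \beta S I + v I + \theta(A/d - S - I) + cI/(b+I),}
#' \deqn{dI/dt = \beta S I - (d+v) I - cI/(b+I),}
#' and whenever the susceptible population reaches the threshold \code{S_T}
#' a fraction \code{q} is vaccinated instantaneously:
#' \eqn{S^+ = (1-q)S_T}, \eqn{I^+ = I}.
#'
#' @param A recruitment rate of susceptibles (individuals per unit time).
#' @param d natural death rate (per unit time).
#' @param beta transmission coefficient (per individual per unit time).
#' @param v natural (untreated) recovery rate (per unit time).
#' @param theta vaccine-waning rate (per unit time); may be zero.
#' @param c maximal treatment rate (individuals per unit time); the treated
#'   recovery term is \eqn{cI/(b+I)}, which saturates at \code{c}.
#' @param b treatment half-saturation constant (individuals).
#' @param q pulse vaccination fraction, strictly between 0 and 1.
#' @param S_T susceptible threshold triggering the vaccination pulse
#'   (individuals); must satisfy \eqn{0 < S_T < A/d}.
#' @param rtol,atol relative and absolute solver tolerances.  The defaults
#'   are tight because Poincare-map derivative estimates difference nearby
#'   orbits.
#' @param method integration method passed to \pkg{deSolve}
#'   (\code{"lsodar"} handles both stiff and non-stiff regimes and provides
#'   the root-finding used for threshold detection).
#'
#' @return An object of class \code{"sis_params"}: a named list of the nine
#'   model constants plus \code{rtol}, \code{atol}, \code{method}.
#' @seealso [sis_preset()] for the built-in parameter sets.
#' @export
#' @examples
#' p <- sis_params(A = 7, d = 0.7, beta = 1, v = 4, theta = 0.1,
#'                 c = 2.5, b = 1, q = 0.22, S_T = 8)
#' sis_R0(p)
sis_params <- function(A, d, beta, v, theta, c, b, q, S_T,
                       rtol = 1e-10, atol = 1e-12, method = "lsodar") {
  vals <- list(A = A, d = d, beta = beta, v = v, theta = theta,
               c = c, b = b, q = q, S_T = S_T)
  for (nm in names(vals)) {
    x <- vals[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("A", "d", "beta", "v", "c", "b"))
    if (vals[[nm]] <= 0)
      stop("parameter '", nm, "' must be positive", call. = FALSE)
  if (theta < 0)
    stop("parameter 'theta' must be nonnegative", call. = FALSE)
  if (q <= 0 || q >= 1)
    stop("parameter 'q' must lie strictly in (0, 1)", call. = FALSE)
  if (S_T <= 0 || S_T >= A / d)
    stop("parameter 'S_T' must satisfy 0 < S_T < A/d = ", format(A / d),
         call. = FALSE)
  structure(c(vals, list(rtol = rtol, atol = atol, method = method)),
            class = "sis_params")
}

#' @export
print.sis_params <- function(x, ...) {
  cat("Impulsive SIS model parameters\n")
  cat(sprintf("  A = %g, d = %g, beta = %g, v = %g, theta = %g\n",
              x$A, x$d, x$beta, x$v, x$theta))
  cat(sprintf("  c = %g, b = %g (saturated treatment cI/(b+I))\n", x$c, x$b))
  cat(sprintf("  q = %g, S_T = %g (pulse: S -> (1-q)S_T at S = S_T)\n",
              x$q, x$S_T))
  cat(sprintf("  carrying level A/d = %g; R0 = %.6g\n", x$A / x$d, sis_R0(x)))
  invisible(x)
}

#' Built-in parameter presets
#'
#' Three reference parameter sets used throughout the documentation and
#' tests: \code{"fig1"} (beta = 1, S_T = 8), \code{"fig2a"} (beta = 0.8,
#' S_T = 6.3) and \code{"fig2b"} (beta = 0.8, S_T = 8).  All share
#' A = 7, d = 0.7, v = 4, c = 2.5, theta = 0.1, b = 1, q = 0.22.
#' Under \code{"fig1"} the disease-free periodic solution is marginally
#' unstable (Floquet multiplier just above 1); under \code{"fig2a"} it is
#' globally attracting; under \code{"fig2b"} it is stable but coexists with
#' a stable endemic equilibrium and an unstable order-1 periodic orbit
#' (bistability).
#'
#' @param name one of \code{"fig1"}, \code{"fig2a"}, \code{"fig2b"}.
#' @param ... overrides passed on to [sis_params()].
#' @return A \code{"sis_params"} object.
#' @export
sis_preset <- function(name = c("fig1", "fig2a", "fig2b"), ...) {
  name <- match.arg(name)
  base <- list(A = 7, d = 0.7, beta = 1, v = 4, theta = 0.1,
               c = 2.5, b = 1, q = 0.22, S_T = 8)
  if (name == "fig2a") { base$beta <- 0.8; base$S_T <- 6.3 }
  if (name == "fig2b") { base$beta <- 0.8 }
  over <- list(...)
  base[names(over)] <- over
  do.call(sis_params, base)
}

.sis_param_keys <- c("A", "d", "beta", "v", "theta", "c", "b", "q", "S_T")

#' Read model parameters from a plain-text config file
#'
#' The format is flat \code{key = value} text, one pair per line, with
#' \code{#} comments allowed.  Exactly the nine keys \code{A, d, beta, v,
#' theta, c, b, q, S_T} must be present; unknown keys are rejected.
#'
#' @param path file to read.
#' @param ... overrides (e.g. solver settings) passed to [sis_params()].
#' @return A \code{"sis_params"} object.
#' @export
sis_read_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: '", lines[bad][1], "'", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  unknown <- setdiff(keys, .sis_param_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.sis_param_keys, keys)
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num))
    stop("non-numeric value for key '", keys[which(is.na(num))[1]], "'",
         call. = FALSE)
  args <- as.list(num)
  names(args) <- keys
  do.call(sis_params, c(args, list(...)))
}

#' Write model parameters to a plain-text config file
#'
#' Inverse of [sis_read_config()]; values are written with full precision so
#' that a round trip is bit-exact.
#'
#' @param params a \code{"sis_params"} object.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
sis_write_config <- function(params, path) {
  stopifnot(inherits(params, "sis_params"))
  lines <- vapply(.sis_param_keys, function(k)
    sprintf("%s = %s", k, formatC(params[[k]], format = "g", digits = 17)),
    "")
  writeLines(lines, path)
  invisible(path)
}
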