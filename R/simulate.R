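# Event-driven hybrid simulation of the impulsive system: continuous flow
# below the threshold S = S_T, instantaneous pulse vaccination at the
# threshold, integration restarted from the post-pulse state.

.sis_deriv2 <- function(t, y, p) list(.sis_rhs(y[1], y[2], p))

.sis_deriv3 <- function(t, y, p) {
  treat <- p$c * y[2] / (p$b + y[2])
  list(c(p$A - p$d * y[1] - p$beta * y[1] * y[2] + p$v * y[2] +
           p$theta * y[3] + treat,
         p$beta * y[1] * y[2] - (p$d + p$v) * y[2] - treat,
         -(p$theta + p$d) * y[3]))
}

.sis_root_ST <- function(t, y, p) y[1] - p$S_T

#' Pulse vaccination map
#'
#' The instantaneous state reset applied when the susceptible population
#' reaches the threshold: \eqn{S^+ = (1-q)S}, \eqn{I^+ = I}, and for the
#' three-compartment system \eqn{V^+ = V + qS} (the vaccinated fraction
#' moves from S to V, so S + V is conserved).  The map itself is total;
#' the simulator applies it only on the section \eqn{S = S_T}.
#'
#' @param state numeric vector \code{c(S, I)} or \code{c(S, I, V)}.
#' @param params a [sis_params()] object.
#' @return State vector of the same length.
#' @export
#' @examples
#' sis_impulse_map(c(S = 8, I = 2), sis_preset("fig1"))
sis_impulse_map <- function(state, params) {
  q <- params$q
  out <- state
  out[[1]] <- (1 - q) * state[[1]]
  if (length(state) == 3L) out[[3]] <- state[[3]] + q * state[[1]]
  out
}

# integrate one continuous segment until the threshold, a time cap, or
# apparent convergence away from the threshold.  Returns the segment grid,
# whether the threshold was hit, and the (event-refined) end state.
.sis_segment <- function(y0, t0, t_end, p, deriv, n_out = 101L) {
  times <- seq(t0, t_end, length.out = n_out)
  out <- deSolve::lsodar(y0, times, deriv, parms = p,
                         rootfunc = .sis_root_ST,
                         rtol = p$rtol, atol = p$atol, maxsteps = 1e5)
  hit <- attr(out, "istate")[1] == 3L
  y_last <- out[nrow(out), -1]
  names(y_last) <- names(y0)
  list(grid = unclass(out), hit = hit,
       t_last = unname(out[nrow(out), 1]), y_last = y_last)
}

#' Simulate the planar impulsive SIS system
#'
#' Event-driven integration of the planar core under the threshold policy:
#' the ODE flow runs while \eqn{S < S_T}; when \eqn{S} reaches \eqn{S_T}
#' (detected by the integrator's root finder and refined to solver
#' precision) the pulse \eqn{S \to (1-q)S_T} is applied and integration
#' restarts.  The state recorded *at* an impulse time is the pre-impulse
#' value (left-continuous convention); the post-impulse value is recorded
#' separately.
#'
#' Termination is one of: \code{"horizon"} (time limit reached),
#' \code{"max_impulses"}, or \code{"converged"} — the orbit stopped making
#' progress toward the threshold (attracted to an interior equilibrium with
#' \eqn{S^* < S_T}), detected when the running maximum of \eqn{S} over a
#' window of length \eqn{10/(d+\theta)} stops increasing while staying
#' below \eqn{S_T}.
#'
#' @param params a [sis_params()] object.
#' @param init numeric \code{c(S, I)} with \eqn{S \le S_T} and inside the
#'   invariant region D.  Initial states with \eqn{S > S_T} are rejected
#'   (the policy does not define an orbit there).
#' @param horizon total simulated time.
#' @param max_impulses stop after this many pulses.
#' @param n_out output points per continuous segment.
#' @return An object of class \code{"sis_trajectory"}: list with
#'   \code{segments} (list of per-segment matrices \code{t, S, I}),
#'   \code{impulse_times}, \code{pre_states}, \code{post_states} (matrices,
#'   one row per impulse), \code{termination}, and \code{params}.
#' @export
#' @examples
#' p <- sis_preset("fig1")
#' tr <- sis_simulate(p, c(S = (1 - p$q) * p$S_T, I = 0.5), horizon = 10)
#' tr$impulse_times
sis_simulate <- function(params, init, horizon, max_impulses = 1000L,
                         n_out = 101L) {
  .sis_simulate_impl(params, init, horizon, max_impulses, n_out,
                     deriv = .sis_deriv2, dim = 2L)
}

#' Simulate the three-compartment impulsive SIVS system
#'
#' As [sis_simulate()] but for the full susceptible-infective-vaccinated
#' system, where the pulse moves \eqn{qS} from S to V.  The total
#' population \eqn{N = S + I + V} obeys \eqn{dN/dt = A - dN} between
#' pulses and is conserved across pulses, so
#' \eqn{N(t) = A/d + (N_0 - A/d)e^{-dt}} along the whole hybrid orbit —
#' a useful exactness check on the event handling.
#'
#' @param init numeric \code{c(S, I, V)}, nonnegative, with
#'   \eqn{S \le S_T}.
#' @inheritParams sis_simulate
#' @return A \code{"sis_trajectory"} object with three state columns.
#' @export
sis_simulate3d <- function(params, init, horizon, max_impulses = 1000L,
                           n_out = 101L) {
  .sis_simulate_impl(params, init, horizon, max_impulses, n_out,
                     deriv = .sis_deriv3, dim = 3L)
}

.sis_simulate_impl <- function(p, init, horizon, max_impulses, n_out,
                               deriv, dim) {
  stopifnot(inherits(p, "sis_params"))
  init <- unlist(init)
  if (length(init) != dim)
    stop("init must have ", dim, " components", call. = FALSE)
  names(init) <- c("S", "I", "V")[seq_len(dim)]
  if (any(init < 0))
    stop("initial state must be nonnegative", call. = FALSE)
  if (init[[1]] > p$S_T + 1e-10)
    stop("initial S = ", init[[1]], " exceeds the threshold S_T = ", p$S_T,
         "; the policy is defined for S <= S_T", call. = FALSE)
  if (dim == 2L && sum(init) > p$A / p$d + 1e-8)
    stop("initial state lies outside the invariant region D", call. = FALSE)

  window <- 10 / (p$d + p$theta)
  segments <- list()
  imp_t <- numeric(0)
  pre <- post <- matrix(numeric(0), 0, dim,
                        dimnames = list(NULL, names(init)))
  t_cur <- 0; y_cur <- init
  termination <- "horizon"
  seg_open <- NULL   # grid rows of the in-progress segment (across chunks)
  prev_maxS <- -Inf

  while (t_cur < horizon - 1e-12) {
    t_chunk <- min(horizon, t_cur + window)
    seg <- .sis_segment(y_cur, t_cur, t_chunk, p, deriv, n_out)
    seg_open <- rbind(seg_open, seg$grid)
    if (seg$hit) {
      segments[[length(segments) + 1L]] <- seg_open
      seg_open <- NULL
      prev_maxS <- -Inf
      y_pre <- seg$y_last
      y_pre[[1]] <- p$S_T          # event refined; pin the section exactly
      y_post <- sis_impulse_map(y_pre, p)
      imp_t <- c(imp_t, seg$t_last)
      pre <- rbind(pre, y_pre)
      post <- rbind(post, y_post)
      t_cur <- seg$t_last
      y_cur <- y_post
      if (length(imp_t) >= max_impulses) { termination <- "max_impulses"; break }
    } else {
      maxS <- max(seg$grid[, 2])
      if (t_chunk >= horizon - 1e-12) { t_cur <- t_chunk; break }
      if (maxS <= prev_maxS + 1e-10 && maxS < p$S_T - 1e-9) {
        termination <- "converged"
        t_cur <- seg$t_last
        break
      }
      prev_maxS <- maxS
      t_cur <- seg$t_last
      y_cur <- seg$y_last
    }
  }
  if (!is.null(seg_open)) segments[[length(segments) + 1L]] <- seg_open
  rownames(pre) <- rownames(post) <- NULL

  structure(list(segments = segments, impulse_times = imp_t,
                 pre_states = pre, post_states = post,
                 termination = termination, params = p, dim = dim),
            class = "sis_trajectory")
}

#' @export
print.sis_trajectory <- function(x, ...) {
  last <- x$segments[[length(x$segments)]]
  cat(sprintf("Hybrid SIS trajectory: %d segment(s), %d impulse(s), t in [0, %.6g]\n",
              length(x$segments), length(x$impulse_times),
              last[nrow(last), 1]))
  cat("  termination:", x$termination, "\n")
  if (length(x$impulse_times))
    cat(sprintf("  impulses at t = %s%s\n",
                paste(format(utils::head(x$impulse_times, 5), digits = 6),
                      collapse = ", "),
                if (length(x$impulse_times) > 5) ", ..." else ""))
  invisible(x)
}

#' Flatten a hybrid trajectory to a data frame
#'
#' Columns \code{t, S, I[, V], segment, is_impulse}.  Impulse times appear
#' twice: the pre-impulse row (closing one segment) and the post-impulse
#' row (opening the next), flagged by \code{is_impulse}.
#'
#' @param x a \code{"sis_trajectory"} object.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.sis_trajectory <- function(x, ...) {
  cols <- c("S", "I", "V")[seq_len(x$dim)]
  out <- do.call(rbind, lapply(seq_along(x$segments), function(k) {
    g <- as.data.frame(x$segments[[k]])
    names(g) <- c("t", cols)
    g$segment <- k
    g
  }))
  out$is_impulse <- 0L
  out$is_impulse[out$t %in% x$impulse_times] <- 1L
  rownames(out) <- NULL
  out
}

#' Write a trajectory to CSV
#'
#' @param x a \code{"sis_trajectory"} object.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
sis_write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "sis_trajectory"))
  .sis_write_csv(as.data.frame(x), path,
                 c(.sis_csv_banner(x$params),
                   sprintf("# termination = %s", x$termination)))
}
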