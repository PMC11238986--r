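#' Thalamocortical loop parameters
#'
#' Constants of the three-variable firing-rate model of the pain-processing
#' thalamocortical loop (ventroposterolateral nucleus VPL, primary
#' somatosensory cortex SSC, thalamic reticular nucleus TRN):
#' \deqn{\tau \dot S + \theta S = f_1(bV)}
#' \deqn{\tau \dot T + \theta T = f_2(bV + bS)}
#' \deqn{\tau \dot V + \theta V = g(aT) \frac{(bS)^h}{f_a(aT)^h + (bS)^h}}
#' with \eqn{f_1, f_2} increasing Hill functions of maximum `m1` and `m2`,
#' \eqn{g} a decreasing Hill function of maximum `m1`, and
#' \eqn{f_a(x) = e_0 + } increasing Hill of maximum `m2`.  TRN inhibition
#' thus both depresses the maximal VPL response (through \eqn{g}) and
#' desensitises it (raising the half-saturation through \eqn{f_a}).
#'
#' @param a GABAergic strength, in (0, 1].
#' @param b Glutamatergic strength, in (0, 1].
#' @param theta Self-limiting coefficient, in (0, 1] (default 1).
#' @param tau Time constant in seconds (default 0.5).
#' @param m1 Maximum excitatory firing rate, Hz (default 100).
#' @param m2 Maximum inhibitory firing rate, Hz (default 80).
#' @param e Half-saturation constant, Hz (default 20).
#' @param e0 Basal half-saturation constant, Hz (default 20).
#' @param h Hill coefficient (default 2.5).
#' @return An object of class `thalamo_params`.
#' @export
thalamo_params <- function(a, b, theta = 1, tau = 0.5, m1 = 100, m2 = 80,
                           e = 20, e0 = 20, h = 2.5) {
  p <- list(a = a, b = b, theta = theta, tau = tau, m1 = m1, m2 = m2,
            e = e, e0 = e0, h = h)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm),
           call. = FALSE)
  }
  for (nm in c("a", "b", "theta"))
    if (p[[nm]] > 1)
      stop(sprintf("'%s' must not exceed 1", nm), call. = FALSE)
  structure(p, class = "thalamo_params")
}

#' @export
print.thalamo_params <- function(x, ...) {
  cat(sprintf(
    "Thalamocortical loop: a = %g, b = %g, theta = %g | tau = %g s, m1 = %g, m2 = %g, e = %g, e0 = %g, h = %g\n",
    x$a, x$b, x$theta, x$tau, x$m1, x$m2, x$e, x$e0, x$h))
  invisible(x)
}

# composite VPL drive: TRN inhibition scales the maximum (g, decreasing)
# and shifts the half-saturation (fa, increasing) of the SSC excitation
.thalamo_drive <- function(S, T_, p) {
  g <- .hill_down(p$a * T_, p$m1, p$e, p$h)
  fa <- p$e0 + .hill_up(p$a * T_, p$m2, p$e, p$h)
  g * (p$b * S)^p$h / (fa^p$h + (p$b * S)^p$h)
}

#' Right-hand side of the thalamocortical ODE system
#'
#' @param state Numeric vector `(S, T, V)` of mean firing rates in Hz,
#'   all nonnegative.
#' @param params A [thalamo_params()].
#' @return Named numeric vector of derivatives `(S, T, V)` in Hz/s.
#' @examples
#' thalamo_rhs(c(0, 0, 0), thalamo_params(a = 0.3, b = 1))  # origin fixed
#' @export
thalamo_rhs <- function(state, params) {
  stopifnot(inherits(params, "thalamo_params"))
  if (length(state) != 3L)
    stop("'state' must have length 3: (S, T, V)", call. = FALSE)
  .check_nonneg(state, "state")
  S <- state[[1]]; T_ <- state[[2]]; V <- state[[3]]
  p <- params
  c(S = (.hill_up(p$b * V, p$m1, p$e, p$h) - p$theta * S) / p$tau,
    T = (.hill_up(p$b * V + p$b * S, p$m2, p$e, p$h) - p$theta * T_) / p$tau,
    V = (.thalamo_drive(S, T_, p) - p$theta * V) / p$tau)
}

# unchecked rhs for solvers/Jacobians (finite-difference steps may probe
# slightly negative coordinates, where the expressions remain smooth for
# the even-order use made of them; clamp at 0 instead)
.thalamo_rhs_raw <- function(state, p) {
  s <- pmax(state, 0)
  c((.hill_up(p$b * s[3], p$m1, p$e, p$h) - p$theta * s[1]) / p$tau,
    (.hill_up(p$b * (s[3] + s[1]), p$m2, p$e, p$h) - p$theta * s[2]) / p$tau,
    (.thalamo_drive(s[1], s[2], p) - p$theta * s[3]) / p$tau)
}

#' Simulate the thalamocortical loop
#'
#' Adaptive-step integration (stiff-capable `lsoda`) of the loop from a
#' nonnegative initial state.  States that undershoot zero by less than
#' the solver tolerance are clamped to zero.  The final state is flagged
#' converged when the right-hand-side infinity norm falls below
#' `conv_tol`.
#'
#' @param initial Numeric `(S, T, V)` initial firing rates, Hz.
#' @param params A [thalamo_params()].
#' @param horizon Integration horizon in seconds.
#' @param n_out Number of reported time points (default 201).
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param conv_tol Convergence threshold on the RHS infinity norm, Hz/s.
#' @return A data frame of class `thalamo_sim` with columns
#'   `time, S, T, V`; attributes `converged`, `final`, `params`.
#' @export
simulate_thalamo <- function(initial, params, horizon = 60, n_out = 201,
                             rtol = 1e-8, atol = 1e-10, conv_tol = 1e-6) {
  stopifnot(inherits(params, "thalamo_params"))
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  .check_nonneg(initial, "initial")
  times <- seq(0, horizon, length.out = max(2L, n_out))
  sol <- deSolve::ode(
    y = c(S = initial[[1]], T = initial[[2]], V = initial[[3]]),
    times = times,
    func = function(t, y, p) list(.thalamo_rhs_raw(y, p)),
    parms = params, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("solver failure; last valid state (%s)",
                 paste(sprintf("%.4g", sol[nrow(sol), -1]),
                       collapse = ", ")), call. = FALSE)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  clamp_tol <- max(atol, 1e-8)
  for (v in c("S", "T", "V")) {
    if (any(out[[v]] < -clamp_tol))
      stop("state left the nonnegative octant beyond solver tolerance",
           call. = FALSE)
    out[[v]] <- pmax(out[[v]], 0)
  }
  final <- unlist(out[nrow(out), c("S", "T", "V")])
  converged <- max(abs(.thalamo_rhs_raw(final, params))) < conv_tol
  structure(out, converged = converged, final = final, params = params,
            class = c("thalamo_sim", "data.frame"))
}

#' @export
plot.thalamo_sim <- function(x, ...) {
  graphics::matplot(x$time, as.matrix(x[c("S", "T", "V")]), type = "l",
                    lty = 1, lwd = 2, xlab = "time (s)",
                    ylab = "firing rate (Hz)", ...)
  graphics::legend("topright", legend = c("SSC", "TRN", "VPL"),
                   col = 1:3, lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

# scalar reduction of the steady state: with S* = f1(bV*)/theta and
# T* = f2(bV* + bS*)/theta eliminated, a steady state is a root in V of
# drive(S*(V), T*(V))/theta - V on [0, m1/theta]
.thalamo_scalar_residual <- function(V, p) {
  S <- .hill_up(p$b * V, p$m1, p$e, p$h) / p$theta
  T_ <- .hill_up(p$b * (V + S), p$m2, p$e, p$h) / p$theta
  .thalamo_drive(S, T_, p) / p$theta - V
}

.thalamo_state_from_V <- function(V, p) {
  S <- .hill_up(p$b * V, p$m1, p$e, p$h) / p$theta
  T_ <- .hill_up(p$b * (V + S), p$m2, p$e, p$h) / p$theta
  c(S = S, T = T_, V = V)
}

#' Enumerate equilibria of the thalamocortical loop
#'
#' Reduces the steady state to a scalar fixed-point problem in the VPL
#' rate `V` (the SSC and TRN rates follow algebraically), brackets all
#' roots on a dense grid over `[0, m1/theta]` with a tenfold local
#' refinement around each sign change, polishes them with
#' [stats::uniroot()], deduplicates within `dedup_tol`, and classifies
#' each equilibrium by the eigenvalues of the full 3x3 Jacobian.  The
#' origin is always included (every Hill numerator vanishes there).
#'
#' @param params A [thalamo_params()].
#' @param n_grid Number of points of the coarse bracketing grid
#'   (default 2001).
#' @param dedup_tol State-space deduplication tolerance in Hz
#'   (default 1e-4).
#' @param stab_tol Stability threshold on eigenvalue real parts, Hz/s
#'   (default 1e-6); eigenvalues within it are flagged marginal.
#' @return An `equilibria_set` (see [n_stable()]).
#' @examples
#' \donttest{
#' n_stable(find_equilibria(thalamo_params(a = 0.3, b = 1)))  # 1
#' }
#' @export
find_equilibria <- function(params, n_grid = 2001, dedup_tol = 1e-4,
                            stab_tol = 1e-6) {
  stopifnot(inherits(params, "thalamo_params"))
  p <- params
  Vmax <- p$m1 / p$theta
  grid <- seq(0, Vmax, length.out = n_grid)
  fg <- .thalamo_scalar_residual(grid, p)
  roots <- 0 # origin
  sc <- which(fg[-1] * fg[-length(fg)] < 0)
  for (i in sc) {
    # refine x10 inside the bracketing interval to separate close roots
    sub <- seq(grid[i], grid[i + 1], length.out = 11L)
    fs <- .thalamo_scalar_residual(sub, p)
    ssc <- which(fs[-1] * fs[-length(fs)] < 0)
    for (j in ssc)
      roots <- c(roots, stats::uniroot(
        .thalamo_scalar_residual, c(sub[j], sub[j + 1]), p = p,
        tol = 1e-12)$root)
  }
  states <- .dedup_states(lapply(sort(roots),
                                 .thalamo_state_from_V, p = p),
                          dedup_tol)
  eqs <- lapply(states, function(s)
    .make_equilibrium(function(x) .thalamo_rhs_raw(x, p), s,
                      stab_tol = stab_tol))
  bad <- vapply(eqs, function(e) e$residual > 1e-8, logical(1))
  .make_equilibria_set(eqs[!bad], params, "thalamocortical")
}

#' Locate the saddle-node bifurcation in the GABAergic strength
#'
#' Bisects the GABAergic strength `a` over the count of stable equilibria
#' returned by [find_equilibria()]: the loop is bistable (two stable
#' states plus a saddle) below the critical value \eqn{\hat a} and
#' monostable above it.  The bracket must straddle the regime change:
#' bistable at its lower end, monostable at its upper end.
#'
#' @param b Glutamatergic strength (fixed).
#' @param theta Self-limiting coefficient (fixed, default 1).
#' @param params Optional [thalamo_params()] template supplying the Hill
#'   constants; its `a` is ignored.
#' @param bracket Initial search interval for `a`
#'   (default `c(0.01, 0.99)`).
#' @param tol Bisection tolerance on `a` (default 1e-3).
#' @param ... Passed to [find_equilibria()].
#' @return An object of class `bifurcation_result` with fields `a_hat`,
#'   `b`, `theta`, `bracket` (final interval), `tol`.
#' @examples
#' \donttest{
#' bifurcation_point(b = 1)  # a_hat near 0.265
#' }
#' @export
bifurcation_point <- function(b, theta = 1, params = NULL,
                              bracket = c(0.01, 0.99), tol = 1e-3, ...) {
  base <- if (is.null(params)) thalamo_params(a = 0.5, b = b,
                                              theta = theta)
          else thalamo_params(a = 0.5, b = b, theta = theta,
                              tau = params$tau, m1 = params$m1,
                              m2 = params$m2, e = params$e,
                              e0 = params$e0, h = params$h)
  count <- function(a) {
    prm <- base
    prm$a <- a
    n_stable(find_equilibria(prm, ...))
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!(count(lo) >= 2L))
    stop("no bifurcation in range: system not bistable at the lower bracket end",
         call. = FALSE)
  if (count(hi) != 1L)
    stop("no bifurcation in range: system not monostable at the upper bracket end",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) >= 2L) lo <- mid else hi <- mid
  }
  structure(list(a_hat = (lo + hi) / 2, b = b, theta = theta,
                 bracket = c(lo, hi), tol = tol),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf(
    "Saddle-node bifurcation: a_hat = %.4f (b = %g, theta = %g; bracket [%.4f, %.4f])\n",
    x$a_hat, x$b, x$theta, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Bifurcation value across a grid of glutamatergic strengths
#'
#' Computes \eqn{\hat a(b)} with [bifurcation_point()] for each entry of
#' `b`.  Grid points where no regime change exists in the bracket are
#' flagged (`flag = "none"`, `a_hat = NA`) rather than dropped.
#'
#' @param b Numeric vector of glutamatergic strengths in (0, 1].
#' @param theta Self-limiting coefficient (default 1).
#' @param ... Passed to [bifurcation_point()].
#' @return Data frame with columns `b`, `theta`, `a_hat`, `flag`.
#' @export
bifurcation_curve <- function(b, theta = 1, ...) {
  stopifnot(is.numeric(b), length(b) >= 1L, all(b > 0), all(b <= 1))
  rows <- lapply(b, function(bi) {
    r <- tryCatch(bifurcation_point(bi, theta = theta, ...),
                  error = function(e) e)
    if (inherits(r, "error"))
      data.frame(b = bi, theta = theta, a_hat = NA_real_, flag = "none")
    else
      data.frame(b = bi, theta = theta, a_hat = r$a_hat, flag = "ok")
  })
  do.call(rbind, rows)
}
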