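#' Endocrine loop parameters
#'
#' Constants of the mutually inhibitory HPG-HPA system.  Each axis
#' activity `x` (0-100 scale) evolves as
#' \deqn{\tau \dot{x}_1 = f(x_2) - k(x_1) x_1}
#' (and symmetrically for the other axis), with
#' \eqn{f(x) = 100 / (1 + (x/e_x)^{h_x})} the decreasing mutual-inhibition
#' response and \eqn{k(x) = 1 + 4 / (1 + (\alpha x / e_k)^{h_k})} the
#' shifted self-limiting factor (see [shifted_self_limit()]): near 5 at
#' low activity (self-inhibition dominates), near 1 at high activity
#' (mutual inhibition dominates).  Parameters are identical for both axes.
#'
#' @param e_x Mutual-inhibition half-saturation, activity units
#'   (default 28).
#' @param h_x Mutual-inhibition Hill coefficient (default 4.2).
#' @param e_k Self-limit half-saturation (default 25.57).
#' @param h_k Self-limit Hill coefficient (default 6.6).
#' @param alpha Self-limit modulation, strictly inside (0, 1)
#'   (default 0.48).
#' @param tau Time constant in minutes (default 30).
#' @return An object of class `endocrine_params`.
#' @export
endocrine_params <- function(e_x = 28, h_x = 4.2, e_k = 25.57, h_k = 6.6,
                             alpha = 0.48, tau = 30) {
  p <- list(e_x = e_x, h_x = h_x, e_k = e_k, h_k = h_k, alpha = alpha,
            tau = tau)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number", nm),
           call. = FALSE)
  if (alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1)", call. = FALSE)
  structure(p, class = "endocrine_params")
}

#' @export
print.endocrine_params <- function(x, ...) {
  cat(sprintf(
    "HPG-HPA loop: e_x = %g, h_x = %g | e_k = %g, h_k = %g, alpha = %g | tau = %g min\n",
    x$e_x, x$h_x, x$e_k, x$h_k, x$alpha, x$tau))
  invisible(x)
}

.endo_f <- function(x, p) 100 / (1 + (x / p$e_x)^p$h_x)
.endo_k <- function(x, p) 1 + 4 / (1 + (p$alpha * x / p$e_k)^p$h_k)

#' Right-hand side of the HPG-HPA system
#'
#' @param state Numeric vector `(HPA, HPG)` of axis activities on the
#'   0-100 scale, nonnegative.
#' @param params An [endocrine_params()].
#' @return Named derivative vector `(HPA, HPG)` in activity/min.
#' @examples
#' endocrine_rhs(c(0, 0), endocrine_params())  # (100/30, 100/30)
#' @export
endocrine_rhs <- function(state, params = endocrine_params()) {
  stopifnot(inherits(params, "endocrine_params"))
  if (length(state) != 2L)
    stop("'state' must have length 2: (HPA, HPG)", call. = FALSE)
  .check_nonneg(state, "state")
  d <- .endo_rhs_raw(state, params)
  c(HPA = d[1], HPG = d[2])
}

.endo_rhs_raw <- function(state, p) {
  s <- pmax(state, 0)
  c((.endo_f(s[2], p) - .endo_k(s[1], p) * s[1]) / p$tau,
    (.endo_f(s[1], p) - .endo_k(s[2], p) * s[2]) / p$tau)
}

# steady-state residual without the time constant (same zero set)
.endo_balance <- function(s, p) {
  c(.endo_f(s[2], p) - .endo_k(s[1], p) * s[1],
    .endo_f(s[1], p) - .endo_k(s[2], p) * s[2])
}

#' Enumerate equilibria of the HPG-HPA system
#'
#' Finds all solutions of `f(HPG) = k(HPA) HPA`, `f(HPA) = k(HPG) HPG`
#' by (i) a scalar root scan of `k(x) x = f(x)` along the diagonal (the
#' system is symmetric under coordinate exchange, so symmetric equilibria
#' live there) and (ii) multi-start 2-D Newton root finding from a grid
#' over the state square, plus the exchange mirror of every candidate.
#' Roots are deduplicated within `dedup_tol` and classified by Jacobian
#' eigenvalues.
#'
#' @param params An [endocrine_params()].
#' @param n_starts Starts per axis for the multi-start grid (default 21).
#' @param dedup_tol Deduplication tolerance, activity units
#'   (default 1e-4).
#' @param stab_tol Stability threshold on eigenvalue real parts
#'   (default 1e-6).
#' @return An `equilibria_set` (see [n_stable()]); at the default
#'   parameters it holds three stable points (one symmetric, one
#'   high-HPA/low-HPG, one low-HPA/high-HPG) and a saddle pair.
#' @export
find_equilibria_endocrine <- function(params = endocrine_params(),
                                      n_starts = 21, dedup_tol = 1e-4,
                                      stab_tol = 1e-6) {
  stopifnot(inherits(params, "endocrine_params"))
  p <- params
  cand <- list()

  # (i) diagonal scan: k(x) x = f(x)
  gdiag <- function(x) .endo_f(x, p) - .endo_k(x, p) * x
  xs <- seq(0, 100, length.out = 2001)
  gs <- gdiag(xs)
  for (i in which(gs[-1] * gs[-length(gs)] < 0)) {
    r <- stats::uniroot(gdiag, c(xs[i], xs[i + 1]), tol = 1e-12)$root
    cand[[length(cand) + 1L]] <- c(r, r)
  }

  # (ii) multi-start 2-D root finding over the state square
  starts <- seq(0, 100, length.out = n_starts)
  for (x0 in starts) for (y0 in starts) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(function(s) .endo_balance(s, p),
                                      c(x0, y0), tol = 1e-13)),
      error = function(e) NULL)
    if (is.null(sol)) next
    s <- sol$x
    if (any(s < -1e-8) || any(s > 150)) next
    s <- pmax(s, 0)
    if (max(abs(.endo_balance(s, p))) > 1e-8) next
    cand[[length(cand) + 1L]] <- s
    cand[[length(cand) + 1L]] <- rev(s) # exchange symmetry
  }

  # polish mirrors and dedup
  cand <- lapply(cand, function(s) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(function(z) .endo_balance(z, p), s,
                                      tol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(sol) && max(abs(.endo_balance(sol$x, p))) <= 1e-10)
      pmax(sol$x, 0) else s
  })
  ok <- vapply(cand, function(s) max(abs(.endo_balance(s, p))) <= 1e-8,
               logical(1))
  states <- .dedup_states(cand[ok], dedup_tol)
  states <- states[order(vapply(states, function(s) s[1] - s[2] * 1e-6,
                                numeric(1)))]
  eqs <- lapply(states, function(s) {
    eq <- .make_equilibrium(function(x) .endo_rhs_raw(x, p),
                            c(HPA = s[1], HPG = s[2]),
                            stab_tol = stab_tol)
    eq
  })
  .make_equilibria_set(eqs, params, "HPG-HPA")
}

#' Simulate the HPG-HPA system
#'
#' Adaptive integration of the endocrine loop.  The final state is
#' flagged converged when the RHS norm drops below `conv_tol`, and the
#' index of the stable equilibrium reached (nearest within
#' `capture_radius`) is reported, or `"unresolved"`.
#'
#' @param initial Numeric `(HPA, HPG)` initial activities.
#' @param params An [endocrine_params()].
#' @param horizon Integration horizon in minutes (default 1e4).
#' @param n_out Number of reported time points (default 201).
#' @param rtol,atol Solver tolerances.
#' @param conv_tol Convergence threshold on the RHS norm, activity/min.
#' @param capture_radius Distance within which the endpoint is attributed
#'   to a stable equilibrium, activity units (default 0.5).
#' @param equilibria Optional precomputed `equilibria_set` (recomputed
#'   otherwise).
#' @return A data frame of class `endocrine_sim` with columns
#'   `time, HPA, HPG`; attributes `converged`, `final`, `reached` (index
#'   into the stable equilibria or `"unresolved"`), `equilibria`,
#'   `params`.
#' @export
simulate_endocrine <- function(initial, params = endocrine_params(),
                               horizon = 1e4, n_out = 201, rtol = 1e-8,
                               atol = 1e-10, conv_tol = 1e-6,
                               capture_radius = 0.5, equilibria = NULL) {
  stopifnot(inherits(params, "endocrine_params"))
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  .check_nonneg(initial, "initial")
  times <- seq(0, horizon, length.out = max(2L, n_out))
  sol <- deSolve::ode(
    y = c(HPA = initial[[1]], HPG = initial[[2]]),
    times = times,
    func = function(t, y, p) list(.endo_rhs_raw(y, p)),
    parms = params, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("solver failure in the endocrine system", call. = FALSE)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  final <- unlist(out[nrow(out), c("HPA", "HPG")])
  converged <- max(abs(.endo_rhs_raw(final, params))) < conv_tol
  if (is.null(equilibria))
    equilibria <- find_equilibria_endocrine(params)
  stable <- Filter(function(e) e$stability == "stable", equilibria)
  reached <- "unresolved"
  if (length(stable)) {
    d <- vapply(stable, function(e) sqrt(sum((e$state - final)^2)),
                numeric(1))
    if (min(d) <= capture_radius) reached <- which.min(d)
  }
  structure(out, converged = converged, final = final, reached = reached,
            equilibria = equilibria, params = params,
            class = c("endocrine_sim", "data.frame"))
}

#' @export
plot.endocrine_sim <- function(x, ...) {
  graphics::plot(x$HPA, x$HPG, type = "l", xlab = "HPA activity",
                 ylab = "HPG activity", xlim = c(0, 100),
                 ylim = c(0, 100), ...)
  eqs <- attr(x, "equilibria")
  if (!is.null(eqs)) {
    m <- as.matrix(eqs)
    st <- attr(m, "stability") == "stable"
    graphics::points(m[st, 1], m[st, 2], pch = 16)
    graphics::points(m[!st, 1], m[!st, 2], pch = 1)
  }
  invisible(x)
}

# fast attractor lookup used by basin_map: integrate with a terminal
# root at capture distance from any stable equilibrium
.endo_attractor <- function(init, p, stable_states, horizon,
                            capture_radius, rtol, atol) {
  root <- function(t, y, parms) {
    min(vapply(stable_states,
               function(s) sqrt(sum((s - y)^2)), numeric(1))) -
      capture_radius
  }
  sol <- deSolve::lsodar(
    y = init, times = c(0, horizon),
    func = function(t, y, parms) list(.endo_rhs_raw(y, p)),
    parms = NULL, rtol = rtol, atol = atol, rootfunc = root)
  final <- sol[nrow(sol), -1]
  d <- vapply(stable_states, function(s) sqrt(sum((s - final)^2)),
              numeric(1))
  if (min(d) <= capture_radius) which.min(d) else NA_integer_
}

#' Map the basins of attraction of the HPG-HPA system
#'
#' Labels every point of a regular grid over the state square
#' `[0, 100] x [0, 100]` by the stable equilibrium its trajectory
#' reaches (integration stops as soon as the trajectory enters the
#' capture radius of a stable point).  Points that reach no attractor
#' within the horizon are labelled 0 ("unresolved") rather than dropped.
#'
#' @param params An [endocrine_params()].
#' @param n Grid resolution per axis (default 101).
#' @param horizon Integration horizon in minutes (default 1e4).
#' @param capture_radius Capture distance, activity units (default 0.5).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @return An object of class `basin_map`: list with `x`, `y` (grid
#'   coordinates), `label` (matrix of stable-equilibrium indices, 0 =
#'   unresolved), `equilibria` (the stable set, in the
#'   [find_equilibria_endocrine()] order), `fractions` (grid fraction per
#'   basin) and `unresolved`.
#' @export
basin_map <- function(params = endocrine_params(), n = 101,
                      horizon = 1e4, capture_radius = 0.5, rtol = 1e-8,
                      atol = 1e-10) {
  stopifnot(inherits(params, "endocrine_params"))
  eqs <- find_equilibria_endocrine(params)
  stable <- Filter(function(e) e$stability == "stable", eqs)
  if (!length(stable))
    stop("no stable equilibrium at these parameters", call. = FALSE)
  stable_states <- lapply(stable, function(e) unname(e$state))
  xg <- seq(0, 100, length.out = n)
  yg <- seq(0, 100, length.out = n)
  lab <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- .endo_attractor(c(xg[i], yg[j]), params, stable_states,
                         horizon, capture_radius, rtol, atol)
    lab[i, j] <- if (is.na(r)) 0L else r
  }
  fractions <- vapply(seq_along(stable_states),
                      function(k) mean(lab == k), numeric(1))
  names(fractions) <- vapply(stable_states, function(s)
    sprintf("HPA=%.2f,HPG=%.2f", s[1], s[2]), character(1))
  structure(list(x = xg, y = yg, label = lab,
                 equilibria = stable, fractions = fractions,
                 unresolved = sum(lab == 0L), params = params),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("Basin map on a %d x %d grid over [0,100]^2\n",
              length(x$x), length(x$y)))
  for (k in seq_along(x$fractions))
    cat(sprintf("  basin %d (%s): %.1f%% of grid\n", k,
                names(x$fractions)[k], 100 * x$fractions[k]))
  if (x$unresolved)
    cat(sprintf("  unresolved points: %d\n", x$unresolved))
  invisible(x)
}

#' @export
plot.basin_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$label, col = c("grey80", "#a6cee3",
                                             "#fb9a99", "#b2df8a"),
                  xlab = "initial HPA activity",
                  ylab = "initial HPG activity", ...)
  m <- do.call(rbind, lapply(x$equilibria, function(e) e$state))
  graphics::points(m[, 1], m[, 2], pch = 16)
  invisible(x)
}

#' @export
summary.basin_map <- function(object, ...) {
  structure(list(fractions = object$fractions,
                 unresolved = object$unresolved,
                 n = length(object$x)),
            class = "summary.basin_map")
}

#' @export
print.summary.basin_map <- function(x, ...) {
  cat(sprintf("%d x %d basin map; basin fractions: %s; unresolved: %d\n",
              x$n, x$n,
              paste(sprintf("%.3f", x$fractions), collapse = ", "),
              x$unresolved))
  invisible(x)
}
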