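# Shared equilibrium plumbing: numerical Jacobians, eigenvalue-based
# stability classification, and the container returned by the equilibrium
# enumerators of both loop models.

# central-difference Jacobian of f: R^n -> R^n at x
.num_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    step <- eps * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- xp[j] + step
    xm[j] <- xm[j] - step
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

# one located steady state with spectrum and stability label.
# stable iff every real part < -stab_tol; eigenvalues within +/- stab_tol
# of zero make the point "marginal" (excluded from stable counts, which
# keeps bisection over regime changes from flickering at the fold).
.make_equilibrium <- function(rhs_fn, state, stab_tol = 1e-6) {
  J <- .num_jacobian(rhs_fn, state)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stability <-
    if (max(re) < -stab_tol) "stable"
    else if (any(abs(re) <= stab_tol)) "marginal"
    else if (min(re) < -stab_tol) "saddle"
    else "unstable"
  structure(list(state = state,
                 eigenvalues = ev,
                 stability = stability,
                 residual = max(abs(rhs_fn(state)))),
            class = "loop_equilibrium")
}

#' @export
print.loop_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium at (%s); max Re(eig) = %.3g, residual = %.2g\n",
              x$stability,
              paste(sprintf("%.4f", x$state), collapse = ", "),
              max(Re(x$eigenvalues)), x$residual))
  invisible(x)
}

.make_equilibria_set <- function(eqs, params, system) {
  structure(eqs, params = params, system = system,
            class = "equilibria_set")
}

#' Number of stable equilibria in an enumeration
#'
#' @param eqs An `equilibria_set` as returned by [find_equilibria()] or
#'   [find_equilibria_endocrine()].
#' @return Integer count of equilibria classified stable (marginal points
#'   are excluded).
#' @export
n_stable <- function(eqs) {
  stopifnot(inherits(eqs, "equilibria_set"))
  sum(vapply(eqs, function(e) e$stability == "stable", logical(1)))
}

#' @export
print.equilibria_set <- function(x, ...) {
  cat(sprintf("%d equilibria of the %s system (%d stable):\n",
              length(x), attr(x, "system"), n_stable(x)))
  for (e in x) print(e)
  invisible(x)
}

#' Extract equilibrium states as a matrix
#'
#' @param x An `equilibria_set`.
#' @param ... Unused.
#' @return Numeric matrix, one row per equilibrium, plus a `stability`
#'   column attribute.
#' @export
as.matrix.equilibria_set <- function(x, ...) {
  m <- do.call(rbind, lapply(x, function(e) e$state))
  attr(m, "stability") <- vapply(x, function(e) e$stability, character(1))
  m
}

# deduplicate candidate states within a Euclidean tolerance
.dedup_states <- function(states, tol) {
  keep <- list()
  for (s in states) {
    dup <- any(vapply(keep, function(k)
      sqrt(sum((k - s)^2)) < tol, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- s
  }
  keep
}
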