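#' Coupling configuration between the endocrine and thalamocortical loops
#'
#' Monotone maps translating the endocrine steady state into the coupling
#' strengths of the thalamocortical loop.  The source material anchors the
#' endpoints (withdrawal allopregnanolone 1.6 ng/mL, follicular 2.4,
#' luteal 20; physiological glutamatergic strength b = 0.5, excitotoxic
#' b = 1, stressed b = 0.6 at full HPA activation) but prescribes no
#' functional form, so the defaults are the simplest monotone
#' interpolants through those anchors and are labelled "configured" in
#' scenario reports.
#'
#' @param hpg_to_A Function mapping HPG activity (0-100) to brain
#'   allopregnanolone ng/mL; default piecewise-linear through
#'   (0, 1.6), (`hpg_low`, 2.4), (100, 20), clamped outside.
#' @param hpa_to_b Function mapping HPA activity (0-100) to glutamatergic
#'   strength; default `b = 0.5 * (1 + 0.2 * HPA / 100)` (0.5 at rest,
#'   0.6 at full activation, a 20 percent rise).
#' @param hpg_low HPG activity treated as the follicular ("low") anchor
#'   (default 20).
#' @param b_anchors Named reference values
#'   `c(excitotoxic = 1, physiological = 0.5, stressed = 0.6)`.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(hpg_to_A = NULL, hpa_to_b = NULL,
                            hpg_low = 20,
                            b_anchors = c(excitotoxic = 1,
                                          physiological = 0.5,
                                          stressed = 0.6)) {
  if (is.null(hpg_to_A))
    hpg_to_A <- stats::approxfun(c(0, hpg_low, 100), c(1.6, 2.4, 20),
                                 rule = 2)
  if (is.null(hpa_to_b))
    hpa_to_b <- function(HPA) 0.5 * (1 + 0.2 * HPA / 100)
  stopifnot(is.function(hpg_to_A), is.function(hpa_to_b))
  # monotonicity and range sanity on a probe grid
  probe <- seq(0, 100, length.out = 51)
  A <- hpg_to_A(probe)
  b <- hpa_to_b(probe)
  if (any(diff(A) < -1e-12) || any(diff(b) < -1e-12))
    stop("coupling maps must be monotone nondecreasing", call. = FALSE)
  if (any(A < 0) || any(b <= 0) || any(b > 1))
    stop("coupling outputs must satisfy A >= 0 and b in (0, 1]",
         call. = FALSE)
  structure(list(hpg_to_A = hpg_to_A, hpa_to_b = hpa_to_b,
                 b_anchors = b_anchors),
            class = "coupling_config")
}

#' Classify the thalamocortical regime at given coupling strengths
#'
#' Computes the critical GABAergic strength \eqn{\hat a(b, \theta)} with
#' [bifurcation_point()] and compares: the loop is bistable (the
#' pathogenic, chronic-pain-prone regime) exactly when `a` falls below
#' \eqn{\hat a}.
#'
#' @param a GABAergic strength in (0, 1].
#' @param b Glutamatergic strength in (0, 1].
#' @param theta Self-limiting coefficient (default 1).
#' @param ... Passed to [bifurcation_point()].
#' @return List with `regime` (`"bistable"` or `"monostable"`), `a`,
#'   `a_hat` and the full `bifurcation` result.
#' @examples
#' \donttest{
#' classify_regime(a = 0.13, b = 0.6)$regime  # "bistable"
#' }
#' @export
classify_regime <- function(a, b, theta = 1, ...) {
  stopifnot(a > 0, a <= 1)
  bp <- bifurcation_point(b = b, theta = theta, ...)
  list(regime = if (a < bp$a_hat) "bistable" else "monostable",
       a = a, a_hat = bp$a_hat, bifurcation = bp)
}

#' Run the coupled endocrine-to-thalamocortical scenario
#'
#' Simulates the endocrine loop to steady state from a given initial
#' condition, maps the resulting HPG activity to brain allopregnanolone
#' and on to GABAergic strength (via [gaba_strength()]) and the HPA
#' activity to glutamatergic strength, classifies the thalamocortical
#' regime at those strengths, and - when bistable - enumerates the loop
#' equilibria and reports the high-firing-rate state.  Every intermediate
#' is recorded with its provenance (`"computed"` from the dynamics or
#' `"configured"` by the coupling choice).
#'
#' @param initial Numeric `(HPA, HPG)` endocrine initial condition.
#' @param coupling A [coupling_config()].
#' @param endocrine A [endocrine_params()].
#' @param steroid_map A [steroid_map_params()].
#' @param theta Thalamocortical self-limiting coefficient (default 1).
#' @param horizon Endocrine integration horizon, minutes (default 1e4).
#' @param ... Passed to [simulate_endocrine()].
#' @return An object of class `fm_scenario`: a named list of steps, each
#'   `list(value, provenance)`, including `regime` and (when bistable)
#'   `high_firing_state`.  An unresolved endocrine run yields
#'   `regime = "indeterminate"`.
#' @export
run_scenario <- function(initial, coupling = coupling_config(),
                         endocrine = endocrine_params(),
                         steroid_map = steroid_map_params(),
                         theta = 1, horizon = 1e4, ...) {
  stopifnot(inherits(coupling, "coupling_config"))
  sim <- simulate_endocrine(initial, endocrine, horizon = horizon, ...)
  final <- attr(sim, "final")
  step <- function(value, provenance) list(value = value,
                                           provenance = provenance)
  rep <- list(initial = step(initial, "configured"),
              endocrine_final = step(final, "computed"),
              endocrine_converged = step(attr(sim, "converged"),
                                         "computed"),
              endocrine_equilibrium = step(attr(sim, "reached"),
                                           "computed"))
  if (!isTRUE(attr(sim, "converged"))) {
    rep$regime <- step("indeterminate", "computed")
    return(structure(rep, class = "fm_scenario"))
  }
  A <- coupling$hpg_to_A(final[["HPG"]])
  a <- gaba_strength(A, steroid_map)
  b <- coupling$hpa_to_b(final[["HPA"]])
  rep$A <- step(A, "configured")
  rep$a <- step(a, "computed")
  rep$b <- step(b, "configured")
  cls <- classify_regime(a = a, b = b, theta = theta)
  rep$a_hat <- step(cls$a_hat, "computed")
  rep$regime <- step(cls$regime, "computed")
  if (cls$regime == "bistable") {
    eqs <- find_equilibria(thalamo_params(a = a, b = b, theta = theta))
    stable <- Filter(function(e) e$stability == "stable", eqs)
    hi <- stable[[which.max(vapply(stable, function(e) e$state[["V"]],
                                   numeric(1)))]]
    rep$high_firing_state <- step(hi$state, "computed")
  }
  structure(rep, class = "fm_scenario")
}

#' @export
print.fm_scenario <- function(x, ...) {
  cat("Coupled endocrine-thalamocortical scenario:\n")
  for (nm in names(x)) {
    v <- x[[nm]]$value
    vs <- if (is.numeric(v) && length(v) > 1L)
      paste(sprintf("%s = %.4g", names(v), v), collapse = ", ")
    else if (is.numeric(v)) sprintf("%.4g", v)
    else as.character(v)
    cat(sprintf("  %-24s [%s] %s\n", nm, x[[nm]]$provenance, vs))
  }
  invisible(x)
}

#' Predicted gender prevalence from withdrawal-episode probabilities
#'
#' A woman experiences one allopregnanolone withdrawal episode per
#' reproductive cycle, so her daily episode probability is
#' `cycles / (years * days_per_year)`; the male daily probability of a
#' neurosteroid withdrawal episode is supplied directly.  The predicted
#' prevalence ratio is `G = p_woman / p_man` and the corresponding
#' fraction of women among patients is `100 G / (G + 1)`.  The unrounded
#' daily probability is used throughout (rounding it to two digits first
#' would not reproduce the printed ratio).
#'
#' @param cycles Total reproductive cycles per woman (default 460).
#' @param years Reproductive span in years (default 37).
#' @param p_man Daily male withdrawal probability (default 0.005,
#'   positive).
#' @param days_per_year Days per year (default 365).
#' @return An object of class `fm_prevalence`: list with `p_woman`, `G`,
#'   `percent_women`.
#' @examples
#' prevalence()  # G about 6.8, about 87.2% women
#' @export
prevalence <- function(cycles = 460, years = 37, p_man = 0.005,
                       days_per_year = 365) {
  stopifnot(is.numeric(cycles), cycles >= 0, is.numeric(years),
            years > 0, is.numeric(days_per_year), days_per_year > 0)
  if (!is.numeric(p_man) || p_man <= 0)
    stop("'p_man' must be positive", call. = FALSE)
  p_woman <- cycles / (years * days_per_year)
  G <- p_woman / p_man
  structure(list(p_woman = p_woman, G = G,
                 percent_women = 100 * G / (G + 1)),
            class = "fm_prevalence")
}

#' @export
print.fm_prevalence <- function(x, ...) {
  cat(sprintf(
    "Predicted prevalence: p_woman = %.4g/day, G = %.3g, %.1f%% women among patients\n",
    x$p_woman, x$G, x$percent_women))
  invisible(x)
}
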