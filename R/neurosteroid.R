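#' Allopregnanolone-to-GABAergic-strength map parameters
#'
#' Constants of the two-component Hill map from brain allopregnanolone
#' concentration `A` (ng/mL) to the GABAergic strength `a` of the
#' thalamocortical loop:
#' \deqn{a(A) = a_f \frac{A^{h_w}}{e_w^{h_w} + A^{h_w}} +
#'       (1 - a_f) \frac{A^{h_g}}{e_g^{h_g} + A^{h_g}}}
#' The first (withdrawal) component captures the genomic effect on GABA-A
#' alpha-4 subunit expression at sub-follicular concentrations; the second
#' (allosteric) component the positive allosteric modulation of GABA-A
#' activity at follicular-to-pregnancy concentrations.
#'
#' @param a_f GABAergic strength at the follicular level (default 0.4).
#' @param e_w Withdrawal half-saturation, ng/mL (default 1.8).
#' @param h_w Withdrawal Hill coefficient (default 6.5).
#' @param e_g Allosteric half-saturation, ng/mL (default 18).
#' @param h_g Allosteric Hill coefficient (default 2).
#' @return An object of class `steroid_map_params`.
#' @export
steroid_map_params <- function(a_f = 0.4, e_w = 1.8, h_w = 6.5,
                               e_g = 18, h_g = 2) {
  if (!is.numeric(a_f) || a_f <= 0 || a_f >= 1)
    stop("'a_f' must lie strictly inside (0, 1)", call. = FALSE)
  for (v in list(e_w = e_w, h_w = h_w, e_g = e_g, h_g = h_g))
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("all half-saturations and Hill coefficients must be positive",
           call. = FALSE)
  structure(list(a_f = a_f, e_w = e_w, h_w = h_w, e_g = e_g, h_g = h_g),
            class = "steroid_map_params")
}

#' @export
print.steroid_map_params <- function(x, ...) {
  cat(sprintf(
    "Allopregnanolone map: a_f = %g | withdrawal (e_w = %g ng/mL, h_w = %g) | allosteric (e_g = %g ng/mL, h_g = %g)\n",
    x$a_f, x$e_w, x$h_w, x$e_g, x$h_g))
  invisible(x)
}

#' GABAergic strength from brain allopregnanolone
#'
#' Evaluates the two-component map (see [steroid_map_params()]).  The
#' result is strictly increasing in `A` and bounded above by 1.
#'
#' @param A Brain allopregnanolone concentration(s), ng/mL, nonnegative.
#' @param params A [steroid_map_params()].
#' @return GABAergic strength in `[0, 1)`.
#' @examples
#' gaba_strength(c(1.6, 18))  # about 0.13 and 0.70
#' @export
gaba_strength <- function(A, params = steroid_map_params()) {
  stopifnot(inherits(params, "steroid_map_params"))
  .check_nonneg(A, "A")
  p <- params
  .hill_up(A, p$a_f, p$e_w, p$h_w) + .hill_up(A, 1 - p$a_f, p$e_g, p$h_g)
}

#' Follicular GABAergic strength from the maximal fold increase
#'
#' The follicular strength solves `a_f + fold * a_f = 1`: the maximal
#' allopregnanolone-induced increase of GABA-A activity (a `fold` of 1.5,
#' i.e. 150 percent, the mean of reported 100 and 200 percent maxima)
#' carries the follicular baseline to the saturating value 1.
#'
#' @param max_fold_increase Positive fold increase (default 1.5).
#' @return `a_f = 1 / (1 + fold)`.
#' @examples
#' follicular_af(1.5)  # 0.4
#' @export
follicular_af <- function(max_fold_increase = 1.5) {
  if (!is.numeric(max_fold_increase) || max_fold_increase <= 0)
    stop("'max_fold_increase' must be positive", call. = FALSE)
  1 / (1 + max_fold_increase)
}

#' Fold decrease of the integrated GABA-A current
#'
#' With exponential current decay `I(t) = I0 exp(-t/tau)`, the total
#' charge is `I0 * tau`, so a change of the decay time constant from
#' `tau_ref` to `tau_new` scales the integrated current by
#' `tau_ref / tau_new` (closed form of the integral ratio).
#'
#' @param tau_ref Reference decay time constant (positive).
#' @param tau_new New decay time constant (positive).
#' @return Fold decrease of the total integrated current.
#' @examples
#' integrated_current_ratio(1, 1/6)  # 6
#' @export
integrated_current_ratio <- function(tau_ref, tau_new) {
  if (!is.numeric(tau_ref) || any(tau_ref <= 0) ||
      !is.numeric(tau_new) || any(tau_new <= 0))
    stop("time constants must be positive", call. = FALSE)
  tau_ref / tau_new
}

#' GABAergic strength at allopregnanolone withdrawal
#'
#' Applies a fold decrease of integrated GABA-A current to the follicular
#' strength: `a_w = a_f / fold`.  The applied fold defaults to 3, the
#' value used downstream of the current-integral argument (the exact
#' integral ratio for a 6-fold time-constant drop is 6; see
#' [integrated_current_ratio()] - both numbers are reported by
#' [calibration_chain()]).
#'
#' @param a_f Follicular GABAergic strength.
#' @param current_fold_decrease Fold decrease, at least 1 (default 3).
#' @return Withdrawal strength `a_f / fold`.
#' @examples
#' withdrawal_a(0.4, 3)  # 0.1333...
#' @export
withdrawal_a <- function(a_f, current_fold_decrease = 3) {
  if (!is.numeric(a_f) || a_f <= 0)
    stop("'a_f' must be positive", call. = FALSE)
  if (!is.numeric(current_fold_decrease) || current_fold_decrease < 1)
    stop("'current_fold_decrease' must be at least 1", call. = FALSE)
  a_f / current_fold_decrease
}

#' Estimate a brain level from a plasma level via a reference ratio
#'
#' Scales a plasma concentration by a measured brain/plasma ratio (by
#' default the luteal-phase allopregnanolone ratio 20/1.2) to estimate the
#' corresponding brain concentration.
#'
#' @param plasma Plasma concentration, ng/mL (positive).
#' @param ref_brain Reference brain concentration, ng/mL (default 20).
#' @param ref_plasma Reference plasma concentration, ng/mL (default 1.2).
#' @return Estimated brain level with attribute
#'   `provenance = "ratio-estimated"`.
#' @examples
#' brain_from_plasma(0.15)  # 2.5 (the source table prints 2.4)
#' @export
brain_from_plasma <- function(plasma, ref_brain = 20, ref_plasma = 1.2) {
  if (!is.numeric(plasma) || any(plasma <= 0))
    stop("'plasma' must be positive", call. = FALSE)
  if (!is.numeric(ref_brain) || ref_brain <= 0)
    stop("'ref_brain' must be positive", call. = FALSE)
  if (!is.numeric(ref_plasma) || ref_plasma <= 0)
    stop("'ref_plasma' must be positive (zero reference plasma is undefined)",
         call. = FALSE)
  structure(plasma * ref_brain / ref_plasma, provenance = "ratio-estimated")
}

#' Estimate the withdrawal brain allopregnanolone level
#'
#' Scales the follicular brain level by the plasma drop observed in the
#' finasteride withdrawal paradigm (plasma 9 to 6 ng/mL), assuming the
#' same proportional reduction holds in brain.
#'
#' @param follicular_brain Follicular brain level, ng/mL (default 2.4).
#' @param plasma_pre Pre-withdrawal plasma level, ng/mL (default 9).
#' @param plasma_post Post-withdrawal plasma level, ng/mL (default 6);
#'   must not exceed `plasma_pre`.
#' @return Withdrawal brain level, ng/mL.
#' @examples
#' estimate_withdrawal_level()  # 1.6
#' @export
estimate_withdrawal_level <- function(follicular_brain = 2.4,
                                      plasma_pre = 9, plasma_post = 6) {
  for (v in list(follicular_brain, plasma_pre, plasma_post))
    if (!is.numeric(v) || v <= 0)
      stop("all levels must be positive", call. = FALSE)
  if (plasma_post > plasma_pre)
    stop("'plasma_post' exceeds 'plasma_pre': not a withdrawal",
         call. = FALSE)
  follicular_brain * plasma_post / plasma_pre
}

#' Calibrate the withdrawal Hill component
#'
#' Solves for the withdrawal half-saturation and Hill coefficient
#' `(e_w, h_w)` from two constraints: the full map must pass through the
#' withdrawal point (`gaba_strength(A_w) = a_w`), and the withdrawal
#' component alone must have essentially saturated at the follicular
#' level (`f_w(A_sat) = sat_fraction * a_f`).  The two-equation system is
#' solved by 2-D root finding (a closed-form reduction provides the
#' start, a Newton polish enforces residuals below 1e-8), with bounds
#' `e_w` in `(0, A_sat]` and `h_w` in `[1, 20]`; an infeasible
#' constraint set raises an error rather than returning a spurious fit.
#'
#' @param a_f Follicular strength (default 0.4).
#' @param A_w Withdrawal brain level, ng/mL (default 1.6).
#' @param a_w Strength at withdrawal, in `(0, a_f)` (default 0.13).
#' @param e_g,h_g Allosteric component constants (defaults 18, 2).
#' @param A_sat Level at which the withdrawal component saturates,
#'   ng/mL (default 2.4, the follicular brain level).
#' @param sat_fraction Fraction of `a_f` reached at `A_sat`, in
#'   (0.5, 1) (default 0.866, the value implied by the published
#'   constants).
#' @return List with `e_w`, `h_w`, `residual` (max constraint residual)
#'   and `spec`, the calibrated [steroid_map_params()].
#' @examples
#' calibrate_withdrawal_hill()  # e_w about 1.8, h_w about 6.5
#' @export
calibrate_withdrawal_hill <- function(a_f = 0.4, A_w = 1.6, a_w = 0.13,
                                      e_g = 18, h_g = 2, A_sat = 2.4,
                                      sat_fraction = 0.866) {
  if (!(a_w > 0 && a_w < a_f))
    stop("'a_w' must lie strictly between 0 and 'a_f'", call. = FALSE)
  if (!(A_w > 0 && A_w < A_sat))
    stop("'A_w' must be positive and below 'A_sat'", call. = FALSE)
  if (!(sat_fraction > 0.5 && sat_fraction < 1))
    stop("'sat_fraction' must lie in (0.5, 1)", call. = FALSE)

  infeasible <- function(msg)
    stop(sprintf("no root in bounds (e_w in (0, A_sat], h_w in [1, 20]): %s",
                 msg), call. = FALSE)

  # closed-form reduction: subtract the allosteric part at A_w, then
  # eliminate e_w between the two Hill constraints
  fg_w <- .hill_up(A_w, 1 - a_f, e_g, h_g)
  t1 <- a_w - fg_w
  if (t1 <= 0 || t1 >= a_f)
    infeasible("withdrawal target is outside the reachable band")
  r1 <- a_f / t1 - 1                       # (e_w / A_w)^h_w
  r2 <- (1 - sat_fraction) / sat_fraction  # (e_w / A_sat)^h_w
  h_w <- log(r1 / r2) / log(A_sat / A_w)
  if (!is.finite(h_w) || h_w < 1 || h_w > 20)
    infeasible(sprintf("implied h_w = %.3g", h_w))
  e_w <- A_sat * r2^(1 / h_w)
  if (!(e_w > 0 && e_w <= A_sat))
    infeasible(sprintf("implied e_w = %.3g", e_w))

  resid <- function(p) {
    c(.hill_up(A_w, a_f, p[1], p[2]) + fg_w - a_w,
      .hill_up(A_sat, a_f, p[1], p[2]) - sat_fraction * a_f)
  }
  sol <- tryCatch(
    suppressWarnings(pracma::fsolve(resid, c(e_w, h_w), tol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(sol) && max(abs(resid(sol$x))) <= max(abs(resid(c(e_w, h_w)))))
    { e_w <- sol$x[1]; h_w <- sol$x[2] }
  r <- max(abs(resid(c(e_w, h_w))))
  if (r > 1e-8)
    infeasible(sprintf("constraint residual %.2g", r))
  list(e_w = e_w, h_w = h_w, residual = r,
       spec = steroid_map_params(a_f = a_f, e_w = e_w, h_w = h_w,
                                 e_g = e_g, h_g = h_g))
}

#' Run the full neurosteroid calibration chain
#'
#' Composes every calibration step from the published constants and
#' reports each intermediate with its provenance: the follicular strength
#' from the 150 percent maximal increase; the exact integrated-current
#' ratio for the 6-fold time-constant drop alongside the applied 3-fold
#' factor; the withdrawal strength; the ratio-estimated follicular brain
#' level; the finasteride-derived withdrawal brain level; and the
#' calibrated withdrawal Hill component.
#'
#' @param max_fold_increase Maximal GABA-A activity increase (default 1.5).
#' @param tau_fold_decrease Fold decrease of the current time constant
#'   (default 6).
#' @param applied_current_fold Fold decrease applied to `a_f`
#'   (default 3).
#' @param follicular_plasma Follicular plasma level, ng/mL (default 0.15).
#' @param ref_brain,ref_plasma Luteal reference levels, ng/mL
#'   (defaults 20, 1.2).
#' @param follicular_brain Follicular brain level used downstream,
#'   ng/mL (default 2.4, the printed value; the raw ratio arithmetic
#'   gives 2.5 and is reported alongside).
#' @param plasma_pre,plasma_post Finasteride plasma levels, ng/mL
#'   (defaults 9, 6).
#' @param e_g,h_g Allosteric constants (defaults 18, 2).
#' @param A_sat,sat_fraction Saturation constraint for
#'   [calibrate_withdrawal_hill()].
#' @return An object of class `steroid_chain`: a list of steps, each with
#'   `value` and `provenance` (`"computed"` or `"configured"`).
#' @export
calibration_chain <- function(max_fold_increase = 1.5,
                              tau_fold_decrease = 6,
                              applied_current_fold = 3,
                              follicular_plasma = 0.15,
                              ref_brain = 20, ref_plasma = 1.2,
                              follicular_brain = 2.4,
                              plasma_pre = 9, plasma_post = 6,
                              e_g = 18, h_g = 2,
                              A_sat = follicular_brain,
                              sat_fraction = 0.866) {
  a_f <- follicular_af(max_fold_increase)
  exact_fold <- integrated_current_ratio(1, 1 / tau_fold_decrease)
  a_w <- withdrawal_a(a_f, applied_current_fold)
  brain_arith <- brain_from_plasma(follicular_plasma, ref_brain,
                                   ref_plasma)
  A_w <- estimate_withdrawal_level(follicular_brain, plasma_pre,
                                   plasma_post)
  cal <- calibrate_withdrawal_hill(a_f = a_f, A_w = A_w, a_w = a_w,
                                   e_g = e_g, h_g = h_g, A_sat = A_sat,
                                   sat_fraction = sat_fraction)
  step <- function(value, provenance) list(value = value,
                                           provenance = provenance)
  structure(list(
    a_f = step(a_f, "computed"),
    integrated_current_fold_exact = step(exact_fold, "computed"),
    integrated_current_fold_applied = step(applied_current_fold,
                                           "configured"),
    a_withdrawal = step(a_w, "computed"),
    follicular_brain_ratio_arithmetic = step(as.numeric(brain_arith),
                                             "computed"),
    follicular_brain_used = step(follicular_brain, "configured"),
    A_withdrawal = step(A_w, "computed"),
    e_w = step(cal$e_w, "computed"),
    h_w = step(cal$h_w, "computed"),
    map = step(cal$spec, "computed"),
    a_at_withdrawal_check = step(gaba_strength(A_w, cal$spec),
                                 "computed")),
    class = "steroid_chain")
}

#' @export
print.steroid_chain <- function(x, ...) {
  cat("Neurosteroid calibration chain:\n")
  for (nm in names(x)) {
    v <- x[[nm]]$value
    if (inherits(v, "steroid_map_params")) {
      cat(sprintf("  %-34s [%s] ", nm, x[[nm]]$provenance))
      print(v)
    } else {
      cat(sprintf("  %-34s [%s] %.6g\n", nm, x[[nm]]$provenance, v))
    }
  }
  invisible(x)
}
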