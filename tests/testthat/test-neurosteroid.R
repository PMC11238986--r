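test_that("the allopregnanolone map hits the calibrated anchor points", {
  expect_equal(gaba_strength(0), 0)
  expect_equal(gaba_strength(1.6), 0.13, tolerance = 0.005 / 0.13)
  expect_equal(gaba_strength(18), 0.70, tolerance = 0.005 / 0.70)
  # closed-form cross-check at the withdrawal point
  byhand <- oracle_hill_up(1.6, 0.4, 1.8, 6.5) +
    oracle_hill_up(1.6, 0.6, 18, 2)
  expect_equal(gaba_strength(1.6), byhand, tolerance = 1e-12)
  expect_error(gaba_strength(-2), "nonnegative")
})

test_that("the map is strictly increasing and bounded by 1", {
  A <- seq(0, 500, length.out = 4000)
  a <- gaba_strength(A)
  expect_true(all(diff(a) > 0))
  expect_true(all(a < 1))
  expect_gt(gaba_strength(1e4), 0.99)
})

test_that("component dominance switches across the transition zone", {
  p <- steroid_map_params()
  num_deriv <- function(f, x, eps = 1e-6) (f(x + eps) - f(x - eps)) / (2 * eps)
  fw <- function(A) oracle_hill_up(A, p$a_f, p$e_w, p$h_w)
  fg <- function(A) oracle_hill_up(A, 1 - p$a_f, p$e_g, p$h_g)
  for (A in seq(0.8, 1.8, by = 0.2)) # below ~e_w: withdrawal term steeper
    expect_gt(num_deriv(fw, A), num_deriv(fg, A))
  for (A in seq(20, 60, by = 10)) # above e_g: allosteric term steeper
    expect_gt(num_deriv(fg, A), num_deriv(fw, A))
})

test_that("the scalar calibration steps reproduce the published constants", {
  expect_equal(follicular_af(1.5), 0.4)
  expect_equal(follicular_af(1.0), 0.5)
  expect_equal(follicular_af(2.0), 1 / 3)
  expect_equal(integrated_current_ratio(1, 1), 1)
  expect_equal(integrated_current_ratio(1, 1 / 6), 6)
  expect_equal(integrated_current_ratio(2, 1), 2)
  expect_error(integrated_current_ratio(0, 1), "positive")
  expect_equal(withdrawal_a(0.4, 3), 0.4 / 3)
  expect_equal(round(withdrawal_a(0.4, 3), 2), 0.13)
  expect_equal(withdrawal_a(0.4, 1), 0.4)
  expect_equal(withdrawal_a(0.6, 2), 0.3)
  expect_error(withdrawal_a(0.4, 0.5), "at least 1")
})

test_that("brain levels follow the reference ratio arithmetic", {
  expect_equal(as.numeric(brain_from_plasma(0.15)), 2.5)
  expect_equal(as.numeric(brain_from_plasma(1.2)), 20) # identity at ref
  expect_equal(as.numeric(brain_from_plasma(16)), 266.6667,
               tolerance = 1e-6)
  expect_equal(attr(brain_from_plasma(0.15), "provenance"),
               "ratio-estimated")
  expect_error(brain_from_plasma(1, ref_plasma = 0), "positive")
  expect_equal(estimate_withdrawal_level(), 1.6)
  expect_equal(estimate_withdrawal_level(2.4, 9, 9), 2.4)
  expect_equal(estimate_withdrawal_level(3.0, 10, 5), 1.5)
  expect_error(estimate_withdrawal_level(2.4, 6, 9), "not a withdrawal")
})

test_that("withdrawal-component calibration recovers the published Hill pair", {
  cal <- calibrate_withdrawal_hill()
  expect_equal(cal$e_w, 1.8, tolerance = 0.05)
  expect_equal(cal$h_w, 6.5, tolerance = 0.05)
  expect_lt(cal$residual, 1e-8)
  # the defining constraint round-trips through the full map
  expect_equal(gaba_strength(1.6, cal$spec), 0.13, tolerance = 1e-8)
  # infeasible saturation demand fails explicitly
  expect_error(calibrate_withdrawal_hill(A_w = 1.6, A_sat = 1.7,
                                         sat_fraction = 0.999),
               "no root in bounds")
})

test_that("the full calibration chain reproduces its own constraints", {
  ch <- calibration_chain()
  expect_equal(ch$a_f$value, 0.4)
  expect_equal(ch$integrated_current_fold_exact$value, 6)
  expect_equal(ch$integrated_current_fold_applied$value, 3)
  expect_equal(ch$a_withdrawal$value, 0.4 / 3)
  expect_equal(ch$follicular_brain_ratio_arithmetic$value, 2.5)
  expect_equal(ch$A_withdrawal$value, 1.6)
  # the calibrated map sends the withdrawal level to the withdrawal strength
  expect_equal(ch$a_at_withdrawal_check$value, ch$a_withdrawal$value,
               tolerance = 1e-8)
  expect_equal(ch$e_w$value, 1.8, tolerance = 0.05)
  expect_equal(ch$h_w$value, 6.5, tolerance = 0.05)
  provs <- vapply(ch, function(s) s$provenance, character(1))
  expect_setequal(unique(provs), c("computed", "configured"))
})
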