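test_that("the right-hand side matches an independent hand evaluation", {
  p <- thalamo_params(a = 0.3, b = 1)
  expect_equal(unname(thalamo_rhs(c(0, 0, 0), p)), c(0, 0, 0))
  # VPL excites SSC: from (0, 0, V > 0) the cortex is driven up
  d <- thalamo_rhs(c(0, 0, 15), p)
  expect_gt(d[["S"]], 0)
  expect_equal(d[["V"]], -15 / 0.5) # drive vanishes without cortical input
  expect_equal(unname(thalamo_rhs(c(10, 10, 10), p)),
               oracle_thalamo_rhs(10, 10, 10, a = 0.3, b = 1),
               tolerance = 1e-12)
  # a second parameter point, off defaults
  p2 <- thalamo_params(a = 0.7, b = 0.5, theta = 0.8)
  expect_equal(unname(thalamo_rhs(c(30, 40, 25), p2)),
               oracle_thalamo_rhs(30, 40, 25, a = 0.7, b = 0.5,
                                  theta = 0.8),
               tolerance = 1e-12)
  expect_error(thalamo_rhs(c(-1, 0, 0), p), "nonnegative")
  expect_error(thalamo_params(a = 1.5, b = 1), "'a'")
})

test_that("equilibrium enumeration matches the known regime structure", {
  mono <- find_equilibria(thalamo_params(a = 0.3, b = 1))
  expect_equal(n_stable(mono), 1)
  bi <- find_equilibria(thalamo_params(a = 0.2, b = 1))
  expect_equal(n_stable(bi), 2)
  labs <- vapply(bi, function(e) e$stability, character(1))
  expect_equal(sum(labs == "saddle"), 1)
  half <- find_equilibria(thalamo_params(a = 0.13, b = 0.5))
  expect_equal(n_stable(half), 1)
  # every reported equilibrium satisfies the dynamics to tight tolerance
  for (eqs in list(mono, bi, half))
    for (e in eqs) expect_lt(e$residual, 1e-8)
})

test_that("the origin is an equilibrium for every admissible parameter set", {
  set.seed(11)
  for (i in 1:10) {
    p <- thalamo_params(a = runif(1, 0.05, 1), b = runif(1, 0.05, 1),
                        theta = runif(1, 0.3, 1))
    expect_equal(unname(thalamo_rhs(c(0, 0, 0), p)), c(0, 0, 0))
    eqs <- find_equilibria(p)
    m <- as.matrix(eqs)
    expect_true(any(rowSums(abs(m)) < 1e-8))
  }
})

test_that("simulation respects fixed points, basins and forward invariance", {
  p <- thalamo_params(a = 0.2, b = 1)
  eqs <- find_equilibria(p)
  stable <- Filter(function(e) e$stability == "stable", eqs)
  hi_state <- stable[[which.max(vapply(stable, function(e)
    e$state[["V"]], numeric(1)))]]$state
  # started at a stable equilibrium, the system stays there
  sim0 <- simulate_thalamo(hi_state, p, horizon = 30)
  expect_true(attr(sim0, "converged"))
  expect_equal(unname(attr(sim0, "final")), unname(hi_state),
               tolerance = 1e-6)
  # bistability: origin-adjacent and high initial states split
  lo_sim <- simulate_thalamo(c(1, 1, 1), p, horizon = 60)
  hi_sim <- simulate_thalamo(c(100, 80, 100), p, horizon = 60)
  expect_gt(sqrt(sum((attr(lo_sim, "final") -
                        attr(hi_sim, "final"))^2)), 10)
  # forward invariance within solver tolerance
  for (sim in list(lo_sim, hi_sim))
    expect_true(all(as.matrix(sim[c("S", "T", "V")]) >= -1e-8))
})

test_that("in the monostable regime random initial states share one attractor", {
  p <- thalamo_params(a = 0.3, b = 1)
  set.seed(2024)
  finals <- t(replicate(20, {
    init <- runif(3, 0, 100)
    attr(simulate_thalamo(init, p, horizon = 60), "final")
  }))
  expect_lt(max(apply(finals, 2, function(col) diff(range(col)))), 1e-4)
  # and the shared attractor is the enumerated stable equilibrium
  eqs <- find_equilibria(p)
  st <- Filter(function(e) e$stability == "stable", eqs)[[1]]$state
  expect_equal(unname(finals[1, ]), unname(st), tolerance = 1e-4)
})

test_that("bifurcation search reports brackets and refuses empty ranges", {
  bp <- bifurcation_point(b = 1, tol = 5e-3)
  expect_s3_class(bp, "bifurcation_result")
  expect_lte(diff(bp$bracket), 5e-3)
  expect_true(bp$a_hat > bp$bracket[1] - 1e-12 &&
                bp$a_hat < bp$bracket[2] + 1e-12)
  # bistable below, monostable above the located point
  expect_gte(n_stable(find_equilibria(
    thalamo_params(a = bp$a_hat - 0.01, b = 1))), 2)
  expect_equal(n_stable(find_equilibria(
    thalamo_params(a = bp$a_hat + 0.01, b = 1))), 1)
  expect_error(bifurcation_point(b = 1, bracket = c(0.4, 0.9)),
               "no bifurcation in range")
})

test_that("bifurcation curve flags failures instead of dropping rows", {
  single <- bifurcation_curve(0.6, tol = 5e-3)
  expect_equal(nrow(single), 1)
  expect_equal(single$flag, "ok")
  # b = 0.05 is too weak to sustain bistability anywhere in the bracket
  curve <- bifurcation_curve(c(0.05, 0.6), tol = 5e-3)
  expect_equal(curve$flag, c("none", "ok"))
  expect_true(is.na(curve$a_hat[1]))
})
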