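test_that("the endocrine right-hand side matches hand evaluation and symmetry", {
  p <- endocrine_params()
  expect_equal(unname(endocrine_rhs(c(0, 0), p)), c(100 / 30, 100 / 30),
               tolerance = 1e-12)
  expect_equal(unname(endocrine_rhs(c(50, 50), p)),
               oracle_endo_rhs(50, 50), tolerance = 1e-12)
  # exchange symmetry of the vector field: parameters are shared by the axes
  for (s in list(c(10, 70), c(33, 5), c(88, 92))) {
    d <- unname(endocrine_rhs(s, p))
    d_swap <- unname(endocrine_rhs(rev(s), p))
    expect_equal(d, rev(d_swap), tolerance = 1e-12)
  }
  # symmetric states have equal derivative components
  for (x in c(5, 20, 60))
    expect_equal(endocrine_rhs(c(x, x), p)[["HPA"]],
                 endocrine_rhs(c(x, x), p)[["HPG"]], tolerance = 1e-14)
  expect_error(endocrine_rhs(c(-1, 5), p), "nonnegative")
})

test_that("equilibrium enumeration finds the three stable states and respects symmetry", {
  eqs <- find_equilibria_endocrine()
  expect_equal(n_stable(eqs), 3)
  for (e in eqs) expect_lt(e$residual, 1e-8)
  m <- as.matrix(eqs)
  st <- attr(m, "stability")
  # the set is closed under coordinate exchange
  for (i in seq_len(nrow(m))) {
    mirror <- rev(m[i, ])
    d <- apply(m, 1, function(r) sqrt(sum((r - mirror)^2)))
    expect_lt(min(d), 1e-6)
    expect_equal(st[which.min(d)], st[i])
  }
  # one stable symmetric point with both activities in (10, 20)
  sym <- m[st == "stable" & abs(m[, 1] - m[, 2]) < 1e-6, , drop = FALSE]
  expect_equal(nrow(sym), 1)
  expect_true(all(sym > 10 & sym < 20))
  # an asymmetric stable pair: high coordinate > 80, low coordinate < 5
  asym <- m[st == "stable" & abs(m[, 1] - m[, 2]) > 1, , drop = FALSE]
  expect_equal(nrow(asym), 2)
  expect_true(all(apply(asym, 1, max) > 80))
  expect_true(all(apply(asym, 1, min) < 5))
})

test_that("the stable count is invariant under multistart grid refinement", {
  coarse <- find_equilibria_endocrine(n_starts = 21)
  fine <- find_equilibria_endocrine(n_starts = 42)
  expect_equal(n_stable(coarse), n_stable(fine))
  expect_equal(length(coarse), length(fine))
})

test_that("trajectories stay trapped and converge to the expected attractors", {
  p <- endocrine_params()
  eqs <- find_equilibria_endocrine(p)
  stable <- Filter(function(e) e$stability == "stable", eqs)
  states <- do.call(rbind, lapply(stable, function(e) e$state))
  lowlow <- states[abs(states[, 1] - states[, 2]) < 1e-6, ]
  hi_hpa <- states[states[, 1] > 80, ]
  # a stable equilibrium is a fixed point of the simulation
  sim0 <- simulate_endocrine(lowlow, p, horizon = 2000,
                             equilibria = eqs)
  expect_true(attr(sim0, "converged"))
  expect_equal(unname(attr(sim0, "final")), unname(lowlow),
               tolerance = 1e-6)
  # high-HPA/low-HPG initial conditions reach the high-HPA attractor
  sim1 <- simulate_endocrine(c(90, 5), p, equilibria = eqs)
  expect_equal(unname(attr(sim1, "final")), unname(hi_hpa),
               tolerance = 1e-4)
  # both-axes-high initial conditions fall back to the low-low state
  sim2 <- simulate_endocrine(c(95, 95), p, equilibria = eqs)
  expect_equal(unname(attr(sim2, "final")), unname(lowlow),
               tolerance = 1e-4)
  expect_true(is.numeric(attr(sim1, "reached")))
  # trapping: trajectories started at the corner never leave the box
  sim3 <- simulate_endocrine(c(100, 100), p, horizon = 3000,
                             equilibria = eqs)
  expect_true(all(as.matrix(sim3[c("HPA", "HPG")]) <= 100 + 1e-6))
  expect_true(all(as.matrix(sim3[c("HPA", "HPG")]) >= -1e-8))
})

test_that("the basin map is exchange-symmetric with the low-low basin largest", {
  bm <- basin_map(n = 21, horizon = 5000)
  expect_equal(dim(bm$label), c(21, 21))
  expect_equal(bm$unresolved, 0)
  states <- do.call(rbind, lapply(bm$equilibria, function(e) e$state))
  sym_idx <- which(abs(states[, 1] - states[, 2]) < 1e-6)
  # pair up the asymmetric labels under exchange
  pair <- vapply(seq_len(nrow(states)), function(k) {
    mirror <- rev(states[k, ])
    which.min(apply(states, 1, function(r) sum((r - mirror)^2)))
  }, integer(1))
  swapped <- matrix(pair[bm$label], nrow(bm$label))
  expect_equal(swapped, t(bm$label))
  # the symmetric low-activity basin has the widest basin of attraction
  expect_equal(unname(which.max(bm$fractions)), sym_idx)
  # spot-check: relabelled points re-simulate to their labelled attractor
  set.seed(5)
  for (idx in sample(length(bm$label), 6)) {
    ij <- arrayInd(idx, dim(bm$label))
    sim <- simulate_endocrine(c(bm$x[ij[1]], bm$y[ij[2]]),
                              horizon = 5000, equilibria = bm$equilibria)
    lab <- bm$label[ij[1], ij[2]]
    expect_lt(sqrt(sum((attr(sim, "final") - states[lab, ])^2)), 0.5)
  }
})
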