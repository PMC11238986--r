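test_that("increasing Hill evaluation matches closed-form arithmetic", {
  sp <- hill_spec(m = 100, e = 20, h = 2.5)
  expect_identical(hill_increasing(0, sp), 0)
  expect_equal(hill_increasing(20, sp), 50)
  expect_equal(hill_increasing(40, sp), 100 / (1 + 0.5^2.5),
               tolerance = 1e-12)
  expect_equal(round(hill_increasing(40, sp), 2), 84.98)
  # offset shifts the whole curve
  spo <- hill_spec(m = 100, e = 20, h = 2.5, offset = 7)
  expect_equal(hill_increasing(0, spo), 7)
  expect_error(hill_increasing(-1, sp), "nonnegative")
})

test_that("decreasing Hill evaluation matches closed-form arithmetic", {
  sp <- hill_spec(m = 100, e = 28, h = 4.2, direction = "decreasing")
  expect_equal(hill_decreasing(0, sp), 100)
  expect_equal(hill_decreasing(28, sp), 50)
  expect_equal(hill_decreasing(56, sp), 100 / (1 + 2^4.2),
               tolerance = 1e-12)
  expect_equal(round(hill_decreasing(56, sp), 2), 5.16)
  expect_error(hill_decreasing(-0.1, sp), "nonnegative")
})

test_that("hill_spec rejects invalid parameters", {
  expect_error(hill_spec(m = -1, e = 20, h = 2), "'m'")
  expect_error(hill_spec(m = 1, e = 0, h = 2), "'e'")
  expect_error(hill_spec(m = 1, e = 20, h = 0), "'h'")
  expect_error(hill_spec(m = 1, e = 20, h = 2, offset = -1), "offset")
})

test_that("shifted self-limit spans (1, 5] with midpoint 3", {
  expect_equal(shifted_self_limit(0, 25.57, 6.6, 0.48), 5)
  # alpha * x = e_k is the midpoint of the band
  x_mid <- 25.57 / 0.48
  expect_equal(shifted_self_limit(x_mid, 25.57, 6.6, 0.48), 3)
  # far out the factor approaches 1
  x_far <- 10 * 25.57 / 0.48
  expect_equal(shifted_self_limit(x_far, 25.57, 6.6, 0.48), 1,
               tolerance = 1e-5)
  expect_gt(shifted_self_limit(x_far, 25.57, 6.6, 0.48), 1)
  expect_error(shifted_self_limit(1, 25.57, 6.6, 1.2), "alpha")
  expect_error(shifted_self_limit(1, 25.57, 6.6, 0), "alpha")
})

test_that("Hill responses are monotone on dense grids", {
  x <- seq(0, 500, length.out = 2000)
  for (h in c(0.5, 1, 2.5, 4.2, 6.5)) for (e in c(1.8, 20, 28)) {
    up <- hill_increasing(x, hill_spec(100, e, h))
    dn <- hill_decreasing(x, hill_spec(100, e, h,
                                       direction = "decreasing"))
    # nondecreasing / nonincreasing up to double rounding at saturation
    expect_true(all(diff(up) >= -1e-12),
                label = sprintf("up e=%g h=%g", e, h))
    expect_true(all(diff(dn) <= 1e-12),
                label = sprintf("dn e=%g h=%g", e, h))
  }
})

test_that("increasing and decreasing forms are complementary", {
  x <- seq(0, 200, length.out = 500)
  for (h in c(1, 2.5, 4.2)) {
    sp_up <- hill_spec(1, 20, h)
    sp_dn <- hill_spec(1, 20, h, direction = "decreasing")
    expect_equal(hill_increasing(x, sp_up) + hill_decreasing(x, sp_dn),
                 rep(1, length(x)), tolerance = 1e-12)
  }
})

test_that("median aggregation reproduces the packaged reference medians", {
  h_vals <- c(2, 2, 2, 2, 1.2, 1.15, 2.8)
  expect_equal(aggregate_medians(data.frame(h = h_vals))[["h"]], 2)
  thr <- c(600, 1500, 150, 300, 90, 900)
  expect_equal(aggregate_medians(data.frame(thr = thr))[["thr"]], 450)
  # single record is its own median
  expect_equal(aggregate_medians(data.frame(e = 18, h = 2)),
               c(e = 18, h = 2))
})

test_that("median aggregation is permutation invariant and handles gaps", {
  df <- data.frame(e = c(15, 45, 300, 18, 9, 3.9, 300),
                   thr = c(NA, 600, 1500, 150, 300, 90, 900))
  set.seed(42)
  for (i in 1:5) {
    perm <- df[sample(nrow(df)), ]
    expect_equal(aggregate_medians(perm), aggregate_medians(df))
  }
  expect_equal(aggregate_medians(df)[["thr"]], 450) # NA skipped per field
  expect_error(aggregate_medians(data.frame()), "aggregate|records")
  expect_error(aggregate_medians(list()), "nonempty")
})

test_that("aggregation accepts lists of records with uneven fields", {
  specs <- list(list(e = 15, h = 2), list(e = 45, h = 2),
                list(e = 18, h = 1.2, extra = 7))
  med <- aggregate_medians(specs)
  expect_equal(med[["e"]], 18)
  expect_equal(med[["h"]], 2)
  expect_equal(med[["extra"]], 7)
})
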