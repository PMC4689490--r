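test_that("solver reproduces the closed-form prevalence when r = f = 0", {
  hz <- hazard_schedule(age_bands(0, Inf), i = 0.02, r = 0, f = 0, m = 0.013)
  sol <- idm_solve(hz, age_max = 100)
  a <- sol$ages[-1]
  expect_lt(max(abs(sol$p[-1] - (1 - exp(-0.02 * a))) /
                  (1 - exp(-0.02 * a))), 1e-4)
  # background mortality cancels from the prevalence ratio
  hz2 <- hazard_schedule(age_bands(0, Inf), i = 0.02, r = 0, f = 0, m = 0.04)
  expect_equal(idm_solve(hz2, age_max = 100)$p, sol$p, tolerance = 1e-10)
})

test_that("solver reproduces the closed-form sojourn duration", {
  # constant exit hazard r+m+f = 0.06 -> D = 16.667 y; horizon long enough
  # that truncation is negligible
  hz <- hazard_schedule(age_bands(0, Inf), i = 2e-4, r = 0.04, f = 0.01,
                        m = 0.01)
  sol <- idm_solve(hz, age_max = 300)
  expect_equal(sol$duration[1], 1 / 0.06, tolerance = 1e-4)
})

test_that("no disease means zero prevalence, zero duration, SMR = (m+f)/m", {
  hz <- hazard_schedule(surveillance_bands(), i = 0, r = 0.1, f = 0.02,
                        m = 0.01)
  sol <- idm_solve(hz)
  expect_true(all(sol$p == 0))
  # duration reported as zero for an empty disease state
  s <- epiburden:::idm_band_summary(sol)
  expect_true(all(s$duration == 0))
  expect_equal(unique(sol$smr), (0.01 + 0.02) / 0.01)
})

test_that("invalid inputs are rejected", {
  b <- age_bands(0, Inf)
  expect_error(hazard_schedule(b, i = -1e-4, r = 0, f = 0, m = 0.01),
               "non-negative")
  hz <- hazard_schedule(b, i = 1e-4, r = 0, f = 0, m = 0.01)
  expect_error(idm_solve(hz, ages = c(0, 2, 1)), "strictly increasing")
  expect_error(idm_solve(hz, init_prev = 1.5), "init_prev")
})

test_that("state fractions stay valid on random hazard schedules", {
  set.seed(42)
  for (k in 1:20) {
    sol <- idm_solve(random_schedule(), init_prev = runif(1, 0, 0.05))
    expect_true(all(sol$W >= 0))
    expect_true(all(sol$C >= 0))
    expect_true(all(sol$p >= 0 & sol$p <= 1))
    expect_true(all(sol$duration >= 0))
  }
})

test_that("SMR is exactly 1 in every band when there is no excess hazard", {
  set.seed(7)
  for (k in 1:5) {
    hz <- random_schedule()
    hz$f <- 0
    expect_true(all(idm_solve(hz)$smr == 1))
  }
})

test_that("solver agrees with an independent adaptive ODE integrator", {
  hz <- truth_schedule()
  rhs <- function(a, y, parms) {
    b <- findInterval(a, c(hz$age_lo, 100), rightmost.closed = TRUE)
    b <- min(max(b, 1), nrow(hz))
    with(hz[b, ], list(c(-(i + m) * y[1] + r * y[2],
                         i * y[1] - (r + m + f) * y[2])))
  }
  ref <- deSolve::lsoda(c(W = 1, C = 0), times = seq(0, 100, 1), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  sol <- idm_solve(hz)
  at <- match(ref[, "time"], sol$ages)
  p_ref <- ref[, "C"] / (ref[, "W"] + ref[, "C"])
  expect_equal(sol$p[at], unname(p_ref), tolerance = 1e-6)
})

test_that("prevalence equals incidence x duration in a stationary population", {
  # age-constant hazards, mortality fast enough that the age horizon holds
  # essentially the whole stationary population
  hz <- hazard_schedule(age_bands(0, Inf), i = 2e-4, r = 0.04, f = 0.005,
                        m = 0.05)
  sol <- idm_solve(hz)
  h <- diff(sol$ages)[1]
  P <- sum(sol$C) / sum(sol$W + sol$C)     # person-time-weighted prevalence
  D <- 1 / (0.04 + 0.005 + 0.05)
  expect_equal(P, 2e-4 * D * (1 - P), tolerance = 0.02)
  expect_equal(P, 2e-4 * D, tolerance = 0.02)
})
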