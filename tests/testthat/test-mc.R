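test_that("zero standard errors give a degenerate interval at the point", {
  out <- mc_propagate(c(a = 5, b = 2), se = 0, iterations = 50, seed = 3)
  expect_equal(out$lo, out$point)
  expect_equal(out$hi, out$point)
})

test_that("propagation is deterministic under a fixed seed", {
  a <- mc_propagate(10, 1, iterations = 500, seed = 99)
  b <- mc_propagate(10, 1, iterations = 500, seed = 99)
  expect_identical(a, b)
})

test_that("normal pass-through matches the analytic 95% quantiles", {
  out <- mc_propagate(10, 1, iterations = 10000, seed = 20151223)
  expect_equal(out$lo, qnorm(0.025, 10, 1), tolerance = 0.01)
  expect_equal(out$hi, qnorm(0.975, 10, 1), tolerance = 0.01)
})

test_that("zero iterations are rejected", {
  expect_error(mc_propagate(1, 1, iterations = 0), "iterations")
  fit <- idm_fit(idm_observe(truth_schedule()))
  expect_error(propagate_uncertainty(fit, iterations = 0), "iterations")
})

test_that("fit-stage uncertainty collapses to the point when SEs are zero", {
  obs <- idm_observe(truth_schedule())
  for (q in c("prevalence", "incidence", "remission", "cause_mortality"))
    obs[[paste0(q, "_se")]] <- 0
  fit <- idm_fit(obs)
  ui <- propagate_uncertainty(fit, iterations = 5, seed = 1)
  expect_equal(ui$lo, ui$point, tolerance = 1e-6)
  expect_equal(ui$hi, ui$point, tolerance = 1e-6)
})

test_that("fit-stage uncertainty is deterministic and brackets the point", {
  coh <- generate_cohort(agincourt_cohort_spec(seed = 5))
  fit <- idm_fit(coh$strata)
  u1 <- propagate_uncertainty(fit, iterations = 25, seed = 42)
  u2 <- propagate_uncertainty(fit, iterations = 25, seed = 42)
  expect_identical(u1, u2)
  expect_true(all(u1$lo <= u1$hi))
})
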