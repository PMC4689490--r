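test_that("noise-free observations round-trip to the generating hazards", {
  truth <- truth_schedule()
  fit <- idm_fit(idm_observe(truth))
  co <- coef(fit)
  expect_lt(max(abs(co$i - truth$i) / truth$i), 0.01)
  expect_lt(max(abs(co$r - truth$r) / truth$r), 0.01)
  expect_lt(max(abs(co$f - truth$f) / truth$f), 0.01)
  expect_true(fit$converged)
  expect_lt(fit$discrepancy, 1e-8)
})

test_that("round trip also holds without remission observations", {
  truth <- truth_schedule()
  obs <- idm_observe(truth)
  obs$remission <- NULL      # r identified through prevalence consistency
  co <- coef(idm_fit(obs))
  expect_lt(max(abs(co$i - truth$i) / truth$i), 0.01)
  expect_lt(max(abs(co$r - truth$r) / pmax(truth$r, 1e-3)), 0.01)
})

test_that("a sex with no observed disease is flagged unidentified", {
  b <- surveillance_bands()
  obs <- data.frame(band = b$band, age_lo = b$age_lo, age_hi = b$age_hi,
                    m = 0.01, prevalence = 0, incidence = 0,
                    cause_mortality = 0)
  fit <- idm_fit(obs)
  expect_true("unidentified" %in% fit$flags)
  co <- coef(fit)
  expect_true(all(co$i == 0) && all(co$r == 0) && all(co$f == 0))
})

test_that("fewer than three observed quantities is underdetermined", {
  b <- surveillance_bands()
  obs <- data.frame(age_lo = b$age_lo, age_hi = b$age_hi, m = 0.01,
                    prevalence = 0.002, incidence = 2e-4)
  expect_error(idm_fit(obs), "underdetermined")
  expect_error(idm_fit(data.frame(age_lo = 0, age_hi = Inf, m = 0,
                                  prevalence = 0.1, incidence = 1e-4,
                                  remission = 0.1)),
               "positive")
})

test_that("fitting stratum counts yields a valid consistency table", {
  coh <- generate_cohort(agincourt_cohort_spec(seed = 11))
  fit <- idm_fit(coh$strata)
  s <- summary(fit)
  expect_setequal(unique(s$sex), c("male", "female"))
  expect_true(all(is.finite(s$prev_per1000)) && all(s$prev_per1000 >= 0))
  expect_true(all(s$duration_years >= 0))
  expect_true(all(s$smr >= 1 - 1e-12))
  res <- residuals(fit)
  expect_true(all(c("prevalence", "incidence", "cause_mortality") %in%
                    names(res)))
})

test_that("predict and coef expose the fitted schedules coherently", {
  truth <- truth_schedule()
  fit <- idm_fit(idm_observe(truth))
  p50 <- predict(fit, ages = 50, type = "prevalence")
  expect_true(p50 > 0 && p50 < 1)
  expect_equal(predict(fit, ages = 10, type = "incidence"),
               coef(fit)$i[2], tolerance = 1e-8)
  sol <- fit$solutions[[1]]
  expect_equal(predict(fit, ages = sol$ages[11], type = "prevalence"),
               sol$p[11])
})
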