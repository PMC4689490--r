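make_strata <- function() {
  data.frame(sex = rep(c("male", "female"), each = 2),
             age_lo = c(0, 50, 0, 50), age_hi = c(50, NA, 50, NA),
             population = c(2e4, 5e3, 2e4, 6e3),
             person_years = c(8e4, 2e4, 8e4, 2.4e4),
             deaths_all_cause = c(300, 600, 250, 550),
             cases_prevalent = c(60, 25, 55, 20),
             cases_incident = c(15, 6, 13, 5),
             deaths_cause = c(5, 4, 3, 3))
}

test_that("a constant statistic yields a degenerate interval", {
  b <- bootstrap_interval(make_strata(), function(d) 7.25,
                          iterations = 200, seed = 1)
  expect_equal(b$point, 7.25)
  expect_equal(b$lo, 7.25)
  expect_equal(b$hi, 7.25)
})

test_that("the bootstrap is deterministic under a fixed seed", {
  st <- function(d) sum(d$cases_prevalent) * 0.346
  b1 <- bootstrap_interval(make_strata(), st, iterations = 300, seed = 12)
  b2 <- bootstrap_interval(make_strata(), st, iterations = 300, seed = 12)
  expect_identical(b1[c("point", "lo", "hi", "replicates")],
                   b2[c("point", "lo", "hi", "replicates")])
})

test_that("case resampling of a normal sample matches the analytic SE", {
  set.seed(2026)
  cases <- data.frame(x = rnorm(1000))
  b <- bootstrap_interval(cases, function(d) mean(d$x),
                          iterations = 10000, seed = 7, unit = "cases")
  se <- sd(cases$x) / sqrt(1000)
  expect_equal(b$hi - b$lo, 2 * 1.96 * se, tolerance = 0.05)
  expect_equal((b$hi + b$lo) / 2, mean(cases$x), tolerance = 2 * se)
})

test_that("interval bounds bracket the point for monotone count statistics", {
  st <- function(d) sum(d$cases_prevalent) + sum(d$deaths_cause)
  b <- bootstrap_interval(make_strata(), st, iterations = 500, seed = 3)
  expect_lte(b$lo, b$point)
  expect_gte(b$hi, b$point)
})

test_that("failing replicates are dropped, counted and capped at 5%", {
  flaky <- function(d) {
    if (sum(d$cases_incident) %% 2 == 0) stop("boom")
    sum(d$cases_incident)
  }
  expect_error(bootstrap_interval(make_strata(), flaky, iterations = 200,
                                  seed = 5), "failed on")
  expect_error(bootstrap_interval(make_strata(), function(d) 1,
                                  iterations = 50, seed = 1), ">= 100")
})
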