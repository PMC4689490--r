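test_that("prevalence-based YLD matches the surveillance aggregates", {
  expect_equal(round(yld_prevalence(39313, 2.6 / 1000, 0.346), 1), 35.4)
  expect_equal(round(yld_prevalence(42443, 2.4 / 1000, 0.346), 1), 35.2)
  expect_equal(yld_prevalence(1e6, 0.01, 0), 0)
  expect_error(yld_prevalence(-1, 0.1, 0.3), "non-negative")
  expect_error(yld_prevalence(10, 1.2, 0.3), "\\[0, 1\\]")
})

test_that("incidence-based YLD matches the surveillance aggregates", {
  expect_equal(round(yld_incidence(39313, 19.4 / 1e5, 21.5, 0.346), 1), 56.7)
  expect_equal(round(yld_incidence(42443, 17.2 / 1e5, 19.7, 0.346), 1), 49.8)
  expect_equal(yld_incidence(1e5, 1e-4, 0, 0.5), 0)
  expect_error(yld_incidence(10, -1e-4, 5, 0.3), "non-negative")
})

test_that("both YLD formulas are linear in weight and population", {
  set.seed(1)
  for (k in 1:10) {
    pop <- runif(1, 1e3, 1e5); pr <- runif(1, 0, 0.01)
    inc <- runif(1, 0, 1e-3); dur <- runif(1, 1, 40)
    dw <- runif(1, 0.05, 0.9); s <- runif(1, 0.1, 3)
    expect_equal(yld_prevalence(pop, pr, dw) * s,
                 yld_prevalence(pop * s, pr, dw))
    expect_equal(yld_incidence(pop, inc, dur, dw) / dw * 0.5,
                 yld_incidence(pop, inc, dur, 0.5))
  }
})

test_that("the two approaches agree exactly in the stationary limit", {
  pop <- 83121; inc <- 2e-4; dur <- 18; dw <- 0.346
  prev <- inc * dur                       # stationarity identity
  expect_equal(yld_prevalence(pop, prev, dw),
               yld_incidence(pop, inc, dur, dw), tolerance = 1e-12)
})

test_that("YLL sums deaths weighted by remaining expectancy", {
  lt5 <- toy_life_table(c(0, 10, 20, 50, 100), c(80, 72, 64, 36, 1))
  expect_equal(yll(data.frame(age = numeric(0), count = numeric(0)), lt5), 0)
  expect_equal(yll(data.frame(age = c(10, 50), count = c(2, 1)), lt5),
               2 * 72 + 36)
  expect_equal(yll(data.frame(age = 0, count = 1), load_life_table()), 86.02)
  # band deaths use the configured representative age
  bd <- data.frame(age_lo = 0, age_hi = 20, count = 1)
  expect_equal(yll(bd, lt5, convention = "midpoint"), 72)
  expect_equal(yll(bd, lt5, convention = "lower"), 80)
})

test_that("DALY assembly is additive with consistent totals and rates", {
  cells <- expand.grid(sex = c("male", "female"),
                       band = c("young", "old"), stringsAsFactors = FALSE)
  yll_t <- cbind(cells, value = c(10, 5, 40, 20))
  yld_t <- cbind(cells, value = c(4, 6, 10, 12))
  pop <- cbind(cells, population = c(1e4, 1.1e4, 6e3, 8e3))
  bt <- assemble_daly(yll_t, yld_t, pop)
  expect_equal(bt$daly, bt$yll + bt$yld)
  both <- bt[bt$sex == "both" & bt$band == "all", ]
  expect_equal(both$daly, sum(c(10, 5, 40, 20)) + sum(c(4, 6, 10, 12)))
  # per-1,000 rates reproduce absolute values
  expect_equal(bt$daly_per_1000 * bt$population / 1000, bt$daly)
  # per-sex totals equal sum of band cells
  m <- bt[bt$sex == "male", ]
  expect_equal(m$yll[m$band == "all"], sum(m$yll[m$band != "all"]))
  expect_error(assemble_daly(yll_t[-1, ], yld_t, pop), "do not match")
})

test_that("zero burden assembles to zero DALYs and rates", {
  cells <- data.frame(sex = "all", band = "all-ages")
  bt <- assemble_daly(cbind(cells, value = 0), cbind(cells, value = 0),
                      cbind(cells, population = 1000))
  expect_true(all(bt$daly == 0) && all(bt$daly_per_1000 == 0))
})

test_that("method comparison reports the printed percent differences", {
  m <- compare_methods(35.4, 56.7)
  expect_equal(m$pct_diff_yld_int, 38)
  f <- compare_methods(35.2, 49.8)
  expect_equal(f$pct_diff_yld_int, 29)
  expect_equal(compare_methods(12, 12)$pct_diff_yld, 0)
  expect_error(compare_methods(1, 0), "positive")
})
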