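test_that("constant band values smooth to a constant under every method", {
  b <- surveillance_bands()
  v <- rep(3.7, 6)
  for (m in c("piecewise-linear", "moving-average", "cubic-spline")) {
    f <- smooth_schedule(v, b, method = m)
    expect_equal(f(seq(0, 100, 5)), rep(3.7, 21), tolerance = 1e-12)
  }
})

test_that("piecewise-linear interpolates between band midpoints", {
  b <- age_bands(c(0, 10), c(10, 20))   # midpoints 5 and 15
  f <- smooth_schedule(c(3, 9), b, method = "piecewise-linear")
  expect_equal(f(10), 6)                # midpoint of midpoints
  expect_equal(f(c(5, 15)), c(3, 9))    # exact at midpoints
})

test_that("moving average uses a window of 3 over bands", {
  b <- age_bands(c(0, 10, 20), c(10, 20, 30))
  f <- smooth_schedule(c(1, 4, 1), b, method = "moving-average")
  expect_equal(f(15), 2)                        # mean(1, 4, 1)
  expect_equal(f(5), mean(c(1, 4)))             # edge window shrinks
})

test_that("cubic spline passes through band midpoints", {
  b <- surveillance_bands()
  v <- c(2, 5, 3, 8, 1, 4)
  f <- smooth_schedule(v, b, method = "cubic-spline")
  expect_equal(f(band_midpoints <- epiburden:::band_midpoints(b)), v,
               tolerance = 1e-10)
})

test_that("unknown methods and degenerate inputs are rejected", {
  b <- age_bands(c(0, 10), c(10, 20))
  expect_error(smooth_schedule(c(1, 2), b, method = "loess"))
  expect_error(smooth_schedule(1, age_bands(0, 10)), "at least 2")
})
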