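# shared fixtures for the test suite, built in code

# a plausible six-band truth schedule at surveillance-site magnitudes
truth_schedule <- function() {
  hazard_schedule(surveillance_bands(),
                  i = c(30, 24, 15, 15, 17, 20) / 1e5,
                  r = c(0.16, 0.033, 0.045, 0.093, 0.001, 0.02),
                  f = c(0.02, 0.025, 0.009, 0.004, 0.019, 0.11),
                  m = c(3.9, 1.3, 0.9, 4.4, 18.7, 43.6) / 1000)
}

# small in-memory life table for interpolation checks
toy_life_table <- function(age, ex) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age = age, ex = ex), path, row.names = FALSE)
  load_life_table(path)
}

# random non-degenerate hazard schedule on the surveillance bands
random_schedule <- function() {
  b <- surveillance_bands()
  hazard_schedule(b,
                  i = runif(6, 0, 0.005),
                  r = runif(6, 0, 0.5),
                  f = runif(6, 0, 0.05),
                  m = runif(6, 1e-4, 0.05))
}
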