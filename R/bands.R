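#' Age bands
#'
#' Construct and validate a set of age bands. Bands must partition the age
#' axis without overlap: each band's lower bound equals the previous band's
#' upper bound, starting at 0. The last band may be open-ended
#' (`upper = Inf`), in which case downstream integration truncates it at the
#' life table's terminal age (100 years by default).
#'
#' @param lower integer lower bounds in years, starting at 0.
#' @param upper upper bounds in years; `Inf` (or `NA`) for an open-ended
#'   terminal band.
#' @return a data frame of class `age_bands` with columns `age_lo`, `age_hi`
#'   and a printable `band` label.
#' @examples
#' surveillance_bands()
#' @export
age_bands <- function(lower, upper) {
  if (length(lower) != length(upper) || length(lower) < 1)
    stopf("lower and upper must be equal-length, non-empty")
  upper[is.na(upper)] <- Inf
  if (any(lower < 0)) stopf("age band bounds must be >= 0")
  if (lower[1] != 0) stopf("age bands must start at 0")
  if (any(lower >= upper)) stopf("each band needs lower < upper")
  if (length(lower) > 1 && any(lower[-1] != upper[-length(upper)]))
    stopf("age bands must partition the age axis without gaps or overlap")
  if (any(is.infinite(upper[-length(upper)])))
    stopf("only the last band may be open-ended")
  lab <- ifelse(is.finite(upper),
                paste0(lower, "-", upper - 1),
                paste0(lower, "+"))
  structure(data.frame(band = lab, age_lo = lower, age_hi = upper,
                       stringsAsFactors = FALSE),
            class = c("age_bands", "data.frame"))
}

#' @describeIn age_bands the six bands used by African epilepsy surveillance
#'   studies: 0--5, 6--12, 13--18, 19--28, 29--49 and 50+ years.
#' @export
surveillance_bands <- function() {
  age_bands(lower = c(0, 6, 13, 19, 29, 50),
            upper = c(6, 13, 19, 29, 50, Inf))
}

# midpoint of each band, with the open-ended band truncated at age_max
band_midpoints <- function(bands, age_max = 100) {
  hi <- pmin(bands$age_hi, age_max)
  (bands$age_lo + hi) / 2
}

# representative age of a band under a death-age convention
band_age <- function(age_lo, age_hi, convention = c("midpoint", "lower", "upper"),
                     age_max = 100) {
  convention <- match.arg(convention)
  age_hi <- pmin(ifelse(is.na(age_hi), Inf, age_hi), age_max)
  switch(convention,
         midpoint = (age_lo + age_hi) / 2,
         lower    = age_lo,
         upper    = age_hi)
}

# map ages to band indices; ages at a boundary belong to the upper band
band_index <- function(ages, bands, age_max = 100) {
  brk <- c(bands$age_lo, min(bands$age_hi[nrow(bands)], age_max))
  idx <- findInterval(ages, brk, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(bands)] <- nrow(bands)
  idx
}
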