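#' Smooth band-level quantities onto a continuous age axis
#'
#' Turns per-band values (anchored at band midpoints) into a function of
#' continuous age, the way consistency-engine outputs are presented on a
#' smooth axis. Three methods are provided: piecewise-linear interpolation
#' between band midpoints, a moving average of window 3 over bands (then
#' linearly interpolated), and a natural cubic spline through the midpoints.
#' Piecewise-linear and spline reproduce the band values exactly at the
#' midpoints; the moving average by construction does not.
#'
#' @param values numeric per-band values (length >= 2).
#' @param bands an [age_bands()] object matching `values`, or a numeric
#'   vector of midpoint ages.
#' @param method one of `"piecewise-linear"`, `"moving-average"`,
#'   `"cubic-spline"`.
#' @param age_max truncation age for an open-ended band midpoint.
#' @return a function of age returning the smoothed value; constant
#'   extrapolation beyond the first/last midpoint.
#' @examples
#' f <- smooth_schedule(c(1, 4, 1), age_bands(c(0, 10, 20), c(10, 20, 30)),
#'                      method = "moving-average")
#' f(15)  # mean of the three band values at the central midpoint
#' @export
smooth_schedule <- function(values,
                            bands,
                            method = c("piecewise-linear", "moving-average",
                                       "cubic-spline"),
                            age_max = 100) {
  method <- match.arg(method)
  if (is.numeric(bands)) mids <- bands else mids <- band_midpoints(bands, age_max)
  if (length(values) != length(mids))
    stopf("values and bands must have equal length")
  if (length(values) < 2) stopf("smoothing needs at least 2 bands")
  if (any(!is.finite(values))) stopf("values must be finite")

  if (method == "moving-average") {
    n <- length(values)
    values <- vapply(seq_len(n), function(k) {
      w <- max(1, k - 1):min(n, k + 1)
      mean(values[w])
    }, numeric(1))
  }
  if (method == "cubic-spline") {
    sf <- splinefun(mids, values, method = "natural")
    lo <- min(mids); hi <- max(mids)
    return(function(age) sf(pmin(pmax(age, lo), hi)))
  }
  approxfun(mids, values, rule = 2)
}
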