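#' Bootstrap 95% uncertainty interval for a burden statistic
#'
#' Percentile bootstrap intervals for any statistic of a stratum table,
#' built on the `boot` package's parametric simulation. Two resampling
#' units are supported:
#' \describe{
#'   \item{`"counts"`}{Poisson bootstrap of the stratum event counts
#'     (prevalent cases, incident cases, deaths): each replicate redraws
#'     every count column as `Poisson(observed)`. The default, matching
#'     rare-event counts over person-time denominators.}
#'   \item{`"parametric"`}{zero-truncated normal redraw of rate columns
#'     using their `<name>_se` companions.}
#'   \item{`"cases"`}{ordinary nonparametric bootstrap: rows of `data`
#'     (one row per case or observation unit) resampled with
#'     replacement.}
#' }
#'
#' A replicate on which the statistic fails is dropped and counted; more
#' than 5% failures is an error.
#'
#' @param data a data frame of strata (counts layout) or rates.
#' @param statistic a function of `data` returning a numeric scalar.
#' @param iterations bootstrap replicates, default 1000 (at least 100 for
#'   reporting).
#' @param seed integer seed; output is deterministic given the seed.
#' @param unit `"counts"` or `"parametric"` (see above).
#' @return an object of class `boot_interval`: list with `point` (the
#'   statistic on the original data), `lo`, `hi` (2.5th/97.5th percentile
#'   of the replicates), `failed` (dropped replicates) and `replicates`.
#' @examples
#' strata <- data.frame(sex = "all", age_lo = 0, age_hi = NA,
#'                      population = 10000, person_years = 40000,
#'                      deaths_all_cause = 400, cases_prevalent = 30,
#'                      cases_incident = 8, deaths_cause = 3)
#' bootstrap_interval(strata, function(d) sum(d$cases_prevalent) * 0.346,
#'                    iterations = 200, seed = 1)
#' @export
bootstrap_interval <- function(data, statistic, iterations = 1000,
                               seed = 20151223,
                               unit = c("counts", "parametric", "cases")) {
  unit <- match.arg(unit)
  if (iterations < 100)
    stopf("iterations must be >= 100 for a reportable interval")
  if (!is.function(statistic)) stopf("statistic must be a function")

  count_cols <- intersect(
    c("deaths_all_cause", "cases_prevalent", "cases_incident",
      "deaths_cause", "remissions"), names(data))
  rate_cols <- intersect(obs_quantities, names(data))
  rate_cols <- rate_cols[paste0(rate_cols, "_se") %in% names(data)]
  if (unit == "counts" && length(count_cols) == 0)
    stopf("no resampleable count columns in data")
  if (unit == "parametric" && length(rate_cols) == 0)
    stopf("no rate columns with _se companions in data")

  ran.gen <- function(d, mle) {
    if (unit == "counts") {
      for (cc in count_cols) d[[cc]] <- rpois(nrow(d), d[[cc]])
    } else if (unit == "parametric") {
      for (rc in rate_cols) {
        se <- d[[paste0(rc, "_se")]]
        d[[rc]] <- mapply(function(mn, s) rtnorm0(1, mn, s), d[[rc]], se)
      }
    } else {
      d <- d[sample.int(nrow(d), nrow(d), replace = TRUE), , drop = FALSE]
    }
    d
  }
  safe_stat <- function(d) {
    tryCatch(as.numeric(statistic(d))[1], error = function(e) NA_real_)
  }

  point <- as.numeric(statistic(data))[1]
  if (!is.finite(point)) stopf("statistic failed on the original data")

  set.seed(seed)
  bt <- boot::boot(data, statistic = function(d) safe_stat(d),
                   R = iterations, sim = "parametric", ran.gen = ran.gen)
  reps <- as.numeric(bt$t)
  failed <- sum(!is.finite(reps))
  if (failed > 0.05 * iterations)
    stopf("statistic failed on %d of %d bootstrap replicates", failed,
          iterations)
  reps <- reps[is.finite(reps)]
  qs <- quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(list(point = point, lo = qs[1], hi = qs[2], failed = failed,
                 iterations = iterations, seed = seed, unit = unit,
                 replicates = reps),
            class = "boot_interval")
}

#' @export
print.boot_interval <- function(x, ...) {
  cat(sprintf("Bootstrap 95%% UI (%s unit, %d iterations): %.4g (%.4g-%.4g)\n",
              x$unit, x$iterations, x$point, x$lo, x$hi))
  if (x$failed > 0) cat(sprintf("  %d replicate(s) dropped\n", x$failed))
  invisible(x)
}
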