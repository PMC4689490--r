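#' GBD 2010 disability weights for epilepsy health states
#'
#' The disability-weight set used for the one-way sensitivity analysis:
#' the regional mean weight for sub-Saharan Africa used as the reference,
#' and the four GBD 2010 epilepsy health states spanning the severity
#' range from treated and seizure-free to severe epilepsy.
#'
#' @return a named numeric vector of weights in (0, 1).
#' @export
gbd2010_dw <- function() {
  c(reference = 0.346,
    treated_seizure_free = 0.072,
    treated_recent_seizures = 0.319,
    untreated = 0.420,
    severe = 0.657)
}

#' One-way disability-weight sensitivity scan
#'
#' The disability weight enters the YLD formulas multiplicatively, so a
#' one-way scan rescales the reference YLD exactly:
#' `YLD(dw) = base_yld x dw / reference_dw`. Uncertainty bounds, when
#' supplied, are rescaled by the same factor (an approximation to
#' re-bootstrapping that is exact to the linearity of the estimator).
#'
#' @param base_yld YLD in years computed at `reference_dw`.
#' @param reference_dw the reference disability weight (> 0).
#' @param dw_set named numeric vector of weights to scan;
#'   defaults to [gbd2010_dw()].
#' @param base_lo,base_hi optional uncertainty bounds on `base_yld`.
#' @param yll optional YLL in years; when given, scanned DALY totals and
#'   percent changes of DALYs versus the reference are included.
#' @return a data frame of class `dw_sensitivity`: per weight, `yld`
#'   (with `lo`/`hi` if bounds were given), `pct_change_yld`, and when
#'   `yll` is supplied `daly` and `pct_change_daly` (raw and integer).
#' @examples
#' dw_scan(84.8, 0.346)[, c("state", "dw", "yld")]
#' @export
dw_scan <- function(base_yld, reference_dw, dw_set = gbd2010_dw(),
                    base_lo = NULL, base_hi = NULL, yll = NULL) {
  check_nonneg(base_yld, "base YLD")
  if (length(reference_dw) != 1 || reference_dw <= 0)
    stopf("reference_dw must be a single positive weight")
  check_fraction(dw_set, "disability weights")
  if (is.null(names(dw_set)) || anyDuplicated(names(dw_set)))
    stopf("dw_set must have unique names")

  fac <- dw_set / reference_dw
  out <- data.frame(state = names(dw_set), dw = unname(dw_set),
                    yld = base_yld * fac,
                    pct_change_yld = (fac - 1) * 100,
                    stringsAsFactors = FALSE)
  if (!is.null(base_lo)) out$lo <- base_lo * fac
  if (!is.null(base_hi)) out$hi <- base_hi * fac
  if (!is.null(yll)) {
    check_nonneg(yll, "YLL")
    ref_daly <- yll + base_yld
    out$daly <- yll + out$yld
    out$pct_change_daly <- (out$daly - ref_daly) / ref_daly * 100
    out$pct_change_daly_int <- pct_int(out$pct_change_daly)
  }
  structure(out, class = c("dw_sensitivity", "data.frame"),
            reference_dw = reference_dw, base_yld = base_yld)
}

#' Effect of disability-weight choice on total DALYs
#'
#' Percent change of total DALYs for each scanned disability weight,
#' relative to the reference weight: `(DALY(dw) - DALY(ref)) / DALY(ref)`.
#' YLL is unaffected by the weight, so the change is driven entirely by
#' the rescaled YLD.
#'
#' @param yll YLL in years common to all weights.
#' @param sensitivity a [dw_scan()] result.
#' @return named numeric vector of integer-rounded percent changes, with
#'   the raw values in attribute `"raw"`.
#' @examples
#' sc <- dw_scan(84.8, 0.346)
#' dw_effect_on_daly(247.4, sc)[["treated_seizure_free"]]  # -20
#' @export
dw_effect_on_daly <- function(yll, sensitivity) {
  check_nonneg(yll, "YLL")
  if (!inherits(sensitivity, "dw_sensitivity"))
    stopf("sensitivity must come from dw_scan()")
  ref_daly <- yll + attr(sensitivity, "base_yld")
  if (ref_daly <= 0) stopf("reference DALY must be positive")
  raw <- (yll + sensitivity$yld - ref_daly) / ref_daly * 100
  out <- setNames(pct_int(raw), sensitivity$state)
  attr(out, "raw") <- setNames(raw, sensitivity$state)
  out
}

#' @export
print.dw_sensitivity <- function(x, ...) {
  cat(sprintf("Disability-weight sensitivity (reference DW %.3f, YLD %.1f)\n\n",
              attr(x, "reference_dw"), attr(x, "base_yld")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & names(y) != "dw"
  y[num] <- lapply(y[num], round1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
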