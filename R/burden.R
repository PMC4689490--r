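#' Years lived with disability, prevalence-based
#'
#' The prevalence-based approach to morbidity: prevalent cases in the
#' reference year times the disability weight,
#' `YLD = population x prevalence x DW`, in years per annum.
#'
#' @param population persons in the stratum.
#' @param prevalence prevalence as a fraction in `[0, 1]`.
#' @param dw disability weight in `[0, 1]` (0 = full health,
#'   1 = equivalent to death).
#' @return YLD in years (vectorised over strata).
#' @examples
#' yld_prevalence(39313, 2.6 / 1000, 0.346)  # 35.4 YLD
#' @export
yld_prevalence <- function(population, prevalence, dw) {
  check_nonneg(population, "population")
  check_fraction(prevalence, "prevalence")
  check_fraction(dw, "disability weight")
  population * prevalence * dw
}

#' Years lived with disability, incidence-based
#'
#' The incidence-based approach used by earlier burden studies: incident
#' cases times the expected duration of disease times the disability
#' weight, `YLD = population x incidence x duration x DW`.
#'
#' @inheritParams yld_prevalence
#' @param incidence incidence per person-year.
#' @param duration expected duration of disease in years (to remission or
#'   death).
#' @return YLD in years (vectorised over strata).
#' @examples
#' yld_incidence(39313, 19.4 / 1e5, 21.5, 0.346)  # 56.7 YLD
#' @export
yld_incidence <- function(population, incidence, duration, dw) {
  check_nonneg(population, "population")
  check_nonneg(incidence, "incidence")
  check_nonneg(duration, "duration")
  check_fraction(dw, "disability weight")
  population * incidence * duration * dw
}

#' Years of life lost
#'
#' Deaths directly attributable to the condition, each weighted by the
#' standard remaining life expectancy at the age of death. When deaths are
#' reported per age band rather than at exact ages, the band is mapped to a
#' representative age under `convention` (midpoint by default; the
#' open-ended band uses the life table's terminal age as its upper bound).
#'
#' @param deaths a data frame with a `count` column and either an `age`
#'   column (exact ages) or `age_lo`/`age_hi` columns (bands).
#' @param table a [load_life_table()] object.
#' @param convention band-to-age mapping: `"midpoint"`, `"lower"` or
#'   `"upper"`.
#' @return total YLL in years.
#' @examples
#' lt <- load_life_table()
#' yll(data.frame(age = 0, count = 1), lt)  # 86.02
#' @export
yll <- function(deaths, table, convention = "midpoint") {
  if (!is.data.frame(deaths) || is.null(deaths$count))
    stopf("deaths must be a data frame with a count column")
  check_nonneg(deaths$count, "death counts")
  if (nrow(deaths) == 0 || sum(deaths$count) == 0) return(0)
  ages <- if (!is.null(deaths$age)) deaths$age
          else band_age(deaths$age_lo, deaths$age_hi, convention,
                        age_max = max(table$age))
  sum(deaths$count * expectancy_at(table, ages))
}

#' Assemble a DALY burden table
#'
#' Combines stratum-level YLL and YLD into DALYs (`DALY = YLL + YLD`,
#' exact in every cell), appends all-band and both-sex totals, and derives
#' per-1,000 rates from the stratum populations. All arithmetic is done in
#' full precision; rounding belongs to the presentation layer only.
#'
#' @param yll_table,yld_table data frames with columns `sex`, `band` and
#'   `value` (years); strata must match exactly.
#' @param population data frame with columns `sex`, `band`, `population`.
#' @return a data frame of class `burden_table` with columns `sex`, `band`,
#'   `population`, `yll`, `yld`, `daly` and `*_per_1000` rates. Totals
#'   appear as band `"all"` and sex `"both"` rows.
#' @export
assemble_daly <- function(yll_table, yld_table, population) {
  for (d in list(yll_table, yld_table, population)) {
    if (!all(c("sex", "band") %in% names(d)))
      stopf("tables need sex and band columns")
  }
  key <- function(d) paste(d$sex, d$band)
  if (!setequal(key(yll_table), key(yld_table)) ||
      anyDuplicated(key(yll_table)))
    stopf("YLL and YLD strata do not match")
  if (!setequal(key(yll_table), key(population)))
    stopf("population strata do not match the burden strata")
  check_nonneg(yll_table$value, "YLL")
  check_nonneg(yld_table$value, "YLD")

  cells <- data.frame(sex = yll_table$sex, band = yll_table$band,
                      stringsAsFactors = FALSE)
  cells$yll <- yll_table$value
  cells$yld <- yld_table$value[match(key(cells), key(yld_table))]
  cells$population <- population$population[match(key(cells), key(population))]
  cells$daly <- cells$yll + cells$yld

  sexes <- unique(cells$sex)
  tot_sex <- do.call(rbind, lapply(sexes, function(sx) {
    k <- cells$sex == sx
    data.frame(sex = sx, band = "all",
               yll = sum(cells$yll[k]), yld = sum(cells$yld[k]),
               population = sum(cells$population[k]),
               daly = sum(cells$daly[k]))
  }))
  out <- rbind(cells, tot_sex)
  if (length(sexes) > 1) {
    both <- data.frame(sex = "both", band = "all",
                       yll = sum(cells$yll), yld = sum(cells$yld),
                       population = sum(cells$population),
                       daly = sum(cells$daly))
    out <- rbind(out, both)
  }
  for (v in c("yll", "yld", "daly"))
    out[[paste0(v, "_per_1000")]] <-
      ifelse(out$population > 0, out[[v]] / out$population * 1000, 0)
  structure(out, class = c("burden_table", "data.frame"))
}

#' @export
print.burden_table <- function(x, ...) {
  cat("DALY burden table (years per annum; rates per 1,000 persons)\n\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & names(y) != "population"
  y[num] <- lapply(y[num], round1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Compare prevalence- and incidence-based burden estimates
#'
#' Percent shortfall of the prevalence-based estimate relative to the
#' incidence-based one, for YLD alone and for total DALYs (YLL is common
#' to both methods). Values are reported both raw and integer-rounded as
#' burden comparisons print them.
#'
#' @param yld_prev,yld_inc YLD in years from the two approaches;
#'   `yld_inc` must be positive.
#' @param yll YLL in years entering both DALY totals (default 0 compares
#'   YLD only).
#' @return a list with `pct_diff_yld`, `pct_diff_daly` and integer-rounded
#'   `pct_diff_yld_int`, `pct_diff_daly_int`.
#' @examples
#' compare_methods(35.4, 56.7)$pct_diff_yld_int  # 38
#' @export
compare_methods <- function(yld_prev, yld_inc, yll = 0) {
  check_nonneg(yld_prev, "yld_prev")
  check_nonneg(yll, "yll")
  if (any(yld_inc <= 0)) stopf("incidence-based YLD must be positive")
  pct_yld <- (yld_inc - yld_prev) / yld_inc * 100
  pct_daly <- ((yll + yld_inc) - (yll + yld_prev)) / (yll + yld_inc) * 100
  list(pct_diff_yld = pct_yld, pct_diff_daly = pct_daly,
       pct_diff_yld_int = pct_int(pct_yld),
       pct_diff_daly_int = pct_int(pct_daly))
}
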