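#' Load a standard life table
#'
#' A standard (aspirational) life table maps age at death to remaining life
#' expectancy and is the basis of the years-of-life-lost calculation. The
#' packaged `"gbd2010_standard"` table is the GBD 2010 standard reference
#' life table (synthetic highest-attainable survival; 86.02 years of life
#' expectancy at birth, identical for males and females, as published with
#' that study). Any table can be supplied as a CSV with columns `age`, `ex`.
#'
#' No age weighting and no time discounting are applied anywhere in this
#' package; a death at age a accrues exactly `ex(a)` years.
#'
#' @param source either the name of a built-in table
#'   (`"gbd2010_standard"`) or a path to a CSV file.
#' @return a data frame of class `life_table` with columns `age`, `ex` and
#'   a `name` attribute.
#' @examples
#' lt <- load_life_table()
#' expectancy_at(lt, 0)  # 86.02
#' @export
load_life_table <- function(source = "gbd2010_standard") {
  path <- if (file.exists(source)) source
          else system.file("extdata", paste0(source, "_lifetable.csv"),
                           package = "epiburden")
  if (!nzchar(path) || !file.exists(path))
    stopf("life table '%s' not found (not a built-in name or file)", source)
  tab <- read.csv(path)
  if (!all(c("age", "ex") %in% names(tab)))
    stopf("life table needs columns age, ex")
  if (anyNA(tab$age) || anyNA(tab$ex)) stopf("life table has missing values")
  if (any(diff(tab$age) <= 0))
    stopf("life table ages must be strictly increasing (no duplicates)")
  if (tab$age[1] != 0)
    stopf("life table must include age 0 (life expectancy at birth)")
  if (any(tab$ex <= 0)) stopf("life table ex values must be positive")
  structure(tab, class = c("life_table", "data.frame"), name = source)
}

#' Remaining life expectancy at an age
#'
#' Linear interpolation of the life table between tabulated ages; exact at
#' tabulated ages. Ages beyond the last table row are clamped to the
#' terminal expectancy with a warning (a death past the table end still
#' accrues the terminal expectancy).
#'
#' @param table a [load_life_table()] object.
#' @param age age(s) at death in years, `>= 0`.
#' @return remaining life expectancy in years.
#' @export
expectancy_at <- function(table, age) {
  if (!inherits(table, "life_table")) stopf("table must be a life_table")
  check_nonneg(age, "age")
  amax <- max(table$age)
  if (any(age > amax)) {
    warning(sprintf("age(s) beyond the life table's last row (%g); clamped",
                    amax), call. = FALSE)
    age <- pmin(age, amax)
  }
  approx(table$age, table$ex, xout = age)$y
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Standard life table '%s': %d rows, e(0) = %.2f years\n",
              attr(x, "name"), nrow(x), x$ex[1]))
  invisible(x)
}
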