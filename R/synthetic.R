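#' Specify a synthetic surveillance cohort
#'
#' Describes an HDSS-like stratified cohort with known disease-process
#' parameters: per sex and age band, a population size and the four
#' illness-death hazards, observed for a fixed follow-up period. The
#' defaults produced by [agincourt_cohort_spec()] mirror the scale and
#' rate structure of a rural South African surveillance site (two sexes,
#' six bands, ~80,000 residents, four years of follow-up).
#'
#' @param hazards a [hazard_schedule()] with a `sex` column covering every
#'   stratum.
#' @param population data frame with `sex`, `age_lo`, `age_hi`,
#'   `population` matching the hazard strata.
#' @param years follow-up years (default 4).
#' @param noise observation noise model: `"poisson"` (counts drawn
#'   Poisson around their expectations; the default), `"multiplicative"`
#'   (expected counts scaled by independent truncated-normal factors with
#'   sd `noise_sd`), or `"none"`.
#' @param noise_sd standard deviation of the multiplicative factor
#'   (default 0.05).
#' @param loss_to_followup fraction of person-years removed uniformly
#'   (out-migration thinning); default 0 (off).
#' @param seed integer seed stored with the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(hazards, population, years = 4,
                        noise = c("poisson", "multiplicative", "none"),
                        noise_sd = 0.05, loss_to_followup = 0,
                        seed = 20151223) {
  noise <- match.arg(noise)
  if (is.null(hazards$sex)) stopf("hazards need a sex column")
  if (!all(c("sex", "population") %in% names(population)))
    stopf("population needs sex and population columns")
  check_nonneg(population$population, "population")
  check_fraction(loss_to_followup, "loss_to_followup")
  if (years <= 0) stopf("years must be positive")
  structure(list(hazards = hazards, population = population, years = years,
                 noise = noise, noise_sd = noise_sd,
                 loss_to_followup = loss_to_followup, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic stratified cohort
#'
#' Simulates the illness-death process of a [cohort_spec()]: stratum-level
#' expected counts come from the forward solution ([idm_solve()]) —
#' baseline prevalent cases from the band-midpoint prevalence, incident
#' cases, cause-specific and background deaths from the band hazards over
#' the follow-up person-time — and realised counts are drawn under the
#' spec's noise model. The generating truth is returned alongside the
#' data so parameter recovery can be scored.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `idm_cohort`: list with `strata` (a stratum
#'   table in the counts layout accepted by [idm_fit()]), `truth` (the
#'   generating hazards, band summaries and expected counts) and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  set.seed(spec$seed)
  hz <- spec$hazards
  sexes <- unique(hz$sex)
  draw <- switch(spec$noise,
    poisson = function(mu) rpois(length(mu), mu),
    multiplicative = function(mu)
      mu * vapply(mu, function(x) rtnorm0(1, 1, spec$noise_sd), numeric(1)),
    none = identity)

  strata <- list()
  truth_band <- list()
  truth_exp <- list()
  for (sx in sexes) {
    h <- hz[hz$sex == sx, , drop = FALSE]
    pop <- spec$population
    pop <- pop[pop$sex == sx, , drop = FALSE]
    if (nrow(pop) != nrow(h)) stopf("population strata do not match hazards")
    sol <- idm_solve(h)
    s <- idm_band_summary(sol)
    py <- pop$population * spec$years * (1 - spec$loss_to_followup)
    exp_counts <- data.frame(
      sex = sx, band = s$band, age_lo = s$age_lo, age_hi = s$age_hi,
      population = pop$population,
      person_years = py,
      cases_prevalent = pop$population * s$prevalence,
      cases_incident = py * s$i * (1 - s$prevalence),
      deaths_cause = py * s$f * s$prevalence,
      deaths_background = py * s$m,
      stringsAsFactors = FALSE)
    obs <- exp_counts
    for (cc in c("cases_prevalent", "cases_incident", "deaths_cause",
                 "deaths_background"))
      obs[[cc]] <- draw(exp_counts[[cc]])
    obs$deaths_all_cause <- obs$deaths_background + obs$deaths_cause
    obs$deaths_background <- NULL
    strata[[sx]] <- obs
    truth_band[[sx]] <- cbind(sex = sx, s)
    truth_exp[[sx]] <- exp_counts
  }
  strata <- do.call(rbind, c(strata, make.row.names = FALSE))
  structure(list(strata = strata,
                 truth = list(
                   hazards = hz,
                   band_summary = do.call(rbind,
                                          c(truth_band,
                                            make.row.names = FALSE)),
                   expected = do.call(rbind, c(truth_exp,
                                               make.row.names = FALSE))),
                 spec = spec),
            class = "idm_cohort")
}

#' @export
print.idm_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d strata, %s noise, %g follow-up years, seed %s\n",
    nrow(x$strata), x$spec$noise, x$spec$years, x$spec$seed))
  cat(sprintf("  total population %s; prevalent cases %d; incident cases %d\n",
              format(sum(x$strata$population), big.mark = ","),
              as.integer(round(sum(x$strata$cases_prevalent))),
              as.integer(round(sum(x$strata$cases_incident)))))
  invisible(x)
}

#' Simulate cohorts from a fitted illness-death model
#'
#' Draws synthetic stratum tables whose generating hazards are the fitted
#' schedules, at a given stratum population structure.
#'
#' @param object an [idm_fit()] object.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param population stratum populations (`sex`, `age_lo`, `age_hi`,
#'   `population`); defaults to 10,000 per stratum.
#' @param years follow-up years.
#' @param ... unused.
#' @return a list of `idm_cohort` objects (length `nsim`).
#' @export
simulate.idm_fit <- function(object, nsim = 1, seed = 20151223,
                             population = NULL, years = 4, ...) {
  hz <- do.call(rbind, lapply(names(object$schedules), function(sx) {
    h <- as.data.frame(object$schedules[[sx]])
    cbind(sex = sx, h[setdiff(names(h), "sex")])
  }))
  class(hz) <- c("hazard_schedule", "data.frame")
  if (is.null(population))
    population <- data.frame(sex = hz$sex, age_lo = hz$age_lo,
                             age_hi = hz$age_hi, population = 10000)
  lapply(seq_len(nsim), function(k) {
    generate_cohort(cohort_spec(hz, population, years = years,
                                seed = seed + k - 1))
  })
}

#' Packaged surveillance fixtures
#'
#' Returns the packaged stratum-level tables from the Agincourt HDSS
#' convulsive-epilepsy surveillance (2008--2012): site demography and
#' all-cause mortality by sex and age band; the consistency-engine output
#' schedule (incidence, prevalence, remission, duration, SMR with 95%
#' uncertainty intervals — the female 0--5 duration interval is missing in
#' the source and stored as `NA`); the absolute and per-1,000 burden
#' tables; the prevalence- versus incidence-method comparison inputs; and
#' the disability-weight sensitivity table. Also includes the packaged
#' standard life table.
#'
#' @return a named list of data frames: `demography`, `dismod`,
#'   `burden_absolute`, `burden_per1000`, `method_comparison`,
#'   `dw_sensitivity`, `life_table`.
#' @examples
#' fx <- agincourt_fixture()
#' subset(fx$demography, sex == "male" & band == "0-5")$person_years
#' @export
agincourt_fixture <- function() {
  rd <- function(f) read.csv(system.file("extdata", f, package = "epiburden"),
                             stringsAsFactors = FALSE)
  list(demography = rd("agincourt_demography.csv"),
       dismod = rd("agincourt_dismod.csv"),
       burden_absolute = rd("agincourt_burden_absolute.csv"),
       burden_per1000 = rd("agincourt_burden_per1000.csv"),
       method_comparison = rd("agincourt_method_comparison.csv"),
       dw_sensitivity = rd("agincourt_dw_sensitivity.csv"),
       life_table = load_life_table("gbd2010_standard"))
}

#' Agincourt-scale cohort specification
#'
#' Builds a [cohort_spec()] whose populations and hazards mirror the
#' packaged surveillance fixtures: band populations from observed
#' person-years over the follow-up, incidence and remission from the
#' consistency schedule, background mortality from the demography table,
#' and excess mortality from the schedule's SMR via `f = (SMR - 1) m`.
#' This is the default "realistic" truth for validation studies.
#'
#' @inheritParams cohort_spec
#' @return a `cohort_spec`.
#' @export
agincourt_cohort_spec <- function(years = 4,
                                  noise = "poisson", noise_sd = 0.05,
                                  seed = 20151223) {
  fx <- agincourt_fixture()
  dm <- fx$demography[fx$demography$band != "all", ]
  dd <- fx$dismod[fx$dismod$band != "all", ]
  key <- paste(dm$sex, dm$band)
  dd <- dd[match(key, paste(dd$sex, dd$band)), ]
  m <- dm$mort_per1000 / 1000
  hz <- data.frame(sex = dm$sex, band = dm$band,
                   age_lo = dm$age_lo,
                   age_hi = ifelse(is.na(dm$age_hi), Inf, dm$age_hi),
                   i = dd$inc_per100k / 1e5,
                   r = dd$rem_per100 / 100,
                   f = pmax(dd$smr - 1, 0) * m,
                   m = m)
  class(hz) <- c("hazard_schedule", "data.frame")
  population <- data.frame(sex = dm$sex, age_lo = hz$age_lo,
                           age_hi = hz$age_hi, band = dm$band,
                           population = dm$person_years / years)
  cohort_spec(hz, population, years = years, noise = noise,
              noise_sd = noise_sd, seed = seed)
}

#' Read a stratum table from CSV
#'
#' Reads and validates the stratum-table interchange format: one row per
#' (sex, age band) stratum with columns `sex`, `age_lo`, `age_hi` (empty
#' upper bound = open-ended), `person_years`, `deaths_all_cause`,
#' `population`, `cases_prevalent`, `cases_incident`, `deaths_cause`.
#' Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return a validated stratum data frame.
#' @export
read_strata <- function(path) {
  if (!file.exists(path)) stopf("strata file '%s' not found", path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "person_years", "deaths_all_cause",
            "population", "cases_prevalent", "cases_incident", "deaths_cause")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("strata file missing columns: %s", paste(miss, collapse = ", "))
  for (cc in setdiff(need, c("sex", "age_hi")))
    check_nonneg(d[[cc]], cc)
  d
}

#' Write a stratum table to CSV
#'
#' @param strata a stratum data frame (e.g. from [generate_cohort()]).
#' @param path output CSV path.
#' @param hash optional configuration hash written as a `#` comment line.
#' @return `path`, invisibly.
#' @export
write_strata <- function(strata, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  write.csv(strata, con, row.names = FALSE)
  invisible(path)
}
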