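#' Default pipeline configuration
#'
#' @param outdir output directory for the run.
#' @param ... overrides for any top-level key.
#' @return a named list of configuration values: `strata` (path to a
#'   stratum CSV, or `"agincourt"` for the packaged fixtures),
#'   `life_table` (built-in name or CSV path), `dw_reference` and
#'   `dw_set`, `method` (`"prevalence"`, `"incidence"` or `"both"`),
#'   `death_age_convention`, `years` (follow-up years behind the counts),
#'   `bootstrap` (`enabled`, `iterations`, `seed`, `unit`), `uncertainty`
#'   (`enabled`, `iterations`, `seed`) and `seed`.
#' @export
default_config <- function(outdir = tempfile("epiburden_run"), ...) {
  cfg <- list(
    strata = "agincourt",
    life_table = "gbd2010_standard",
    dw_reference = 0.346,
    dw_set = as.list(gbd2010_dw()),
    method = "both",
    death_age_convention = "midpoint",
    years = 4,
    bootstrap = list(enabled = FALSE, iterations = 1000, seed = 20151223,
                     unit = "counts"),
    uncertainty = list(enabled = FALSE, iterations = 200, seed = 20151223),
    seed = 20151223,
    outdir = outdir)
  mods <- list(...)
  for (k in names(mods)) {
    if (is.list(cfg[[k]]) && is.list(mods[[k]]) && !is.data.frame(mods[[k]]))
      cfg[[k]][names(mods[[k]])] <- mods[[k]]
    else cfg[[k]] <- mods[[k]]
  }
  cfg
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    user <- yaml::read_yaml(config)
    cfg <- default_config()
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]]))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      else cfg[[k]] <- user[[k]]
    }
    cfg
  } else if (is.list(config)) {
    cfg <- do.call(default_config, config[names(config) != ""])
    cfg
  } else stopf("config must be a list or a YAML path")
}

config_hash <- function(cfg) {
  cfg$outdir <- NULL   # where outputs land must not change what they contain
  if (inherits(cfg$strata, "idm_cohort")) cfg$strata <- cfg$strata$strata
  if (is.data.frame(cfg$strata)) cfg$strata <- as.data.frame(cfg$strata)
  fnv1a32(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                        digits = NA)))
}

#' Run the full burden-of-disease pipeline
#'
#' Orchestrates every stage end to end: consistency modelling, YLD by
#' both approaches, life-table YLL, DALY assembly, method comparison,
#' disability-weight sensitivity, and (optionally) bootstrap uncertainty
#' intervals. Two input modes:
#' \describe{
#'   \item{fixture mode (`strata = "agincourt"`)}{reproduces the packaged
#'     surveillance analysis from the fixture tables (the consistency
#'     schedule ships as data; burden arithmetic is recomputed).}
#'   \item{count mode (`strata` = CSV path or stratum data frame)}{fits
#'     the illness-death model to the counts and derives all burden
#'     quantities from the fitted schedules and observed deaths.}
#' }
#' Outputs are written under `config$outdir`: `consistency.csv`,
#' `burden_absolute.csv`, `burden_per_1000.csv`, `method_comparison.csv`,
#' `sensitivity.csv`, a machine-readable `summary.json` and a `run.log`.
#' Every file carries the configuration hash; re-running an identical
#' configuration reproduces identical files. A failing stage aborts with
#' a stage-labelled error and removes partial outputs.
#'
#' @param config a configuration list ([default_config()]) or a YAML path.
#' @return invisibly, a list with the pipeline results (`fit`, `burden`,
#'   `comparison`, `sensitivity`, `summary`, `files`).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  if (!cfg$method %in% c("prevalence", "incidence", "both"))
    stopf("method must be prevalence, incidence or both")
  hash <- config_hash(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s: %s", name, conditionMessage(e)))
  }
  emit <- function(df, file) {
    path <- file.path(cfg$outdir, file)
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    written <<- c(written, path)
    path
  }

  set.seed(cfg$seed)
  lt <- stage("life_table", load_life_table(cfg$life_table))
  dw_ref <- cfg$dw_reference
  fixture_mode <- identical(cfg$strata, "agincourt")

  if (fixture_mode) {
    res <- stage("burden", pipeline_fixture_burden(cfg, lt, dw_ref))
  } else {
    res <- stage("fit_and_burden", pipeline_count_burden(cfg, lt, dw_ref))
  }

  emit(res$consistency, "consistency.csv")
  emit(as.data.frame(res$burden), "burden_absolute.csv")
  per1000 <- res$burden[c("sex", "band", "yll_per_1000", "yld_per_1000",
                          "daly_per_1000")]
  emit(per1000, "burden_per_1000.csv")
  emit(res$comparison_table, "method_comparison.csv")

  sens <- stage("sensitivity",
                dw_scan(res$yld_total, dw_ref,
                        dw_set = unlist(cfg$dw_set),
                        base_lo = res$yld_lo, base_hi = res$yld_hi,
                        yll = res$yll_total))
  emit(as.data.frame(sens), "sensitivity.csv")

  both <- res$burden[res$burden$sex == "both" & res$burden$band == "all", ]
  if (nrow(both) == 0)
    both <- res$burden[res$burden$band == "all", ][1, ]
  summary_out <- list(
    config_hash = hash, seed = cfg$seed,
    package_version = as.character(packageVersion("epiburden")),
    method = cfg$method, mode = if (fixture_mode) "fixture" else "counts",
    totals = list(yll = both$yll, yld = both$yld, daly = both$daly,
                  population = both$population,
                  daly_per_1000 = both$daly_per_1000,
                  yll_share_pct = 100 * both$yll / both$daly,
                  yld_share_pct = 100 * both$yld / both$daly),
    comparison = res$comparison,
    sensitivity = setNames(as.list(sens$yld), sens$state),
    bootstrap = res$bootstrap)
  json_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary_out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written <- c(written, json_path)

  log_path <- file.path(cfg$outdir, "run.log")
  writeLines(c(
    sprintf("epiburden %s", summary_out$package_version),
    sprintf("config_hash %s", hash),
    sprintf("seed %s", cfg$seed),
    sprintf("mode %s", summary_out$mode),
    sprintf("stages consistency,burden,comparison,sensitivity%s",
            if (isTRUE(cfg$bootstrap$enabled)) ",bootstrap" else "")),
    log_path)
  written <- c(written, log_path)

  ok <- TRUE
  invisible(list(fit = res$fit, burden = res$burden,
                 comparison = res$comparison, sensitivity = sens,
                 summary = summary_out, files = written))
}

# fixture mode: burden arithmetic over the packaged surveillance tables
pipeline_fixture_burden <- function(cfg, lt, dw_ref) {
  fx <- agincourt_fixture()
  mc <- fx$method_comparison
  ba <- fx$burden_absolute

  sexes <- c("male", "female")
  pop <- vapply(sexes, function(sx)
    mc$population[mc$sex == sx & mc$method == "prevalence"], numeric(1))
  prev <- vapply(sexes, function(sx)
    mc$prev_per1000[mc$sex == sx & mc$method == "prevalence"] / 1000,
    numeric(1))
  inc <- vapply(sexes, function(sx)
    mc$inc_per100k[mc$sex == sx & mc$method == "incidence"] / 1e5, numeric(1))
  dur <- vapply(sexes, function(sx)
    mc$duration_years[mc$sex == sx & mc$method == "incidence"], numeric(1))

  yld_prev <- yld_prevalence(pop, prev, dw_ref)
  yld_inc <- yld_incidence(pop, inc, dur, dw_ref)
  yll_sex <- vapply(sexes, function(sx)
    ba$yll[ba$sex == sx & ba$band == "all"], numeric(1))

  # assembled table: all-ages per-sex cells; the YLD fixture (per-band
  # pathway) feeds DALY assembly, as the printed burden tables do
  yld_fix <- vapply(sexes, function(sx)
    ba$yld[ba$sex == sx & ba$band == "all"], numeric(1))
  cells <- data.frame(sex = sexes, band = "all-ages")
  burden <- assemble_daly(
    yll_table = cbind(cells, value = yll_sex),
    yld_table = cbind(cells, value = yld_fix),
    population = cbind(cells, population = pop))

  cmp <- compare_methods(yld_prev, yld_inc, yll_sex)
  cmp_both <- compare_methods(sum(yld_prev), sum(yld_inc), sum(yll_sex))
  comparison <- list(
    by_sex = list(sex = sexes,
                  yld_prevalence = yld_prev, yld_incidence = yld_inc,
                  pct_diff_yld = cmp$pct_diff_yld_int,
                  pct_diff_daly = cmp$pct_diff_daly_int),
    both = list(pct_diff_yld = cmp_both$pct_diff_yld_int,
                pct_diff_daly = cmp_both$pct_diff_daly_int))
  comparison_table <- data.frame(
    sex = rep(sexes, each = 2),
    method = rep(c("incidence", "prevalence"), 2),
    population = rep(pop, each = 2),
    yld = as.numeric(rbind(yld_inc, yld_prev)),
    pct_diff_yld = as.numeric(rbind(cmp$pct_diff_yld_int, NA)),
    pct_diff_daly = as.numeric(rbind(cmp$pct_diff_daly_int, NA)))

  both_row <- ba[ba$sex == "both" & ba$band == "all", ]
  list(fit = NULL, burden = burden,
       consistency = fx$dismod,
       comparison = comparison, comparison_table = comparison_table,
       yld_total = both_row$yld, yld_lo = both_row$yld_lo,
       yld_hi = both_row$yld_hi, yll_total = both_row$yll,
       bootstrap = NULL)
}

# count mode: fit the model, then derive the burden from fitted schedules
pipeline_count_burden <- function(cfg, lt, dw_ref) {
  strata <- if (is.character(cfg$strata)) read_strata(cfg$strata)
            else if (inherits(cfg$strata, "idm_cohort")) cfg$strata$strata
            else cfg$strata
  fit <- idm_fit(strata)
  sexes <- names(fit$schedules)
  s <- fit$band_summary
  key <- paste(s$sex, s$age_lo)
  skey <- paste(strata$sex, strata$age_lo)
  pop <- strata$population[match(key, skey)]
  py <- strata$person_years[match(key, skey)]
  deaths_cause <- (strata$deaths_cause %||% rep(0, nrow(strata)))[
    match(key, skey)]

  yld_p <- yld_prevalence(pop, s$prevalence, dw_ref)
  yld_i <- yld_incidence(pop, s$i * (1 - s$prevalence), s$duration, dw_ref)
  ages <- band_age(s$age_lo, s$age_hi, cfg$death_age_convention,
                   age_max = max(lt$age))
  yll_cells <- deaths_cause / cfg$years * expectancy_at(lt, ages)

  cells <- data.frame(sex = s$sex, band = s$band)
  primary_yld <- if (cfg$method == "incidence") yld_i else yld_p
  burden <- assemble_daly(
    yll_table = cbind(cells, value = yll_cells),
    yld_table = cbind(cells, value = primary_yld),
    population = cbind(cells, population = pop))

  agg <- function(v, sx) sum(v[s$sex == sx])
  yld_prev_sex <- vapply(sexes, agg, numeric(1), v = yld_p)
  yld_inc_sex <- vapply(sexes, agg, numeric(1), v = yld_i)
  yll_sex <- vapply(sexes, agg, numeric(1), v = yll_cells)
  cmp <- compare_methods(yld_prev_sex, yld_inc_sex, yll_sex)
  cmp_both <- compare_methods(sum(yld_prev_sex), sum(yld_inc_sex),
                              sum(yll_sex))
  comparison <- list(
    by_sex = list(sex = sexes, yld_prevalence = yld_prev_sex,
                  yld_incidence = yld_inc_sex,
                  pct_diff_yld = cmp$pct_diff_yld_int,
                  pct_diff_daly = cmp$pct_diff_daly_int),
    both = list(pct_diff_yld = cmp_both$pct_diff_yld_int,
                pct_diff_daly = cmp_both$pct_diff_daly_int))
  comparison_table <- data.frame(
    sex = rep(sexes, each = 2),
    method = rep(c("incidence", "prevalence"), length(sexes)),
    population = rep(vapply(sexes, agg, numeric(1), v = pop), each = 2),
    yld = as.numeric(rbind(yld_inc_sex, yld_prev_sex)),
    pct_diff_yld = as.numeric(rbind(cmp$pct_diff_yld_int, NA)),
    pct_diff_daly = as.numeric(rbind(cmp$pct_diff_daly_int, NA)))

  boot_out <- NULL
  if (isTRUE(cfg$bootstrap$enabled)) {
    bs <- cfg$bootstrap
    lt_force <- lt; conv <- cfg$death_age_convention; yrs <- cfg$years
    stat_yld <- function(d) sum(d$cases_prevalent) * dw_ref
    stat_yll <- function(d) {
      a <- band_age(d$age_lo, d$age_hi, conv, age_max = max(lt_force$age))
      sum(d$deaths_cause / yrs * expectancy_at(lt_force, a))
    }
    stat_daly <- function(d) stat_yld(d) + stat_yll(d)
    bi <- lapply(list(yld = stat_yld, yll = stat_yll, daly = stat_daly),
                 function(st) {
                   b <- bootstrap_interval(strata, st,
                                           iterations = bs$iterations,
                                           seed = bs$seed, unit = bs$unit)
                   list(point = b$point, lo = b$lo, hi = b$hi)
                 })
    boot_out <- bi
  }

  consistency <- summary(fit)
  list(fit = fit, burden = burden, consistency = as.data.frame(consistency),
       comparison = comparison, comparison_table = comparison_table,
       yld_total = sum(primary_yld), yld_lo = NULL, yld_hi = NULL,
       yll_total = sum(yll_cells), bootstrap = boot_out)
}
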