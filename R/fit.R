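#' Fit a consistent illness-death model to stratified surveillance data
#'
#' The consistency engine at the heart of the package. Given band-level
#' observations of at least three of \{prevalence, incidence, remission,
#' cause-specific mortality\} together with background all-cause mortality,
#' it finds band-constant hazards (incidence `i`, remission `r`, excess
#' mortality `f`) whose forward solution ([idm_solve()]) reproduces the
#' observations, by weighted least squares. The fitted object reports the
#' mutually consistent incidence, prevalence, remission, duration and SMR
#' schedules that the raw observations cannot supply on their own.
#'
#' Bands are fitted youngest-first: each band's three hazards are optimised
#' (`nlminb`, box-constrained at 0) against that band's observations, with
#' the disease-state vector carried across the band boundary. On noise-free
#' observations generated by the model itself this recovers the generating
#' hazards exactly (up to optimiser tolerance).
#'
#' @param data a data frame in one of two layouts, optionally with a `sex`
#'   column (each sex is fitted separately):
#'   \describe{
#'     \item{counts}{stratum counts: `age_lo`, `age_hi`, `person_years`,
#'       `deaths_all_cause`, `population`, and at least three of
#'       `cases_prevalent`, `cases_incident`, `deaths_cause` (plus optional
#'       `remissions`). Rates and Poisson standard errors are derived.}
#'     \item{rates}{band rates: `age_lo`, `age_hi`, `m` and at least three
#'       of `prevalence`, `incidence`, `remission`, `cause_mortality`, with
#'       optional `<name>_se` columns for inverse-variance weighting.}
#'   }
#' @param weights `"inverse_variance"` (default; uses standard errors where
#'   available) or `"equal"` (each quantity scaled by its cross-band mean).
#' @param age_max truncation age for the open-ended band (years).
#' @param step integration step in years.
#' @param control passed to [stats::nlminb()].
#' @return an object of class `idm_fit` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot` and `simulate`. Key fields:
#'   `schedules` (fitted [hazard_schedule()] per sex), `solutions`
#'   (per-sex [idm_solve()] output), `discrepancy` (total weighted SS),
#'   `converged`, and `flags` (e.g. `"unidentified"` for a sex with no
#'   observed disease).
#' @examples
#' bands <- surveillance_bands()
#' truth <- hazard_schedule(bands, i = 2e-4, r = 0.05, f = 0.01,
#'                          m = c(4, 1, 1, 5, 12, 40) / 1000)
#' obs <- idm_observe(truth)          # model-implied band rates
#' fit <- idm_fit(obs)
#' max(abs(coef(fit)$i - truth$i) / truth$i)  # ~0 on noise-free input
#' @export
idm_fit <- function(data,
                    weights = c("inverse_variance", "equal"),
                    age_max = 100, step = 0.1, control = list()) {
  weights <- match.arg(weights)
  if (!is.data.frame(data)) stopf("data must be a data frame")
  rates <- if ("person_years" %in% names(data)) strata_to_rates(data)
           else validate_rates(data)
  sexes <- if ("sex" %in% names(rates)) unique(rates$sex) else "all"

  fits <- lapply(sexes, function(sx) {
    obs <- if ("sex" %in% names(rates)) rates[rates$sex == sx, , drop = FALSE]
           else rates
    fit_one_sex(obs, weights = weights, age_max = age_max, step = step,
                control = control)
  })
  names(fits) <- sexes

  schedules <- lapply(fits, `[[`, "schedule")
  solutions <- lapply(schedules, idm_solve, age_max = age_max, step = step)
  summaries <- mapply(function(sol, sx) {
    s <- idm_band_summary(sol, age_max = age_max)
    cbind(sex = sx, s)
  }, solutions, sexes, SIMPLIFY = FALSE)

  structure(list(
    schedules = schedules,
    solutions = solutions,
    band_summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
    observed = rates,
    discrepancy = sum(vapply(fits, `[[`, numeric(1), "discrepancy")),
    converged = all(vapply(fits, `[[`, logical(1), "converged")),
    flags = unlist(lapply(fits, `[[`, "flags")),
    weights = weights, age_max = age_max, step = step,
    call = match.call()
  ), class = "idm_fit")
}

# ---- input handling ---------------------------------------------------------

obs_quantities <- c("prevalence", "incidence", "remission", "cause_mortality")

# derive band rates + Poisson standard errors from stratum counts
strata_to_rates <- function(strata) {
  need <- c("age_lo", "age_hi", "person_years")
  if (!all(need %in% names(strata)))
    stopf("count data need columns %s", paste(need, collapse = ", "))
  py <- strata$person_years
  pop <- strata$population %||% stopf("count data need a population column")
  out <- strata[intersect(c("sex", "band", "age_lo", "age_hi"), names(strata))]
  se_rate <- function(count, expo) sqrt(pmax(count, 0.5)) / expo

  if (!is.null(strata$cases_prevalent)) {
    out$prevalence <- strata$cases_prevalent / pop
    out$prevalence_se <- se_rate(strata$cases_prevalent, pop)
  }
  if (!is.null(strata$cases_incident)) {
    out$incidence <- strata$cases_incident / py
    out$incidence_se <- se_rate(strata$cases_incident, py)
  }
  if (!is.null(strata$remissions)) {
    out$remission <- strata$remissions / py
    out$remission_se <- se_rate(strata$remissions, py)
  }
  if (!is.null(strata$deaths_cause)) {
    out$cause_mortality <- strata$deaths_cause / py
    out$cause_mortality_se <- se_rate(strata$deaths_cause, py)
  }
  if (is.null(strata$deaths_all_cause))
    stopf("count data need deaths_all_cause for background mortality")
  # background mortality: strip cause-specific deaths when we have them,
  # so the excess hazard is not counted twice
  d_bg <- strata$deaths_all_cause - (strata$deaths_cause %||% 0)
  out$m <- pmax(d_bg, 0) / py
  validate_rates(out)
}

validate_rates <- function(rates) {
  need <- c("age_lo", "age_hi", "m")
  if (!all(need %in% names(rates)))
    stopf("rate data need columns %s", paste(need, collapse = ", "))
  present <- intersect(obs_quantities, names(rates))
  present <- present[vapply(present, function(q) any(!is.na(rates[[q]])),
                            logical(1))]
  if (length(present) < 3)
    stopf(paste("underdetermined fit: need at least three observed",
                "quantities among prevalence, incidence, remission,",
                "cause_mortality (got %d)"), length(present))
  for (q in present) check_nonneg(rates[[q]][!is.na(rates[[q]])], q)
  check_nonneg(rates$m, "background mortality m")
  if (any(rates$m == 0))
    stopf("background mortality m must be positive in every band")
  rates
}

# model-implied band observations from a known schedule (noise-free);
# useful for round-trip checks and as the generator's expectation layer
#' Model-implied band rates from a hazard schedule
#'
#' Computes the band-level observations (prevalence at the band midpoint,
#' incidence, remission and cause-specific mortality per person-year, and
#' background mortality `m`) that the illness-death model implies for a
#' known [hazard_schedule()]. This is the noise-free observation operator:
#' `idm_fit(idm_observe(h))` recovers `h`.
#'
#' @param hazards a [hazard_schedule()] (single sex).
#' @inheritParams idm_fit
#' @return a data frame in the rates layout accepted by [idm_fit()].
#' @export
idm_observe <- function(hazards, age_max = 100, step = 0.1) {
  sol <- idm_solve(hazards, age_max = age_max, step = step)
  s <- idm_band_summary(sol, age_max = age_max)
  data.frame(band = s$band, age_lo = s$age_lo, age_hi = s$age_hi,
             m = s$m,
             prevalence = s$prevalence,
             incidence = s$i * (1 - s$prevalence),
             remission = s$r,
             cause_mortality = s$f * s$prevalence,
             stringsAsFactors = FALSE)
}

# ---- the per-sex sequential WLS engine --------------------------------------

fit_one_sex <- function(obs, weights, age_max, step, control) {
  nb <- nrow(obs)
  present <- intersect(obs_quantities, names(obs))
  present <- present[vapply(present, function(q) any(!is.na(obs[[q]])),
                            logical(1))]

  zero_prev <- is.null(obs$prevalence) ||
    all(obs$prevalence == 0 | is.na(obs$prevalence))
  zero_inc <- is.null(obs$incidence) ||
    all(obs$incidence == 0 | is.na(obs$incidence))
  if (zero_prev && zero_inc) {
    # no disease observed: i = 0; r and f cannot be identified and are
    # returned as 0 with an explicit flag rather than silently
    sched <- hazard_schedule(obs, i = 0, r = 0, f = 0, m = obs$m)
    return(list(schedule = sched, discrepancy = 0, converged = TRUE,
                flags = "unidentified"))
  }

  wts <- quantity_weights(obs, present, weights)

  i_hat <- r_hat <- f_hat <- numeric(nb)
  disc <- 0
  conv <- TRUE
  st <- c(1, 0)                       # disease-free at age 0

  for (b in seq_len(nb)) {
    hi <- min(obs$age_hi[b], age_max, na.rm = TRUE)
    width <- hi - obs$age_lo[b]
    nsteps <- max(2, round(width / step))
    if (nsteps %% 2 == 1) nsteps <- nsteps + 1
    hstep <- width / nsteps
    half <- nsteps / 2
    m_b <- obs$m[b]

    ob <- lapply(setNames(present, present), function(q) obs[[q]][b])
    wb <- lapply(setNames(present, present), function(q) wts[[q]][b])

    objective <- function(th) {
      M <- rk4_step_matrix(th[1], th[2], th[3], m_b, hstep)
      sm <- matpow(M, half) %*% st
      p_mid <- if (sum(sm) > 0) max(sm[2], 0) / sum(sm) else 0
      ss <- 0
      if (!is.null(ob$prevalence) && !is.na(ob$prevalence))
        ss <- ss + wb$prevalence * (p_mid - ob$prevalence)^2
      if (!is.null(ob$incidence) && !is.na(ob$incidence))
        ss <- ss + wb$incidence * (th[1] * (1 - p_mid) - ob$incidence)^2
      if (!is.null(ob$remission) && !is.na(ob$remission))
        ss <- ss + wb$remission * (th[2] - ob$remission)^2
      if (!is.null(ob$cause_mortality) && !is.na(ob$cause_mortality))
        ss <- ss + wb$cause_mortality * (th[3] * p_mid - ob$cause_mortality)^2
      ss
    }

    p_hint <- max(ob$prevalence %||% NA, st[2] / sum(st), 1e-4, na.rm = TRUE)
    start <- c(
      i = max(if (!is.null(ob$incidence) && !is.na(ob$incidence))
                ob$incidence / (1 - min(p_hint, 0.5)) else i_hat[max(b - 1, 1)],
              1e-8),
      r = max(if (!is.null(ob$remission) && !is.na(ob$remission))
                ob$remission else 0.1, 1e-8),
      f = max(if (!is.null(ob$cause_mortality) && !is.na(ob$cause_mortality))
                ob$cause_mortality / p_hint else 0, 0)
    )
    res <- nlminb(start, objective, lower = c(0, 0, 0), upper = c(1, 10, 10),
                  control = control)
    i_hat[b] <- res$par[1]; r_hat[b] <- res$par[2]; f_hat[b] <- res$par[3]
    disc <- disc + res$objective
    # flag only a hit iteration/evaluation cap (or a non-finite objective);
    # "false/singular convergence" at a machine-precision minimum is benign
    if (!is.finite(res$objective) ||
        grepl("limit reached", res$message %||% "")) conv <- FALSE

    M <- rk4_step_matrix(i_hat[b], r_hat[b], f_hat[b], m_b, hstep)
    st <- matpow(M, nsteps) %*% st
    st <- pmax(as.numeric(st), 0)
  }

  sched <- hazard_schedule(obs, i = i_hat, r = r_hat, f = f_hat, m = obs$m)
  list(schedule = sched, discrepancy = disc, converged = conv,
       flags = character(0))
}

quantity_weights <- function(obs, present, weights) {
  out <- list()
  for (q in present) {
    se <- obs[[paste0(q, "_se")]]
    if (weights == "inverse_variance" && !is.null(se) &&
        all(is.finite(se[!is.na(obs[[q]])]) & se[!is.na(obs[[q]])] > 0)) {
      out[[q]] <- 1 / se^2
    } else {
      # scale-free fallback: weight each quantity by its typical magnitude
      v <- obs[[q]][!is.na(obs[[q]])]
      typ <- mean(v[v > 0])
      if (!is.finite(typ) || typ == 0) typ <- 1
      out[[q]] <- rep(1 / typ^2, nrow(obs))
    }
  }
  out
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.idm_fit <- function(x, ...) {
  cat("Illness-death consistency fit\n")
  cat(sprintf("  sexes: %s; bands per sex: %d\n",
              paste(names(x$schedules), collapse = ", "),
              nrow(x$schedules[[1]])))
  cat(sprintf("  weighted discrepancy: %.4g; converged: %s\n",
              x$discrepancy, x$converged))
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), x$flags, sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.idm_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$schedules), function(sx) {
    s <- object$schedules[[sx]]
    cbind(sex = sx, as.data.frame(s)[c("band", "age_lo", "age_hi",
                                       "i", "r", "f", "m")])
  }))
  rownames(out) <- NULL
  out
}

#' Summarise a fitted illness-death model
#'
#' Produces the consistency table a surveillance analysis reports: per sex
#' and age band, incidence per 100,000 person-years, prevalence per 1,000,
#' remission per 100 person-years, duration of disease in years, and the
#' standardized mortality ratio, plus person-years-weighted all-ages rows.
#'
#' @param object an [idm_fit()] object.
#' @param ... unused.
#' @return a `summary.idm_fit` data frame.
#' @export
summary.idm_fit <- function(object, ...) {
  s <- object$band_summary
  out <- data.frame(
    sex = s$sex, band = s$band,
    inc_per100k = s$i * (1 - s$prevalence) * 1e5,
    prev_per1000 = s$prevalence * 1000,
    rem_per100 = s$r * 100,
    duration_years = s$duration,
    smr = s$smr, stringsAsFactors = FALSE)
  # all-ages rows: weight by band width (proxy exposure share of the grid)
  hi <- pmin(s$age_hi, object$age_max)
  w <- hi - s$age_lo
  all_rows <- do.call(rbind, lapply(unique(out$sex), function(sx) {
    k <- out$sex == sx
    data.frame(sex = sx, band = "all",
               inc_per100k = sum(out$inc_per100k[k] * w[k]) / sum(w[k]),
               prev_per1000 = sum(out$prev_per1000[k] * w[k]) / sum(w[k]),
               rem_per100 = sum(out$rem_per100[k] * w[k]) / sum(w[k]),
               duration_years = sum(out$duration_years[k] * w[k]) / sum(w[k]),
               smr = sum(out$smr[k] * w[k]) / sum(w[k]))
  }))
  out <- rbind(out, all_rows)
  structure(out, class = c("summary.idm_fit", "data.frame"),
            discrepancy = object$discrepancy, converged = object$converged)
}

#' @export
print.summary.idm_fit <- function(x, digits = 3, ...) {
  cat("Consistent epidemiological schedule (illness-death model)\n\n")
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, digits))
  print.data.frame(y, row.names = FALSE)
  cat(sprintf("\nweighted discrepancy %.4g; converged: %s\n",
              attr(x, "discrepancy"), attr(x, "converged")))
  invisible(x)
}

#' Predict from a fitted illness-death model
#'
#' @param object an [idm_fit()] object.
#' @param ages ages (years) at which to evaluate; defaults to the fit grid.
#' @param sex which fitted sex; defaults to the first.
#' @param type quantity to return.
#' @param ... unused.
#' @return numeric vector of the requested quantity at `ages`.
#' @export
predict.idm_fit <- function(object, ages = NULL,
                            sex = names(object$solutions)[1],
                            type = c("prevalence", "duration", "smr",
                                     "incidence", "remission"), ...) {
  type <- match.arg(type)
  sol <- object$solutions[[sex]]
  if (is.null(sol)) stopf("no fitted sex '%s'", sex)
  ages <- ages %||% sol$ages
  if (type %in% c("incidence", "remission")) {
    sched <- object$schedules[[sex]]
    idx <- band_index(ages, sched, age_max = object$age_max)
    return(if (type == "incidence") sched$i[idx] else sched$r[idx])
  }
  y <- switch(type, prevalence = sol$p, duration = sol$duration,
              smr = sol$smr)
  approx(sol$ages, y, xout = pmin(pmax(ages, min(sol$ages)), max(sol$ages)),
         rule = 2)$y
}

#' @export
residuals.idm_fit <- function(object, ...) {
  obs <- object$observed
  sexes <- names(object$schedules)
  out <- do.call(rbind, lapply(sexes, function(sx) {
    o <- if ("sex" %in% names(obs)) obs[obs$sex == sx, , drop = FALSE] else obs
    fitted_rates <- idm_observe(object$schedules[[sx]],
                                age_max = object$age_max, step = object$step)
    res <- data.frame(sex = sx, band = fitted_rates$band)
    for (q in obs_quantities) {
      if (!is.null(o[[q]])) res[[q]] <- o[[q]] - fitted_rates[[q]]
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Plot a fitted illness-death model
#'
#' Draws the fitted age-specific prevalence curve per sex with the observed
#' band-level prevalences overlaid at band midpoints.
#'
#' @param x an [idm_fit()] object.
#' @param ... passed to [plot()].
#' @export
plot.idm_fit <- function(x, ...) {
  sexes <- names(x$solutions)
  cols <- seq_along(sexes) + 1
  ylim <- c(0, max(vapply(x$solutions, function(s) max(s$p), numeric(1)),
                   x$observed$prevalence, na.rm = TRUE) * 1.1)
  plot(NA, xlim = range(x$solutions[[1]]$ages), ylim = ylim,
       xlab = "age (years)", ylab = "prevalence", ...)
  for (k in seq_along(sexes)) {
    sol <- x$solutions[[k]]
    lines(sol$ages, sol$p, col = cols[k], lwd = 2)
    o <- x$observed
    if ("sex" %in% names(o)) o <- o[o$sex == sexes[k], , drop = FALSE]
    if (!is.null(o$prevalence))
      points(band_midpoints(o, x$age_max), o$prevalence, col = cols[k],
             pch = 19)
  }
  legend("topleft", legend = sexes, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
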