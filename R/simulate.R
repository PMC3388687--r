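#' Configuration for the synthetic ICU cohort generator
#'
#' Returns the default generator configuration, optionally overridden
#' element-wise. Defaults emulate the marginal structure of a mixed
#' medical-surgical ICU cohort of the kind the score was developed in:
#' median age ~64 (IQR ~52-73), APACHE II ~21 (16-27), SOFA ~7 (5-9), days
#' from hospital to ICU admission with a large mass near 0 and median ~0.4,
#' BMI ~26.5 (23-31), comorbidity count with median 3, lognormal inflammation
#' markers, 28-day mortality ~23%, and nutrition-history variables
#' (oral intake, weight loss) unreported for ~71% of patients.
#'
#' Mortality is drawn from a logistic model on the patient's published-table
#' points: each point carries `per_point_logodds` (default 0.7) on the
#' log-odds scale, with the intercept solved so the cohort mortality equals
#' `target_rate` (unless an explicit `intercept` is given). Nutritional
#' adequacy modifies the association: the log-odds slope per percentage point
#' of adequacy is `adequacy$main + adequacy$interaction * points` (centred at
#' `adequacy$center`%), so energy benefit is concentrated in high-score
#' patients and absent/mildly harmful at low scores.
#'
#' `outcome$effect_mode = "marginal_integer"` switches to a
#' parameter-recovery design: the six score variables are drawn with
#' published-band probabilities aligned to the quintile grid, and the
#' per-band log-odds increments are calibrated (fixed point on the drawn
#' cohort) so that the cohort's marginal single-variable log-odds contrasts
#' equal the integer point values exactly; adequacy effects are disabled.
#'
#' @param n Number of patients (default 598).
#' @param seed Integer seed; fully determines the cohort.
#' @param ... Named overrides merged into the default list, e.g.
#'   `outcome = list(per_point_logodds = 0)`. Partial lists are merged
#'   element-wise.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 598, seed = 1, ...) {
  config <- list(
    n = n, seed = seed,
    marginals = list(
      age = list(mean = 63.9, sd = 16, min = 18),
      apache2 = list(shape = 7.5, scale = 2.9),
      sofa = list(shape = 7, scale = 1.07),
      days_hosp_to_icu = list(p0 = 0.3, max0 = 0.1, meanlog = 0.216,
                              sdlog = 2),
      bmi = list(meanlog = log(26.5), sdlog = 0.222),
      n_comorbid = list(probs = c(.12, .18, .18, .22, .20, .10)),
      il6 = list(meanlog = 4.7, sdlog = 1.4),
      crp = list(meanlog = 4.745, sdlog = 0.87),
      pct = list(meanlog = 0.405, sdlog = 2.2),
      oral_intake = list(p_full = 0.35, shape1 = 0.7, shape2 = 0.9),
      weight_loss = list(p_zero = 0.76, mean = 4)
    ),
    outcome = list(intercept = NULL, per_point_logodds = 0.7,
                   target_rate = 138 / 598, effect_mode = "calibrated"),
    adequacy = list(shape1 = 1.6, shape2 = 1.15, main = 0.015,
                    interaction = -0.018, center = 60),
    mv = list(p48_intercept = -1.25, p48_slope = 0.18, shape = 1.2,
              scale_base = 1.5, scale_slope = 0.9, p_no_mv = 0.7,
              late_shape = 1, late_scale = 2),
    missingness = list(oral_weight = 1 - 171 / 597, bmi = 0.052,
                       mode = "mcar", worse_slope = 0.15)
  )
  overrides <- list(...)
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  config <- merge_into(config, overrides)
  if (config$n < 1) stop("config error: n must be >= 1")
  probs <- config$marginals$n_comorbid$probs
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("config error: n_comorbid probabilities must be a distribution")
  }
  structure(config, class = "synthetic_config")
}

#' Read a generator configuration from a plain-text (YAML) file
#'
#' @param path Path to a `key: value` YAML file of overrides.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  do.call(synthetic_config, overrides)
}

## internal: draw n values from the realistic marginal of one score variable
draw_marginal <- function(var, n, m) {
  switch(var,
    age = pmax(m$age$min, stats::rnorm(n, m$age$mean, m$age$sd)),
    apache2 = stats::rgamma(n, shape = m$apache2$shape,
                            scale = m$apache2$scale),
    sofa = stats::rgamma(n, shape = m$sofa$shape, scale = m$sofa$scale),
    days_hosp_to_icu = {
      pm <- stats::runif(n) < m$days_hosp_to_icu$p0
      x <- stats::rlnorm(n, m$days_hosp_to_icu$meanlog,
                         m$days_hosp_to_icu$sdlog)
      x[pm] <- stats::runif(sum(pm), 0, m$days_hosp_to_icu$max0)
      x
    },
    il6 = stats::rlnorm(n, m$il6$meanlog, m$il6$sdlog),
    stop("unknown marginal: ", var)
  )
}

## internal: draw values whose published-band memberships follow exact
## probabilities on the quintile grid (parameter-recovery mode); values within
## each band keep the realistic marginal's shape via rejection
draw_banded <- function(var, n, m, edges, band_probs) {
  band <- sample.int(length(band_probs), n, replace = TRUE, prob = band_probs)
  lo <- c(-Inf, edges)[band]
  hi <- c(edges, Inf)[band]
  x <- draw_marginal(var, n, m)
  bad <- which(x < lo | x >= hi)
  guard <- 0
  while (length(bad)) {
    x[bad] <- draw_marginal(var, length(bad), m)
    bad <- bad[x[bad] < lo[bad] | x[bad] >= hi[bad]]
    guard <- guard + 1
    if (guard > 10000) stop("config error: band with negligible mass for ",
                            var)
  }
  x
}

## internal: fixed-point calibration so the cohort's marginal per-band
## log-odds contrasts equal the integer targets
calibrate_marginal_effects <- function(band_index, targets, target_rate,
                                       tol = 1e-8, max_iter = 500) {
  beta <- targets
  a <- stats::qlogis(target_rate)
  for (iter in seq_len(max_iter)) {
    lp <- a
    for (j in seq_along(beta)) lp <- lp + beta[[j]][band_index[[j]]]
    p <- stats::plogis(lp)
    err_rate <- stats::qlogis(target_rate) - stats::qlogis(mean(p))
    a <- a + err_rate
    max_err <- abs(err_rate)
    for (j in seq_along(beta)) {
      means <- tapply(p, band_index[[j]], mean)
      m <- stats::qlogis(means) - stats::qlogis(means[[1]])
      err <- targets[[j]] - as.numeric(m)
      beta[[j]] <- beta[[j]] + err
      beta[[j]] <- beta[[j]] - beta[[j]][1]
      max_err <- max(max_err, abs(err))
    }
    if (max_err < tol) break
  }
  list(beta = beta, intercept = a, iterations = iter, max_err = max_err)
}

#' Simulate a synthetic ICU cohort
#'
#' Generates a reproducible patient-level cohort with the statistical
#' structure the downstream analyses assume: marginals per the configured
#' distributions, 28-day mortality from a logistic model on the
#' published-table points (optionally modified by nutritional adequacy),
#' mechanical-ventilation duration increasing in the score among survivors,
#' daily energy intake as prescription x Beta-distributed adequacy, and
#' explicit missingness for the nutrition-history variables. Each variable
#' uses its own deterministic random sub-stream, so adding a variable does
#' not perturb the others.
#'
#' @param config A [synthetic_config()] (or an integer, shorthand for
#'   `synthetic_config(n = config)`).
#' @return A validated cohort data.frame with attribute `truth` (per-patient
#'   generating points and probabilities, adequacy fractions, and the
#'   resolved outcome model).
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  if (is.numeric(config)) config <- synthetic_config(n = config)
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  seed <- config$seed
  m <- config$marginals
  recovery <- identical(config$outcome$effect_mode, "marginal_integer")

  band_edges <- list(age = c(50, 75), apache2 = c(15, 20, 28),
                     sofa = c(6, 10), days_hosp_to_icu = 1, il6 = 400)
  band_probs <- list(age = c(.2, .6, .2), apache2 = c(.2, .2, .4, .2),
                     sofa = c(.4, .4, .2), days_hosp_to_icu = c(.6, .4),
                     il6 = c(.8, .2))

  draw_var <- function(var) {
    with_stream(seed, var, {
      if (recovery) {
        draw_banded(var, n, m, band_edges[[var]], band_probs[[var]])
      } else {
        draw_marginal(var, n, m)
      }
    })
  }
  age <- draw_var("age")
  apache2 <- draw_var("apache2")
  sofa <- draw_var("sofa")
  days <- draw_var("days_hosp_to_icu")
  il6 <- draw_var("il6")
  if (!recovery) {
    apache2 <- round(apache2)
    sofa <- round(sofa)
  }
  n_comorbid <- with_stream(seed, "n_comorbid",
                            sample(0:5, n, replace = TRUE,
                                   prob = m$n_comorbid$probs))
  bmi <- with_stream(seed, "bmi", stats::rlnorm(n, m$bmi$meanlog,
                                                m$bmi$sdlog))
  crp <- with_stream(seed, "crp", stats::rlnorm(n, m$crp$meanlog,
                                                m$crp$sdlog))
  pct <- with_stream(seed, "pct", stats::rlnorm(n, m$pct$meanlog,
                                                m$pct$sdlog))
  oral <- with_stream(seed, "oral_intake_pct", {
    full <- stats::runif(n) < m$oral_intake$p_full
    x <- round(100 * stats::rbeta(n, m$oral_intake$shape1,
                                  m$oral_intake$shape2))
    x[full] <- 100
    x
  })
  wloss <- with_stream(seed, "weight_loss_pct", {
    zero <- stats::runif(n) < m$weight_loss$p_zero
    x <- round(stats::rexp(n, rate = 1 / m$weight_loss$mean), 1)
    x[zero] <- 0
    x
  })

  points <- nutric_score(age = age, apache2 = apache2, sofa = sofa,
                         n_comorbid = n_comorbid,
                         days_hosp_to_icu = days, il6 = il6)

  adeq_frac <- with_stream(seed, "adequacy",
                           stats::rbeta(n, config$adequacy$shape1,
                                        config$adequacy$shape2))
  adeq_pct <- 100 * adeq_frac

  ## mechanical ventilation and ICU stay (drawn before the outcome model:
  ## the adequacy effect on mortality applies only to patients evaluable for
  ## nutritional intake, i.e. ventilated within 48 h with an ICU stay >= 3 d)
  mvp <- config$mv
  mv <- with_stream(seed, "mv", {
    p48 <- stats::plogis(mvp$p48_intercept + mvp$p48_slope * points)
    mv48 <- stats::rbinom(n, 1, p48)
    dur <- stats::rgamma(n, shape = mvp$shape,
                         scale = mvp$scale_base + mvp$scale_slope * points)
    late <- stats::rbinom(n, 1, 1 - mvp$p_no_mv) *
      stats::rgamma(n, shape = mvp$late_shape, scale = mvp$late_scale)
    mv_days <- ifelse(mv48 == 1, pmin(28, round(dur)),
                      pmin(28, round(late)))
    list(mv48 = mv48, mv_days = mv_days)
  })
  icu_days <- with_stream(seed, "icu", {
    pmin(28, mv$mv_days + stats::rgamma(n, shape = 1.1, scale = 1.5) +
           stats::runif(n, 0.1, 0.9))
  })
  evaluable <- mv$mv48 == 1 & icu_days >= 3

  ## outcome model
  if (recovery) {
    band_of <- function(x, edges) findInterval(x, edges) + 1L
    band_index <- list(
      age = band_of(age, band_edges$age),
      apache2 = band_of(apache2, band_edges$apache2),
      sofa = band_of(sofa, band_edges$sofa),
      n_comorbid = as.integer(n_comorbid) + 1L,
      days_hosp_to_icu = band_of(days, band_edges$days_hosp_to_icu),
      il6 = band_of(il6, band_edges$il6)
    )
    targets <- list(age = c(0, 1, 2), apache2 = c(0, 1, 2, 3),
                    sofa = c(0, 1, 2), n_comorbid = c(0, 0, 1, 1, 1, 1),
                    days_hosp_to_icu = c(0, 1), il6 = c(0, 1))
    cal <- calibrate_marginal_effects(band_index, targets,
                                      config$outcome$target_rate)
    lp <- cal$intercept
    for (j in names(targets)) lp <- lp + cal$beta[[j]][band_index[[j]]]
    outcome_model <- list(mode = "marginal_integer", beta = cal$beta,
                          intercept = cal$intercept,
                          iterations = cal$iterations)
  } else {
    slope <- config$adequacy$main + config$adequacy$interaction * points
    adeq_term <- slope * (adeq_pct - config$adequacy$center) * evaluable
    base <- config$outcome$per_point_logodds * points + adeq_term
    a <- config$outcome$intercept
    if (is.null(a)) {
      a <- stats::uniroot(
        function(b) mean(stats::plogis(b + base)) -
          config$outcome$target_rate,
        interval = c(-15, 10), tol = 1e-10
      )$root
    }
    lp <- a + base
    outcome_model <- list(mode = "calibrated", intercept = a,
                          per_point_logodds = config$outcome$per_point_logodds,
                          adequacy = config$adequacy)
  }
  p_true <- stats::plogis(lp)
  mort28 <- with_stream(seed, "mort28", stats::rbinom(n, 1, p_true))

  ## daily energy intake
  nutrition <- with_stream(seed, "energy", {
    prescribed <- round(pmin(3500, pmax(1200, stats::rnorm(n, 2000, 300))))
    daily <- lapply(seq_len(n), function(i) {
      ndays <- min(ceiling(icu_days[i]), 14)
      kcal <- prescribed[i] * adeq_frac[i] * stats::runif(ndays, 0.85, 1.15)
      if (icu_days[i] < 14) {
        kcal[ndays] <- kcal[ndays] * stats::runif(1, 0.2, 0.7)
      }
      round(kcal)
    })
    list(prescribed = prescribed, daily = daily)
  })
  energy_prescribed <- nutrition$prescribed
  energy_received_daily <- nutrition$daily

  ## missingness
  miss <- config$missingness
  missing_draw <- with_stream(seed, "missing", {
    p_ow <- if (identical(miss$mode, "worse")) {
      stats::plogis(stats::qlogis(miss$oral_weight) +
                      miss$worse_slope * (points - 4))
    } else {
      rep(miss$oral_weight, n)
    }
    list(ow = stats::runif(n) < p_ow, bmi = stats::runif(n) < miss$bmi)
  })
  oral[missing_draw$ow] <- NA
  wloss[missing_draw$ow] <- NA
  bmi[missing_draw$bmi] <- NA

  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, apache2 = apache2, sofa = sofa,
    days_hosp_to_icu = days, bmi = bmi, n_comorbid = n_comorbid,
    il6 = il6, crp = crp, pct = pct,
    oral_intake_pct = oral, weight_loss_pct = wloss,
    mort28 = mort28, mv_start_within_48h = mv$mv48,
    mv_days = mv$mv_days, icu_days = icu_days,
    energy_prescribed = energy_prescribed,
    stringsAsFactors = FALSE
  )
  cohort$energy_received_daily <- energy_received_daily
  cohort <- validate_cohort(cohort)
  attr(cohort, "truth") <- list(points = points, p = p_true,
                                adequacy_pct = adeq_pct,
                                outcome_model = outcome_model,
                                config = config)
  cohort
}
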