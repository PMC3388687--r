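#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks, on pairwise-complete observations
#' (the effective n is reported, as the per-variable observation counts are in
#' published summaries). Two-sided p from the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired non-missing observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Nutritional adequacy of energy intake
#'
#' Percentage of the prescribed energy actually received:
#' `100 * total kcal received over counted ICU days / (daily prescription *
#' counted days)`. Counted days are the ICU days capped at 14, excluding the
#' final (partial) ICU day unless that day is day 14. Patients are eligible
#' for the intake-outcome analysis when they started mechanical ventilation
#' within 48 h of ICU admission and stayed in ICU at least 3 days.
#'
#' @param cohort Cohort data.frame with `icu_days`, `energy_prescribed`,
#'   `energy_received_daily` (list column) and `mv_start_within_48h`.
#' @param cap Optional upper cap on the percentage (default `Inf`, i.e.
#'   overfeeding is representable; set 100 for a capped sensitivity run).
#' @return Data.frame with `patient_id`, `pct_received`, `counted_days`,
#'   `eligible`, `reason` (why ineligible / not computable).
#' @export
adequacy <- function(cohort, cap = Inf) {
  n <- nrow(cohort)
  stopifnot(all(c("icu_days", "energy_prescribed", "energy_received_daily",
                  "mv_start_within_48h") %in% names(cohort)))
  pct <- rep(NA_real_, n); counted <- rep(NA_integer_, n)
  eligible <- rep(FALSE, n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    presc <- cohort$energy_prescribed[i]
    icu <- cohort$icu_days[i]
    received <- cohort$energy_received_daily[[i]]
    if (is.na(presc) || is.null(received)) {
      reason[i] <- "nutrition data missing"
      next
    }
    if (presc <= 0) stop("zero or negative prescription in row ", i)
    ndays <- min(ceiling(icu), 14)
    cdays <- if (icu >= 14) 14L else ndays - 1L  # drop final partial day
    if (cdays < 1) {
      reason[i] <- "no full ICU days to count"
      next
    }
    cdays <- min(cdays, length(received))
    counted[i] <- cdays
    pct[i] <- min(100 * sum(received[seq_len(cdays)]) / (presc * cdays), cap)
    if (isTRUE(cohort$mv_start_within_48h[i] == 1) && icu >= 3) {
      eligible[i] <- TRUE
    } else {
      reason[i] <- if (icu < 3) "ICU stay shorter than 3 days" else
        "MV not started within 48 h"
    }
  }
  data.frame(
    patient_id = if ("patient_id" %in% names(cohort)) cohort$patient_id
    else as.character(seq_len(n)),
    pct_received = pct, counted_days = counted, eligible = eligible,
    reason = reason, stringsAsFactors = FALSE
  )
}

#' Mechanical-ventilation duration as a function of the score
#'
#' Ordinary least squares of MV days on the score (intended for 28-day
#' survivors), with the pure-error lack-of-fit F test using the replicate
#' groups at each distinct score value:
#' `F = [(SSE_line - SSE_pure)/(k-2)] / [SSE_pure/(n-k)]`, k = number of
#' distinct score values.
#'
#' @param score Per-patient score.
#' @param mv_days Days on mechanical ventilation.
#' @return List of class `mv_fit`: `slope`, `slope_p`, `intercept`,
#'   `lof_F`, `lof_p` (NA with a flag when no score value has replicates),
#'   `k`, `n`, `fit` (the `lm` object).
#' @export
mv_duration_model <- function(score, mv_days) {
  keep <- !is.na(score) & !is.na(mv_days)
  score <- score[keep]; mv_days <- mv_days[keep]
  k <- length(unique(score))
  if (k < 3) stop("need at least 3 distinct score values")
  fit <- stats::lm(mv_days ~ score)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  slope_p <- sm$coefficients[2, 4]
  has_reps <- any(table(score) > 1)
  if (has_reps && k > 2) {
    full <- stats::lm(mv_days ~ factor(score))
    sse_line <- sum(stats::residuals(fit)^2)
    sse_pure <- sum(stats::residuals(full)^2)
    n <- length(score)
    df_lof <- k - 2
    df_pure <- n - k
    sse_lof <- max(0, sse_line - sse_pure)
    if (sse_lof <= 1e-10 * max(1, sse_line)) {
      # the line already fits the group means (to numerical precision)
      lof_F <- 0
      lof_p <- 1
    } else if (sse_pure <= 1e-12 * max(1, sse_line)) {
      lof_F <- Inf
      lof_p <- 0
    } else {
      lof_F <- (sse_lof / df_lof) / (sse_pure / df_pure)
      lof_p <- stats::pf(lof_F, df_lof, df_pure, lower.tail = FALSE)
    }
  } else {
    warning("no replicate observations at any score value; ",
            "lack-of-fit test unavailable")
    lof_F <- NA_real_; lof_p <- NA_real_
  }
  structure(
    list(slope = slope, slope_p = slope_p,
         intercept = unname(stats::coef(fit)[1]),
         lof_F = lof_F, lof_p = lof_p, k = k, n = length(score), fit = fit),
    class = "mv_fit"
  )
}

#' @export
print.mv_fit <- function(x, ...) {
  cat(sprintf(
    "MV duration ~ score: slope %.3f d/point (p = %s), lack-of-fit p = %s\n",
    x$slope, format.pval(x$slope_p), format.pval(x$lof_p)))
  invisible(x)
}

#' Effect-modification test: nutritional intake x risk score
#'
#' Logistic regression of 28-day mortality on nutritional intake (% of
#' prescription received), the risk score, and their product, all as
#' continuous predictors, with a likelihood-ratio test (1 df) comparing the
#' models with and without the product term. Also returns predicted-mortality
#' curves with delta-method 95% confidence intervals over the observed intake
#' range, evaluated at the median score of the low (0-5) and high (6-10)
#' score groups.
#'
#' @param adequacy_pct Per-patient % of prescribed energy received.
#' @param score Per-patient risk score.
#' @param mort28 Binary outcome.
#' @param score_split Boundary between the plotted low and high score groups
#'   (default 5.5: groups 0-5 and 6-10).
#' @return List of class `nutric_interaction`: `coefficients`,
#'   `lrt_statistic`, `lrt_p`, `curves` (data.frame: group, intake grid,
#'   fit, lwr, upr), `n`, `converged`.
#' @export
interaction_test <- function(adequacy_pct, score, mort28,
                             score_split = 5.5) {
  keep <- !is.na(adequacy_pct) & !is.na(score) & !is.na(mort28)
  a <- adequacy_pct[keep]; s <- score[keep]; y <- mort28[keep]
  n <- length(y)
  if (length(unique(y)) < 2) stop("both outcomes must be present")
  if (n < 30) warning("interaction subset smaller than 30 patients")
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  full <- suppressWarnings(stats::glm(y ~ a * s, family = stats::binomial(),
                                      control = ctrl))
  reduced <- suppressWarnings(stats::glm(y ~ a + s,
                                         family = stats::binomial(),
                                         control = ctrl))
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(reduced))))
  lrt_p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  grid <- seq(min(a), max(a), length.out = 50)
  vc <- stats::vcov(full)
  beta <- stats::coef(full)
  curves <- do.call(rbind, lapply(c("low", "high"), function(gname) {
    sel <- if (gname == "low") s <= score_split else s > score_split
    if (!any(sel)) return(NULL)
    s_rep <- stats::median(s[sel])
    xmat <- cbind(1, grid, s_rep, grid * s_rep)
    eta <- drop(xmat %*% beta)
    se <- sqrt(rowSums((xmat %*% vc) * xmat))
    data.frame(group = gname, score_at = s_rep, intake = grid,
               fit = stats::plogis(eta),
               lwr = stats::plogis(eta - 1.96 * se),
               upr = stats::plogis(eta + 1.96 * se),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(coefficients = beta, lrt_statistic = lrt, lrt_p = lrt_p,
         curves = curves, n = n,
         converged = full$converged && reduced$converged),
    class = "nutric_interaction"
  )
}

#' @export
print.nutric_interaction <- function(x, ...) {
  cat("Intake x score effect modification (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  interaction coefficient: %.4f per %%*point\n",
              x$coefficients[["a:s"]]))
  cat(sprintf("  likelihood-ratio test: X2 = %.2f (df 1), p = %.4f\n",
              x$lrt_statistic, x$lrt_p))
  if (!x$converged) cat("  [warning: model did not converge]\n")
  invisible(x)
}
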