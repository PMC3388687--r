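#' Concordance index (c-statistic / AUC)
#'
#' Probability that a randomly chosen case (outcome 1) has a higher score
#' than a randomly chosen control, counting ties as 1/2; equals the area
#' under the ROC curve. Computed from average ranks (equivalent to all-pairs
#' enumeration, against which it is tested exactly).
#'
#' @param score Per-patient ordinal or continuous score.
#' @param outcome Binary outcome vector.
#' @return c-index in `[0, 1]`.
#' @export
c_index <- function(score, outcome) {
  keep <- !is.na(score) & !is.na(outcome)
  score <- score[keep]; outcome <- outcome[keep]
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    stop("c-index undefined: both outcome classes must be present")
  }
  r <- rank(score)  # average ranks handle ties as 1/2
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Likelihood-based R-squared statistics for a binary-outcome model
#'
#' Generalized (Cox-Snell) R2 = 1 - exp(2 (L0 - L1) / n) and its max-rescaled
#' (Nagelkerke) version, which divides by the attainable maximum
#' 1 - exp(2 L0 / n).
#'
#' @param loglik_null Log-likelihood of the intercept-only model (L0).
#' @param loglik_model Log-likelihood of the fitted model (L1 >= L0).
#' @param n Number of observations.
#' @return Named list with `r2_generalized` and `r2_max_rescaled`.
#' @export
logistic_r2 <- function(loglik_null, loglik_model, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_model < loglik_null - 1e-8) {
    stop("loglik_model must be >= loglik_null")
  }
  cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  max_attainable <- 1 - exp(2 * loglik_null / n)
  list(r2_generalized = cs, r2_max_rescaled = cs / max_attainable)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into deciles of predicted risk (ties kept together; the
#' number of groups is reduced when tied prediction values straddle decile
#' boundaries), then compares observed and expected deaths:
#' X2 = sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g)), df = g - 2.
#'
#' @param predicted_p Predicted probabilities in (0, 1).
#' @param outcome Binary outcome vector.
#' @param g Number of risk groups (default 10).
#' @return List of class `hl_test`: `statistic`, `df`, `p`, `groups` (table
#'   of n, observed and expected deaths per group), `small_cells` (TRUE when
#'   any expected count < 5).
#' @export
hosmer_lemeshow <- function(predicted_p, outcome, g = 10) {
  keep <- !is.na(predicted_p) & !is.na(outcome)
  p <- predicted_p[keep]; y <- outcome[keep]
  n <- length(p)
  if (n < g) stop("need at least g observations")
  if (any(p <= 0 | p >= 1)) stop("predicted_p must be in (0, 1)")
  ## walk the sorted unique prediction values, closing a group once its
  ## cumulative size reaches the next decile boundary; ties never split
  uvals <- sort(unique(p))
  ucounts <- tabulate(match(p, uvals))
  grp_of_uval <- integer(length(uvals))
  cum <- 0; gi <- 1L
  for (j in seq_along(uvals)) {
    grp_of_uval[j] <- gi
    cum <- cum + ucounts[j]
    if (cum >= gi * n / g && j < length(uvals)) gi <- gi + 1L
  }
  grp <- factor(grp_of_uval[match(p, uvals)])
  g_eff <- nlevels(grp)
  if (g_eff < 3) stop("fewer than 3 risk groups after tie-merging")
  n_g <- as.numeric(tapply(y, grp, length))
  o_g <- as.numeric(tapply(y, grp, sum))
  e_g <- as.numeric(tapply(p, grp, sum))
  statistic <- sum((o_g - e_g)^2 / (e_g * (1 - e_g / n_g)))
  df <- g_eff - 2
  small <- any(e_g < 5)
  if (small) {
    warning("Hosmer-Lemeshow: expected count < 5 in at least one group")
  }
  structure(
    list(statistic = statistic, df = df,
         p = stats::pchisq(statistic, df, lower.tail = FALSE),
         groups = data.frame(group = levels(grp), n = n_g, observed = o_g,
                             expected = e_g),
         small_cells = small),
    class = "hl_test"
  )
}

#' @export
print.hl_test <- function(x, ...) {
  cat("Hosmer-Lemeshow test: X2 = ", format(x$statistic, digits = 4),
      ", df = ", x$df, ", p = ", format.pval(x$p), "\n", sep = "")
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) where R2_j comes from the ordinary least-squares
#' regression of predictor j on the remaining predictors. Exact collinearity
#' yields an infinite VIF with a flag.
#'
#' @param design Numeric matrix or data.frame of predictors (>= 2 columns, no
#'   constant column).
#' @return Named numeric vector of VIFs (attribute `collinear` flags infinite
#'   entries).
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (ncol(x) < 2) stop("need at least 2 predictors")
  if (any(apply(x, 2, stats::sd) == 0)) stop("constant column in design")
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  attr(out, "collinear") <- !is.finite(out)
  if (any(!is.finite(out))) {
    warning("exact collinearity: infinite VIF for ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  out
}

#' Split-half cross-validation of the score derivation
#'
#' Randomly partitions the cohort into two halves (sizes differing by at most
#' one; simple random, not outcome-stratified), independently re-derives the
#' score in each half with [derive_score()], and evaluates each half's table
#' on the opposite half. A derivation failure in one half is reported for
#' that half rather than aborting the other.
#'
#' @param cohort Cohort data.frame.
#' @param seed Integer seed governing the partition.
#' @param ... Passed to [derive_score()].
#' @return List of class `split_cv`: per-half `derivation`, `c_in`
#'   (in-sample) and `c_out` (scored on the opposite half), plus the
#'   partition indices.
#' @export
split_half_cv <- function(cohort, seed = 1, ...) {
  n <- nrow(cohort)
  if (n < 100) stop("split-half derivation needs n >= 100")
  idx_a <- with_stream(seed, "split", sort(sample.int(n, floor(n / 2))))
  halves <- list(A = cohort[idx_a, , drop = FALSE],
                 B = cohort[-idx_a, , drop = FALSE])
  res <- lapply(names(halves), function(h) {
    other <- halves[[setdiff(names(halves), h)]]
    der <- tryCatch(derive_score(halves[[h]], ...), error = identity)
    if (inherits(der, "error")) {
      return(list(derivation = NULL, error = conditionMessage(der),
                  c_in = NA_real_, c_out = NA_real_))
    }
    c_in <- {
      s <- der$scores
      c_index(s, halves[[h]]$mort28)
    }
    s_out <- total_score(der$table, other, missing = "na")
    list(derivation = der, error = NULL, c_in = c_in,
         c_out = c_index(s_out, other$mort28))
  })
  names(res) <- names(halves)
  structure(list(halves = res, idx_a = idx_a, n = n, seed = seed),
            class = "split_cv")
}

#' @export
print.split_cv <- function(x, ...) {
  cat("Split-half cross-validation (n = ", x$n, ", halves ",
      length(x$idx_a), "/", x$n - length(x$idx_a), ")\n", sep = "")
  for (h in names(x$halves)) {
    r <- x$halves[[h]]
    if (!is.null(r$error)) {
      cat("  half ", h, ": derivation failed (", r$error, ")\n", sep = "")
    } else {
      cat(sprintf("  half %s: in-sample c = %.3f, out-of-sample c = %.3f\n",
                  h, r$c_in, r$c_out))
    }
  }
  invisible(x)
}

## internal: c-index and R2s of one fitted logistic model
model_metrics <- function(fit) {
  n <- length(fit$y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- ll1 - (fit$null.deviance - fit$deviance) / 2
  r2 <- logistic_r2(ll0, ll1, n)
  list(c_index = c_index(stats::fitted(fit), fit$y),
       r2_generalized = r2$r2_generalized,
       r2_max_rescaled = r2$r2_max_rescaled,
       converged = fit$converged, n = n)
}

#' Compare the score against reference logistic models
#'
#' Fits, on the complete cases of the six score variables, (1) the total
#' score as a single continuous predictor, (2) age + APACHE II + SOFA as
#' continuous predictors, (3) all six score variables as continuous
#' predictors, and (4) the five variables excluding any acute-inflammation
#' marker (no IL-6), and reports c-index and both R-squared statistics for
#' each.
#'
#' @param cohort Cohort data.frame.
#' @param table Point table used for the total score (default the published
#'   table).
#' @return A data.frame, one row per model.
#' @export
compare_models <- function(cohort, table = nutric_points_table()) {
  vars <- c("age", "apache2", "sofa", "n_comorbid", "days_hosp_to_icu", "il6")
  vars <- intersect(vars, names(cohort))
  rows <- stats::complete.cases(cohort[, vars, drop = FALSE]) &
    !is.na(cohort$mort28)
  d <- cohort[rows, , drop = FALSE]
  d$score <- total_score(table, d, missing = "na")
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  specs <- list(
    score_single_predictor = mort28 ~ score,
    age_apache_sofa = mort28 ~ age + apache2 + sofa,
    all_six_variables = stats::reformulate(vars, response = "mort28"),
    no_acute_inflammation = stats::reformulate(setdiff(vars, "il6"),
                                               response = "mort28")
  )
  out <- do.call(rbind, lapply(names(specs), function(m) {
    fit <- suppressWarnings(stats::glm(specs[[m]], data = d,
                                       family = stats::binomial(),
                                       control = ctrl))
    met <- model_metrics(fit)
    data.frame(model = m, c_index = met$c_index,
               r2_generalized = met$r2_generalized,
               r2_max_rescaled = met$r2_max_rescaled,
               converged = met$converged, n = met$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Validate a scoring table on a cohort
#'
#' Full validation report for a point table (by default the published one):
#' discrimination (c-index of the total score, Cox-Snell and Nagelkerke R2 of
#' the logistic model with the score as a continuous predictor), calibration
#' (observed vs model-predicted mortality per score value, Hosmer-Lemeshow
#' test), collinearity (VIF across the six component variables), split-half
#' cross-validation, and the comparison models.
#'
#' @param cohort Cohort data.frame.
#' @param table Point table (default [nutric_points_table()]).
#' @param seed Seed for the split-half partition.
#' @param g Hosmer-Lemeshow group count.
#' @param split Run split-half cross-validation (default `TRUE`; requires
#'   n >= 100).
#' @return List of class `nutric_validation`.
#' @export
validate_score <- function(cohort, table = nutric_points_table(), seed = 1,
                           g = 10, split = TRUE) {
  scores <- total_score(table, cohort, missing = "na")
  rows <- !is.na(scores) & !is.na(cohort$mort28)
  s <- scores[rows]; y <- cohort$mort28[rows]
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit <- stats::glm(y ~ s, family = stats::binomial(), control = ctrl)
  met <- model_metrics(fit)
  pred <- stats::fitted(fit)
  calibration <- do.call(rbind, lapply(sort(unique(s)), function(v) {
    data.frame(score = v, n = sum(s == v),
               observed = mean(y[s == v]),
               predicted = stats::plogis(sum(stats::coef(fit) * c(1, v))))
  }))
  hl <- tryCatch(hosmer_lemeshow(pred, y, g = g), error = identity)
  vars <- intersect(c("age", "apache2", "sofa", "n_comorbid",
                      "days_hosp_to_icu", "il6"), names(cohort))
  vrows <- stats::complete.cases(cohort[, vars, drop = FALSE])
  vifs <- tryCatch(vif(cohort[vrows, vars, drop = FALSE]), error = identity)
  cv <- if (split && nrow(cohort) >= 100) {
    tryCatch(split_half_cv(cohort, seed = seed), error = identity)
  }
  comparison <- tryCatch(compare_models(cohort, table), error = identity)
  structure(
    list(c_index = met$c_index, r2_generalized = met$r2_generalized,
         r2_max_rescaled = met$r2_max_rescaled,
         hl = hl, calibration = calibration, vif = vifs, split = cv,
         comparison = comparison, n = length(s), seed = seed,
         score_model_coef = unname(stats::coef(fit))),
    class = "nutric_validation"
  )
}

#' @export
print.nutric_validation <- function(x, ...) {
  cat("Score validation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  c-index: %.3f\n", x$c_index))
  cat(sprintf("  generalized R2: %.3f  max-rescaled R2: %.3f\n",
              x$r2_generalized, x$r2_max_rescaled))
  if (inherits(x$hl, "hl_test")) {
    cat(sprintf("  Hosmer-Lemeshow: X2 = %.2f (df %d), p = %.3f\n",
                x$hl$statistic, x$hl$df, x$hl$p))
  }
  if (is.numeric(x$vif)) {
    cat("  max VIF:", format(max(x$vif), digits = 3), "(",
        names(x$vif)[which.max(x$vif)], ")\n")
  }
  if (inherits(x$split, "split_cv")) print(x$split)
  if (is.data.frame(x$comparison)) {
    cat("  comparison models:\n")
    cm <- x$comparison
    for (i in seq_len(nrow(cm))) {
      cat(sprintf("    %-24s c = %.3f\n", cm$model[i], cm$c_index[i]))
    }
  }
  invisible(x)
}
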