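#' Single-predictor categorical logistic fit
#'
#' Fits 28-day mortality on one categorized predictor by maximum likelihood
#' (stats::glm, IRLS, log-likelihood tolerance 1e-8, at most 100 iterations).
#' Because the predictor is saturated-categorical, the fitted logit of
#' category k relative to the first category equals
#' `log(d_k/s_k) - log(d_1/s_1)` where `d`, `s` are death/survivor counts;
#' that closed form is the internal oracle the fit is tested against.
#' Categories with zero deaths or zero survivors get a `+Inf`/`-Inf` logit and
#' a sparse flag instead of a diverged coefficient.
#'
#' @param index 1-based category index per patient (or a
#'   `categorized_variable`).
#' @param mort28 Binary outcome vector (1 = dead by day 28).
#' @param name Variable name for reporting.
#' @return An object of class `category_fit`: `logits` (first category = 0),
#'   `se`, `overall_p` (likelihood-ratio test against intercept-only),
#'   `loglik`, `loglik_null`, `deaths`, `survivors`, `sparse`, `n`.
#' @export
fit_category_logit <- function(index, mort28, name = NULL) {
  if (inherits(index, "categorized_variable")) {
    if (is.null(name)) name <- index$name
    index <- index$index
  }
  if (is.null(name)) name <- "variable"
  keep <- !is.na(index) & !is.na(mort28)
  index <- as.integer(index[keep])
  y <- mort28[keep]
  k <- max(index)
  tot <- tabulate(index, nbins = k)
  if (any(tot == 0)) {
    stop("category ", which(tot == 0)[1], " of ", name,
         " has zero deaths and zero survivors")
  }
  deaths <- vapply(seq_len(k), function(j) sum(y[index == j] == 1), numeric(1))
  survivors <- tot - deaths
  if (k < 2) stop("need at least 2 categories to fit ", name)
  sparse <- deaths == 0 | survivors == 0
  f <- factor(index, levels = seq_len(k))
  fit <- suppressWarnings(stats::glm(
    y ~ f, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  logits <- c(0, unname(stats::coef(fit)[-1]))
  se <- c(0, unname(sqrt(diag(stats::vcov(fit)))[-1]))
  if (any(sparse)) {
    logits[sparse & deaths == 0] <- -Inf
    logits[sparse & survivors == 0] <- Inf
    se[sparse] <- Inf
  }
  lrt <- fit$null.deviance - fit$deviance
  structure(
    list(variable = name, k = k, logits = logits, se = se,
         deaths = deaths, survivors = survivors, sparse = sparse,
         loglik = as.numeric(stats::logLik(fit)),
         loglik_null = as.numeric(stats::logLik(fit)) - lrt / 2,
         overall_p = stats::pchisq(lrt, df = k - 1, lower.tail = FALSE),
         n = length(y)),
    class = "category_fit"
  )
}

#' @export
print.category_fit <- function(x, ...) {
  cat("Categorical logistic fit:", x$variable, "\n")
  tab <- data.frame(category = seq_len(x$k), deaths = x$deaths,
                    survivors = x$survivors,
                    logit = round(x$logits, 3), se = round(x$se, 3))
  print(tab, row.names = FALSE)
  cat("overall p (LRT, df ", x$k - 1, "): ", format.pval(x$overall_p),
      if (any(x$sparse)) "  [sparse categories flagged]", "\n", sep = "")
  invisible(x)
}

#' Convert per-category logits to integer points
#'
#' Re-references the logits so the minimum-logit (lowest-risk) category is the
#' reference with 0 points, then rounds half away from zero. Points are
#' therefore always non-negative integers.
#'
#' @param fit A `category_fit` (or a numeric vector of logits).
#' @return Integer vector of points, one per category.
#' @export
assign_points <- function(fit) {
  logits <- if (inherits(fit, "category_fit")) fit$logits else fit
  if (any(!is.finite(logits))) {
    stop("non-finite logits; resolve sparse categories (merge with the ",
         "adjacent category) before assigning points")
  }
  as.integer(round_half_away(logits - min(logits)))
}

## internal: merge a sparse category with the adjacent category closer in raw
## value (for quintile/integer variables: the neighbouring category), then
## refit, until all logits are finite or only one category remains
resolve_sparse_fit <- function(catvar, mort28) {
  index <- catvar$index
  boundaries <- catvar$boundaries
  k <- catvar$k
  repeat {
    fit <- fit_category_logit(index, mort28, name = catvar$name)
    if (!any(fit$sparse) || fit$k <= 2) {
      return(list(fit = fit, index = index, boundaries = boundaries, k = k))
    }
    j <- which(fit$sparse)[1]
    # merge with the adjacent category whose boundary is nearer in raw value
    into <- if (j == 1) 2L else if (j == k) k - 1L else {
      widths <- diff(c(-Inf, boundaries, Inf))
      if (widths[j - 1] <= widths[j + 1]) j - 1L else j + 1L
    }
    lo <- min(j, into); hi <- max(j, into)
    index[index == hi] <- lo
    index[index > hi] <- index[index > hi] - 1L
    boundaries <- boundaries[-lo]
    k <- k - 1L
  }
}

#' Collapse equal-point categories and round boundaries
#'
#' Adjacent categories sharing a point value are merged (interval union); each
#' retained interior boundary is then snapped to a convenient value
#' ([snap_convenient()]), provided snapping keeps the boundaries strictly
#' increasing. A snap that would reorder or merge distinct-point categories
#' falls back to the exact boundary with a warning. Exact boundaries are kept
#' in the `exact_boundaries` attribute.
#'
#' @param catvar A `categorized_variable` (interval kinds: quintile/integer) .
#' @param points Integer points per category, as from [assign_points()].
#' @param rel_tol Relative tolerance for boundary snapping (default 0.05).
#' @return A data.frame of table entries: `variable`, `label`, `lower`,
#'   `upper`, `points`, `kind`.
#' @export
collapse_and_round <- function(catvar, points, rel_tol = 0.05) {
  stopifnot(inherits(catvar, "categorized_variable"))
  k <- length(points)
  if (catvar$kind %in% c("quintile", "integer")) {
    stopifnot(length(catvar$boundaries) == k - 1)
    runs <- rle(points)
    kk <- length(runs$values)
    upper_idx <- cumsum(runs$lengths)         # last original category per run
    exact <- catvar$boundaries[upper_idx[-kk]]  # retained interior boundaries
    snapped <- vapply(exact, snap_convenient, numeric(1), rel_tol = rel_tol)
    ok <- length(snapped) == 0 ||
      all(diff(snapped) > 0) && all(is.finite(snapped))
    if (!ok) {
      warning("boundary snapping would reorder cut-points for ", catvar$name,
              "; keeping exact boundaries")
      snapped <- exact
    }
    lower <- c(-Inf, snapped)
    upper <- c(snapped, Inf)
    integer_valued <- catvar$kind == "integer"
    labels <- mapply(interval_label, lower, upper,
                     MoreArgs = list(integer_valued = integer_valued))
    out <- data.frame(
      variable = catvar$name, label = labels, lower = lower, upper = upper,
      points = runs$values, kind = "interval", stringsAsFactors = FALSE
    )
    attr(out, "exact_boundaries") <- exact
  } else {
    # dichotomous rule-based variables: nothing to collapse or snap unless
    # both categories share a point value
    if (points[1] == points[2]) {
      out <- data.frame(variable = catvar$name, label = "ALL",
                        lower = -Inf, upper = Inf, points = points[1],
                        kind = catvar$kind, stringsAsFactors = FALSE)
    } else {
      out <- data.frame(variable = catvar$name, label = catvar$labels,
                        lower = c(1, 2), upper = c(2, 3), points = points,
                        kind = catvar$kind, stringsAsFactors = FALSE)
    }
    attr(out, "exact_boundaries") <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Assemble a point table
#'
#' A `nutric_table` holds the final integer-points scoring table: one row per
#' (variable, category) with half-open interval bounds `[lower, upper)` and
#' non-negative points. The total score of a patient is the sum of the
#' matched points across variables.
#'
#' @param entries A data.frame with columns `variable`, `label`, `lower`,
#'   `upper`, `points`, `kind` (rbind of [collapse_and_round()] outputs).
#' @return An object of class `nutric_table`.
#' @export
nutric_table <- function(entries) {
  stopifnot(all(c("variable", "label", "lower", "upper", "points", "kind")
                %in% names(entries)))
  if (any(entries$points < 0)) stop("points must be non-negative")
  vars <- unique(entries$variable)
  max_total <- sum(vapply(vars, function(v) {
    max(entries$points[entries$variable == v])
  }, numeric(1)))
  min_total <- sum(vapply(vars, function(v) {
    min(entries$points[entries$variable == v])
  }, numeric(1)))
  structure(
    list(entries = entries, variables = vars,
         total_range = c(min_total, max_total)),
    class = "nutric_table"
  )
}

#' @export
print.nutric_table <- function(x, ...) {
  cat("Integer-points scoring table (total range ",
      x$total_range[1], "-", x$total_range[2], ")\n\n", sep = "")
  e <- x$entries
  for (v in x$variables) {
    rows <- e[e$variable == v, ]
    cat(v, "\n")
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("  %-14s %d\n", rows$label[i], rows$points[i]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.nutric_table <- function(x, ...) x$entries

## internal: points for one variable of a table given raw values, NA if the
## value is missing (interval kind) or unmatchable
score_variable <- function(entries, values, sensitivity = FALSE) {
  kind <- entries$kind[1]
  if (kind == "interval") {
    idx <- findInterval(values, c(entries$lower[1], entries$upper))
    idx[idx == 0 | idx > nrow(entries)] <- NA_integer_
    pts <- entries$points[idx]
    pts[is.na(values)] <- NA
    return(pts)
  }
  cat2 <- switch(kind,
    dichotomous = , bmi = dichotomize_bmi(values)$index,
    oral_intake_pct = dichotomize_oral_intake(values, sensitivity)$index,
    weight_loss_pct = dichotomize_weight_loss(values, sensitivity)$index,
    stop("unknown table kind: ", kind)
  )
  if (nrow(entries) == 1) return(rep(entries$points[1], length(values)))
  entries$points[cat2]
}

#' Total score under a point table
#'
#' Sums the per-variable points of each patient. By default a missing value in
#' any table variable is a scoring error naming the variable; with
#' `missing = "na"` such patients score `NA`; with `missing = "drop_variable"`
#' a wholly absent optional variable (e.g. IL-6) contributes 0 points for
#' patients missing it.
#'
#' @param table A `nutric_table`.
#' @param data Data.frame containing the table's variables as columns.
#' @param missing Missing-value policy: `"error"`, `"na"`, or
#'   `"drop_variable"`.
#' @return Integer vector of total scores.
#' @export
total_score <- function(table, data,
                        missing = c("error", "na", "drop_variable")) {
  missing <- match.arg(missing)
  stopifnot(inherits(table, "nutric_table"))
  n <- nrow(data)
  total <- rep(0, n)
  has_na <- rep(FALSE, n)
  for (v in table$variables) {
    if (!v %in% names(data)) stop("scoring error: variable '", v,
                                  "' not present in data")
    entries <- table$entries[table$entries$variable == v, ]
    special <- entries$kind[1] %in% c("oral_intake_pct", "weight_loss_pct",
                                      "bmi", "dichotomous")
    pts <- score_variable(entries, data[[v]])
    if (anyNA(pts)) {
      if (missing == "error" && !special) {
        stop("scoring error: missing value for variable '", v, "' (row ",
             which(is.na(pts))[1], ")")
      }
      if (missing == "drop_variable") {
        pts[is.na(pts)] <- 0
      } else {
        has_na <- has_na | is.na(pts)
        pts[is.na(pts)] <- 0
      }
    }
    total <- total + pts
  }
  total[has_na] <- NA
  as.integer(total)
}

#' Derive an integer-points mortality risk score from a cohort
#'
#' The fitting function of the package. Runs the full derivation pipeline on
#' per-patient data: (1) categorize each candidate (quintiles for continuous
#' variables, integer categories for the comorbidity count, fixed
#' dichotomizations for BMI, oral intake and weight loss); (2) fit each
#' categorized candidate in a separate single-predictor logistic regression of
#' 28-day mortality and convert the re-referenced log odds ratios to integer
#' points; (3) exclude candidates with overall likelihood-ratio p > `p_max` or
#' with all categories assigned 0 points; (4) a greedy backward pass (weakest
#' candidate first) drops any variable whose inclusion does not improve the
#' total score's c-index by more than `improvement_tol`; (5) collapse
#' equal-point categories and round the surviving boundaries to convenient
#' values.
#'
#' @param data Cohort data.frame with a `mort28` column (see
#'   [cohort_columns()]).
#' @param candidates Candidate variables (default [nutric_candidates()]).
#' @param p_max Overall-significance exclusion threshold (default 0.2).
#' @param improvement_tol Minimum c-index gain for a variable to be kept in
#'   the backward pass (default 0.001).
#' @param sensitivity Recode unreported oral intake / weight loss as abnormal.
#' @param rel_tol Boundary-snapping tolerance, see [collapse_and_round()].
#' @return An object of class `nutric_derivation` with components `fits`
#'   (per-candidate `category_fit`), `points` (per-candidate integer points on
#'   the fitted categories), `included`, `excluded` (data.frame with reasons),
#'   `table` (the final [nutric_table()]), `categorized`, `n`, `call`.
#'   Methods: [print.nutric_derivation()], [summary.nutric_derivation()],
#'   [coef.nutric_derivation()], [predict.nutric_derivation()].
#' @export
derive_score <- function(data, candidates = nutric_candidates(),
                         p_max = 0.2, improvement_tol = 0.001,
                         sensitivity = FALSE, rel_tol = 0.05) {
  cl <- match.call()
  if (!"mort28" %in% names(data)) stop("data must contain mort28")
  y <- data$mort28
  candidates <- intersect(candidates, names(data))
  if (!length(candidates)) stop("no candidate variables present in data")
  categorized <- categorize_cohort(data, candidates, sensitivity = sensitivity)

  fits <- list(); points <- list()
  for (v in candidates) {
    res <- resolve_sparse_fit(categorized[[v]], y)
    categorized[[v]]$index <- res$index
    categorized[[v]]$boundaries <- res$boundaries
    categorized[[v]]$k <- res$k
    categorized[[v]]$counts <- tabulate(res$index, nbins = res$k)
    fits[[v]] <- res$fit
    points[[v]] <- assign_points(res$fit)
  }

  excluded <- data.frame(variable = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  exclude <- function(v, reason) {
    excluded <<- rbind(excluded, data.frame(variable = v, reason = reason,
                                            stringsAsFactors = FALSE))
  }

  ## phase 1: overall significance and all-zero points
  included <- character(0)
  for (v in candidates) {
    if (fits[[v]]$overall_p > p_max) {
      exclude(v, sprintf("overall significance %.3f > %.2f",
                         fits[[v]]$overall_p, p_max))
    } else if (all(points[[v]] == 0)) {
      exclude(v, "all categories assigned 0 points")
    } else {
      included <- c(included, v)
    }
  }
  if (!length(included)) stop("empty score: all candidates excluded")

  ## phase 2: greedy backward pass, weakest (largest overall p) first; drop a
  ## variable if the total score's c-index does not increase by more than
  ## improvement_tol when it is included
  pts_matrix <- vapply(candidates, function(v) {
    p <- points[[v]][categorized[[v]]$index]
    p[is.na(categorized[[v]]$index)] <- NA
    as.numeric(p)
  }, numeric(nrow(data)))
  order_p <- included[order(vapply(included, function(v) fits[[v]]$overall_p,
                                   numeric(1)), decreasing = TRUE)]
  for (v in order_p) {
    if (length(included) == 1) break
    keep <- included
    rows <- stats::complete.cases(pts_matrix[, keep, drop = FALSE]) & !is.na(y)
    with_v <- rowSums(pts_matrix[rows, keep, drop = FALSE])
    without_v <- rowSums(pts_matrix[rows, setdiff(keep, v), drop = FALSE])
    gain <- c_index(with_v, y[rows]) - c_index(without_v, y[rows])
    if (gain <= improvement_tol) {
      exclude(v, sprintf(
        "no discrimination improvement (c-index gain %.4f <= %.4f)",
        gain, improvement_tol))
      included <- setdiff(included, v)
    }
  }

  entries <- do.call(rbind, lapply(included, function(v) {
    collapse_and_round(categorized[[v]], points[[v]], rel_tol = rel_tol)
  }))
  table <- nutric_table(entries)

  ## in-sample scores and a logistic calibration of mortality on the total
  ## score (used by predict(type = "response") and by validate_score)
  scores <- total_score(table, data, missing = "na")
  rows <- !is.na(scores) & !is.na(y)
  calibration <- stats::glm(y[rows] ~ scores[rows],
                            family = stats::binomial(),
                            control = stats::glm.control(epsilon = 1e-8,
                                                         maxit = 100))
  structure(
    list(fits = fits, points = points, included = included,
         excluded = excluded, table = table, categorized = categorized,
         scores = scores, calibration_coef = unname(stats::coef(calibration)),
         n = nrow(data), sensitivity = sensitivity, call = cl),
    class = "nutric_derivation"
  )
}

#' @export
print.nutric_derivation <- function(x, ...) {
  cat("Derived nutrition risk score (n = ", x$n, ")\n", sep = "")
  cat("Included: ", paste(x$included, collapse = ", "), "\n", sep = "")
  if (nrow(x$excluded)) {
    cat("Excluded:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat("  ", x$excluded$variable[i], ": ", x$excluded$reason[i], "\n",
          sep = "")
    }
  }
  cat("\n")
  print(x$table)
  invisible(x)
}

#' @describeIn derive_score Per-candidate fit summary: overall p, points,
#'   inclusion status.
#' @param object,x A `nutric_derivation`.
#' @param ... Unused.
#' @export
summary.nutric_derivation <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$fits), function(v) {
    f <- object$fits[[v]]
    data.frame(
      variable = v, categories = f$k,
      overall_p = f$overall_p,
      points = paste(object$points[[v]], collapse = "/"),
      status = if (v %in% object$included) "included" else "excluded",
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  structure(list(fits = tab, excluded = object$excluded,
                 table = object$table, n = object$n),
            class = "summary.nutric_derivation")
}

#' @export
print.summary.nutric_derivation <- function(x, ...) {
  cat("Score derivation on n =", x$n, "patients\n\n")
  tab <- x$fits
  tab$overall_p <- format.pval(tab$overall_p, digits = 3)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$table)
  invisible(x)
}

#' @describeIn derive_score The final point table as a data.frame.
#' @export
coef.nutric_derivation <- function(object, ...) {
  object$table$entries
}

#' @describeIn derive_score Total score (or fitted mortality probability) for
#'   new patients under the derived table.
#' @param newdata Data.frame of patients to score.
#' @param type `"score"` for the integer total; `"response"` for the fitted
#'   28-day mortality probability from a logistic calibration of the
#'   derivation data on the total score.
#' @param missing Missing-value policy passed to [total_score()].
#' @export
predict.nutric_derivation <- function(object, newdata, type = c("score",
                                                                "response"),
                                      missing = "na", ...) {
  type <- match.arg(type)
  scores <- total_score(object$table, newdata, missing = missing)
  if (type == "score") return(scores)
  b <- object$calibration_coef
  stats::plogis(b[1] + b[2] * scores)
}
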