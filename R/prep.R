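#' Categorize a continuous variable into quintiles
#'
#' Cut-points are the empirical 20/40/60/80th percentiles (type-7 linear
#' interpolation). Intervals are half-open `[a, b)`, the last closed above by
#' +Inf, so ties straddling a cut-point all fall in the lower category.
#' Duplicate cut-points caused by heavy ties are collapsed, reducing the
#' number of categories.
#'
#' @param values Numeric vector (missing values allowed; they receive an `NA`
#'   category index).
#' @param name Variable name carried through to the score table.
#' @return An object of class `categorized_variable`: list with `name`,
#'   `kind = "quintile"`, `boundaries` (interior cut-points), `index`
#'   (1-based category per observation), `k`, `counts`.
#' @export
quintile_bin <- function(values, name = deparse(substitute(values))) {
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < 5) {
    stop("categorization error: fewer than 5 distinct non-missing values; ",
         "dichotomize this variable instead")
  }
  boundaries <- unique(unname(stats::quantile(obs, probs = c(.2, .4, .6, .8),
                                              type = 7)))
  index <- findInterval(values, boundaries) + 1L
  index[is.na(values)] <- NA_integer_
  k <- length(boundaries) + 1L
  structure(
    list(name = name, kind = "quintile", boundaries = boundaries,
         index = index, k = k,
         counts = tabulate(index, nbins = k)),
    class = "categorized_variable"
  )
}

## internal constructor for two-level categorized variables
dichotomous_variable <- function(name, index, labels, boundaries = numeric(0),
                                 kind = "dichotomous") {
  structure(
    list(name = name, kind = kind, boundaries = boundaries,
         index = index, k = 2L, labels = labels,
         counts = tabulate(index, nbins = 2L)),
    class = "categorized_variable"
  )
}

#' Dichotomize body mass index at 20 kg/m2
#'
#' `low` iff BMI is reported and `< 20`; BMI of exactly 20, higher, or missing
#' maps to `other`. (The missing-to-`other` rule is this implementation's
#' extension, consistent with how unreported nutrition-history variables are
#' grouped with the non-exposed category; it is flagged in the categorization
#' manifest.)
#'
#' @param bmi Numeric vector of BMI values, `NA` allowed.
#' @return A `categorized_variable` with levels `low` (category 2, the risk
#'   category) and `other` (category 1, reference).
#' @export
dichotomize_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("invariant error: bmi <= 0")
  index <- ifelse(!is.na(bmi) & bmi < 20, 2L, 1L)
  dichotomous_variable("bmi", index, labels = c("other", "low (< 20)"),
                       boundaries = 20, kind = "bmi")
}

#' Dichotomize reported oral intake in the week prior
#'
#' Default rule: `reduced` iff the variable is reported and `< 100`%; everyone
#' else - including patients without the variable reported - is
#' `full_or_unknown`. In sensitivity mode, missing values are assumed to be
#' reduced intake.
#'
#' @param pct Numeric vector in `[0, 100]`, `NA` allowed.
#' @param sensitivity Recode missing as reduced (default `FALSE`).
#' @return A `categorized_variable`; category 2 is `reduced`.
#' @export
dichotomize_oral_intake <- function(pct, sensitivity = FALSE) {
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("invariant error: oral_intake_pct outside [0, 100]")
  }
  reduced <- (!is.na(pct) & pct < 100) | (is.na(pct) & sensitivity)
  dichotomous_variable("oral_intake_pct", ifelse(reduced, 2L, 1L),
                       labels = c("full_or_unknown", "reduced (< 100%)"),
                       kind = "oral_intake_pct")
}

#' Dichotomize reported weight loss in the past three months
#'
#' Default rule: `any_loss` iff reported and `> 0`; zero reported loss and
#' unreported both map to `none_or_unknown`. In sensitivity mode, missing
#' values are assumed to represent weight loss.
#'
#' @param pct Numeric vector `>= 0`, `NA` allowed.
#' @param sensitivity Recode missing as any_loss (default `FALSE`).
#' @return A `categorized_variable`; category 2 is `any_loss`.
#' @export
dichotomize_weight_loss <- function(pct, sensitivity = FALSE) {
  if (any(pct < 0, na.rm = TRUE)) {
    stop("invariant error: weight_loss_pct < 0")
  }
  loss <- (!is.na(pct) & pct > 0) | (is.na(pct) & sensitivity)
  dichotomous_variable("weight_loss_pct", ifelse(loss, 2L, 1L),
                       labels = c("none_or_unknown", "any_loss"),
                       kind = "weight_loss_pct")
}

#' Categorize the comorbidity count
#'
#' The number of comorbidities is kept as integer categories 0-5 (no quintile
#' binning); categories observed in the data become the fit levels.
#'
#' @param n_comorbid Integer vector in 0-5.
#' @return A `categorized_variable` of kind `"integer"`.
#' @export
integer_categories <- function(n_comorbid) {
  if (any(n_comorbid < 0 | n_comorbid > 5 |
            n_comorbid != round(n_comorbid), na.rm = TRUE)) {
    stop("invariant error: n_comorbid not an integer in 0-5")
  }
  index <- as.integer(n_comorbid) + 1L
  k <- max(index, na.rm = TRUE)
  structure(
    list(name = "n_comorbid", kind = "integer",
         boundaries = seq_len(k - 1L),  # cut at 1, 2, ... on the raw scale
         index = index, k = k, counts = tabulate(index, nbins = k)),
    class = "categorized_variable"
  )
}

#' @export
print.categorized_variable <- function(x, ...) {
  cat("Categorized variable:", x$name, "(", x$kind, ")\n")
  cat("  categories:", x$k, " boundaries:",
      paste(format(x$boundaries, digits = 4), collapse = ", "), "\n")
  cat("  counts:", paste(x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' Compare a candidate variable between survivors and non-survivors
#'
#' Categorical variables are described as counts and percentages and compared
#' by the Pearson chi-square test (no continuity correction); continuous
#' variables are described as medians and IQRs and compared by the two-sided
#' Wilcoxon rank-sum test (average-rank ties, normal approximation).
#'
#' @param x The variable (numeric, factor, or a `categorized_variable`).
#' @param group Binary grouping vector (e.g. `mort28`).
#' @param type `"auto"` treats factors/categorized variables and vectors with
#'   few distinct values as categorical.
#' @return A list of class `group_comparison` with `test`, `statistic`, `p`,
#'   and per-group summaries.
#' @export
compare_groups <- function(x, group, type = c("auto", "continuous",
                                              "categorical")) {
  type <- match.arg(type)
  if (inherits(x, "categorized_variable")) {
    lab <- if (!is.null(x$labels)) x$labels else paste0("cat", seq_len(x$k))
    x <- factor(lab[x$index], levels = lab)
    if (type == "auto") type <- "categorical"
  }
  keep <- !is.na(x) & !is.na(group)
  x <- x[keep]; group <- group[keep]
  g <- unique(group)
  if (length(g) < 2) stop("need two non-empty groups")
  if (length(g) > 2) stop("group must be binary")
  if (type == "auto") {
    type <- if (is.factor(x) || is.character(x)) "categorical" else "continuous"
  }
  if (type == "categorical") {
    tab <- table(x, group)
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    pctab <- prop.table(tab, margin = 2) * 100
    out <- list(test = "chi-square", statistic = unname(tst$statistic),
                df = unname(tst$parameter), p = tst$p.value,
                counts = tab, percentages = pctab)
  } else {
    x <- as.numeric(x)
    tst <- stats::wilcox.test(x ~ group, exact = FALSE, correct = FALSE)
    summ <- t(vapply(split(x, group), function(v) {
      q <- stats::quantile(v, c(.25, .5, .75), type = 7)
      c(n = length(v), q25 = unname(q[1]), median = unname(q[2]),
        q75 = unname(q[3]))
    }, numeric(4)))
    out <- list(test = "wilcoxon", statistic = unname(tst$statistic),
                p = tst$p.value, summary = summ)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$test, "): statistic = ",
      format(x$statistic, digits = 4), ", p = ", format.pval(x$p), "\n",
      sep = "")
  if (!is.null(x$summary)) print(round(x$summary, 2)) else print(x$counts)
  invisible(x)
}

#' Categorize every candidate predictor of a cohort
#'
#' Applies the reparameterization used for score derivation: quintiles for
#' age, APACHE II, SOFA, days from hospital to ICU, IL-6, CRP and PCT;
#' integer categories for the comorbidity count; and the dichotomizations for
#' BMI, oral intake and weight loss (with optional sensitivity recoding of
#' the two nutrition-history variables).
#'
#' @param cohort Cohort data.frame.
#' @param candidates Character vector of candidate variables to categorize.
#' @param sensitivity Assume unreported oral intake / weight loss are abnormal.
#' @return Named list of `categorized_variable` objects.
#' @export
categorize_cohort <- function(cohort, candidates = nutric_candidates(),
                              sensitivity = FALSE) {
  out <- list()
  for (v in candidates) {
    out[[v]] <- switch(
      v,
      n_comorbid = integer_categories(cohort$n_comorbid),
      bmi = dichotomize_bmi(cohort$bmi),
      oral_intake_pct = dichotomize_oral_intake(cohort$oral_intake_pct,
                                                sensitivity),
      weight_loss_pct = dichotomize_weight_loss(cohort$weight_loss_pct,
                                                sensitivity),
      quintile_bin(cohort[[v]], name = v)
    )
  }
  out
}

#' Candidate predictor sets
#'
#' `nutric_candidates()` lists all eleven candidate variables considered for
#' the score; `nutric_score_variables()` lists the six retained in the final
#' published table.
#'
#' @return Character vector of canonical column names.
#' @export
nutric_candidates <- function() {
  c("age", "apache2", "sofa", "days_hosp_to_icu", "n_comorbid", "bmi",
    "il6", "crp", "pct", "oral_intake_pct", "weight_loss_pct")
}

#' @rdname nutric_candidates
#' @export
nutric_score_variables <- function() {
  c("age", "apache2", "sofa", "n_comorbid", "days_hosp_to_icu", "il6")
}

#' Categorization manifest
#'
#' Summarizes a list of categorized variables (one row per variable) for the
#' run report: kind, number of categories, boundaries and per-category counts.
#'
#' @param categorized Named list from [categorize_cohort()].
#' @return A data.frame.
#' @export
categorization_manifest <- function(categorized) {
  do.call(rbind, lapply(categorized, function(cv) {
    data.frame(
      variable = cv$name, kind = cv$kind, k = cv$k,
      boundaries = paste(format(cv$boundaries, digits = 6, trim = TRUE),
                         collapse = "; "),
      counts = paste(cv$counts, collapse = "; "),
      stringsAsFactors = FALSE
    )
  }))
}
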