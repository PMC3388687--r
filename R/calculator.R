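#' The published NUTRIC point table
#'
#' The fixed scoring table (overall-cohort column): age (< 50 -> 0, 50-< 75
#' -> 1, >= 75 -> 2), APACHE II (< 15 -> 0, 15-< 20 -> 1, 20-< 28 -> 2,
#' >= 28 -> 3), SOFA (< 6 -> 0, 6-< 10 -> 1, >= 10 -> 2), comorbidities
#' (0-1 -> 0, >= 2 -> 1), days from hospital to ICU admission (< 1 -> 0,
#' >= 1 -> 1) and IL-6 (< 400 -> 0, >= 400 -> 1). All bands are half-open
#' `[a, b)`; in particular an APACHE II of exactly 28 scores 3 points (the
#' printed "20-28" and ">= 28" bands overlap at 28; the half-open convention
#' used by every other band is applied). Totals range 0-10, or 0-9 when IL-6
#' is omitted.
#'
#' @param with_il6 Include the IL-6 row (default `TRUE`).
#' @return A [nutric_table()].
#' @export
nutric_points_table <- function(with_il6 = TRUE) {
  entries <- data.frame(
    variable = c(rep("age", 3), rep("apache2", 4), rep("sofa", 3),
                 rep("n_comorbid", 2), rep("days_hosp_to_icu", 2),
                 rep("il6", 2)),
    label = c("< 50", "50-< 75", "75+",
              "< 15", "15-< 20", "20-< 28", "28+",
              "< 6", "6-< 10", "10+",
              "0-1", "2+",
              "0-< 1", "1+",
              "0-< 400", "400+"),
    lower = c(-Inf, 50, 75, -Inf, 15, 20, 28, -Inf, 6, 10, -Inf, 2,
              -Inf, 1, -Inf, 400),
    upper = c(50, 75, Inf, 15, 20, 28, Inf, 6, 10, Inf, 2, Inf,
              1, Inf, 400, Inf),
    points = c(0, 1, 2, 0, 1, 2, 3, 0, 1, 2, 0, 1, 0, 1, 0, 1),
    kind = "interval",
    stringsAsFactors = FALSE
  )
  if (!with_il6) entries <- entries[entries$variable != "il6", ]
  nutric_table(entries)
}

#' Compute the NUTRIC score for one or more patients
#'
#' Scores patients with the fixed published table ([nutric_points_table()]).
#' When `il6` is `NA` for a patient, the IL-6 row is omitted entirely for that
#' patient (IL-6-optional variant, maximum 9 instead of 10); dropping IL-6
#' never increases a score.
#'
#' @param age Years (>= 18).
#' @param apache2 Baseline APACHE II score.
#' @param sofa Baseline SOFA score.
#' @param n_comorbid Number of comorbidities (0-5).
#' @param days_hosp_to_icu Days from hospital admission to ICU admission;
#'   "1+" means >= 1.0 day including fractions.
#' @param il6 Serum IL-6 in pg/mL, or `NA` if not available.
#' @return Integer vector of total scores in `[0, 10]` (`[0, 9]` without
#'   IL-6).
#' @examples
#' nutric_score(age = 63, apache2 = 21, sofa = 7, n_comorbid = 3,
#'              days_hosp_to_icu = 0.4, il6 = 100)  # 5
#' @export
nutric_score <- function(age, apache2, sofa, n_comorbid, days_hosp_to_icu,
                         il6 = NA) {
  args <- list(age = age, apache2 = apache2, sofa = sofa,
               n_comorbid = n_comorbid, days_hosp_to_icu = days_hosp_to_icu)
  for (v in names(args)) {
    if (anyNA(args[[v]])) stop("invariant error: missing ", v)
    if (any(args[[v]] < 0)) stop("invariant error: negative ", v)
  }
  if (any(il6 < 0, na.rm = TRUE)) stop("invariant error: negative il6")
  data <- data.frame(args, il6 = il6)
  base <- total_score(nutric_points_table(with_il6 = FALSE), data)
  il6_pts <- ifelse(is.na(il6), 0L, ifelse(il6 >= 400, 1L, 0L))
  as.integer(base + il6_pts)
}

#' Score a whole cohort with the published table
#'
#' Computes the per-patient NUTRIC score and the distribution of score values.
#' Rows with a missing required field are skipped (score `NA`) and logged in
#' the result.
#'
#' @param cohort Cohort data.frame.
#' @param with_il6 Use the IL-6 row (default `TRUE`); when `TRUE`, patients
#'   with missing IL-6 are scored on the remaining five variables.
#' @return A list of class `nutric_scores`: `scores` (per patient),
#'   `distribution` (counts per score value 0..max), `skipped` (row indices
#'   with missing required fields).
#' @export
score_cohort <- function(cohort, with_il6 = TRUE) {
  table <- nutric_points_table(with_il6 = with_il6)
  if (with_il6 && !"il6" %in% names(cohort)) {
    table <- nutric_points_table(with_il6 = FALSE)
    with_il6 <- FALSE
  }
  required <- setdiff(table$variables, "il6")
  miss_req <- Reduce(`|`, lapply(required, function(v) is.na(cohort[[v]])))
  scores <- rep(NA_integer_, nrow(cohort))
  rows <- !miss_req
  if (with_il6) {
    data <- cohort[rows, , drop = FALSE]
    base <- total_score(nutric_points_table(with_il6 = FALSE), data)
    il6_pts <- ifelse(is.na(data$il6), 0L, ifelse(data$il6 >= 400, 1L, 0L))
    scores[rows] <- base + il6_pts
  } else {
    scores[rows] <- total_score(table, cohort[rows, , drop = FALSE])
  }
  max_score <- table$total_range[2] + if (with_il6) 0 else 0
  distribution <- table(factor(scores, levels = 0:max(10, max_score)))
  skipped <- which(miss_req)
  if (length(skipped)) {
    message("score_cohort: skipped ", length(skipped),
            " row(s) with missing required fields")
  }
  structure(list(scores = scores, distribution = distribution,
                 skipped = skipped, with_il6 = with_il6),
            class = "nutric_scores")
}

#' @export
print.nutric_scores <- function(x, ...) {
  cat("Cohort scores (", sum(!is.na(x$scores)), " scored, ",
      length(x$skipped), " skipped)\n", sep = "")
  print(x$distribution)
  invisible(x)
}
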