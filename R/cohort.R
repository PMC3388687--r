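#' Column dictionary for patient-level cohort files
#'
#' One row per canonical column of a cohort CSV. `energy_received_daily` is a
#' per-day list of kcal values stored in a single CSV cell, separated by `";"`
#' (one value per ICU day, up to 14). Missing values are written as empty
#' fields, never as zero.
#'
#' @return A data.frame with columns `name`, `type`, `units`, `required`,
#'   `description`.
#' @export
cohort_columns <- function() {
  dict <- rbind(
    c("patient_id", "character", "", TRUE, "Opaque patient identifier"),
    c("age", "numeric", "years", TRUE, "Age at ICU admission (>= 18)"),
    c("apache2", "integer", "points", TRUE, "Baseline APACHE II score (>= 0)"),
    c("sofa", "integer", "points", TRUE, "Baseline SOFA score (>= 0)"),
    c("days_hosp_to_icu", "numeric", "days", TRUE,
      "Days from hospital admission to ICU admission (>= 0, fractional)"),
    c("bmi", "numeric", "kg/m2", FALSE, "Body mass index (> 0, may be missing)"),
    c("n_comorbid", "integer", "count", TRUE, "Number of comorbidities (0-5)"),
    c("il6", "numeric", "pg/mL", FALSE, "Serum interleukin-6 (> 0, may be missing)"),
    c("crp", "numeric", "mg/L", FALSE, "C-reactive protein (> 0, may be missing)"),
    c("pct", "numeric", "ng/mL", FALSE, "Procalcitonin (> 0, may be missing)"),
    c("oral_intake_pct", "numeric", "%", FALSE,
      "Estimated % oral intake in the week prior (0-100, may be missing)"),
    c("weight_loss_pct", "numeric", "%", FALSE,
      "% weight loss in the last three months (>= 0, may be missing)"),
    c("mort28", "integer", "0/1", TRUE, "28-day mortality (1 = dead by day 28)"),
    c("mv_start_within_48h", "integer", "0/1", FALSE,
      "Mechanical ventilation started within 48 h of ICU admission"),
    c("mv_days", "numeric", "days", TRUE, "Days on mechanical ventilation (0-28)"),
    c("icu_days", "numeric", "days", TRUE, "ICU length of stay (>= 0)"),
    c("energy_prescribed", "numeric", "kcal/day", FALSE,
      "Daily energy prescription from the baseline assessment (> 0)"),
    c("energy_received_daily", "list", "kcal", FALSE,
      "Semicolon-separated daily kcal received, one per ICU day up to 14")
  )
  out <- data.frame(
    name = dict[, 1], type = dict[, 2], units = dict[, 3],
    required = as.logical(dict[, 4]), description = dict[, 5],
    stringsAsFactors = FALSE
  )
  out
}

required_cohort_columns <- function() {
  d <- cohort_columns()
  d$name[d$required]
}

#' Validate a cohort data frame against the patient-record invariants
#'
#' Hard invariants: `age >= 18`, `n_comorbid` an integer in 0-5,
#' `0 <= mv_days <= 28`, non-negative `days_hosp_to_icu` and `icu_days`,
#' `mort28` in {0, 1}, positive `bmi`/`il6`/`crp`/`pct` where present,
#' `oral_intake_pct` in [0, 100], non-negative `weight_loss_pct`, and (where
#' daily energy is recorded) `length(energy_received_daily) ==
#' min(ceiling(icu_days), 14)`.
#'
#' @param cohort A data.frame of patient records.
#' @param action `"error"` (default) stops listing every violating row;
#'   `"drop"` removes violating rows with a warning.
#' @return The validated (possibly reduced) cohort, invisibly classed
#'   `"nutric_cohort"`.
#' @export
validate_cohort <- function(cohort, action = c("error", "drop")) {
  action <- match.arg(action)
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(required_cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(cohort)
  problems <- character(0)
  bad <- logical(n)
  note <- function(rows, msg) {
    rows <- which(rows)
    if (length(rows)) {
      bad[rows] <<- TRUE
      problems <<- c(problems, paste0("row ", rows, ": ", msg))
    }
  }
  ok <- function(x) !is.na(x)
  note(ok(cohort$age) & cohort$age < 18, "age < 18")
  note(is.na(cohort$age), "age missing")
  note(ok(cohort$apache2) & cohort$apache2 < 0, "apache2 < 0")
  note(ok(cohort$sofa) & cohort$sofa < 0, "sofa < 0")
  note(ok(cohort$n_comorbid) &
         (cohort$n_comorbid < 0 | cohort$n_comorbid > 5 |
            cohort$n_comorbid != round(cohort$n_comorbid)),
       "n_comorbid not an integer in 0-5")
  note(ok(cohort$days_hosp_to_icu) & cohort$days_hosp_to_icu < 0,
       "days_hosp_to_icu < 0")
  note(ok(cohort$mv_days) & (cohort$mv_days < 0 | cohort$mv_days > 28),
       "mv_days outside [0, 28]")
  note(ok(cohort$icu_days) & cohort$icu_days < 0, "icu_days < 0")
  note(!cohort$mort28 %in% c(0, 1), "mort28 not 0/1")
  for (v in c("bmi", "il6", "crp", "pct")) {
    if (v %in% names(cohort)) {
      note(ok(cohort[[v]]) & cohort[[v]] <= 0, paste0(v, " <= 0"))
    }
  }
  if ("oral_intake_pct" %in% names(cohort)) {
    note(ok(cohort$oral_intake_pct) &
           (cohort$oral_intake_pct < 0 | cohort$oral_intake_pct > 100),
         "oral_intake_pct outside [0, 100]")
  }
  if ("weight_loss_pct" %in% names(cohort)) {
    note(ok(cohort$weight_loss_pct) & cohort$weight_loss_pct < 0,
         "weight_loss_pct < 0")
  }
  if ("energy_prescribed" %in% names(cohort)) {
    note(ok(cohort$energy_prescribed) & cohort$energy_prescribed <= 0,
         "energy_prescribed <= 0")
  }
  if ("energy_received_daily" %in% names(cohort)) {
    len <- vapply(cohort$energy_received_daily,
                  function(e) if (is.null(e) || all(is.na(e))) NA_integer_
                  else length(e), integer(1))
    expected <- pmin(ceiling(cohort$icu_days), 14)
    note(!is.na(len) & ok(cohort$icu_days) & len != expected,
         "length(energy_received_daily) != min(ceiling(icu_days), 14)")
  }
  if (length(problems)) {
    if (action == "error") {
      stop("cohort invariant violation(s):\n  ",
           paste(problems, collapse = "\n  "))
    }
    warning("dropping ", sum(bad), " row(s) violating invariants:\n  ",
            paste(problems, collapse = "\n  "))
    cohort <- cohort[!bad, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  class(cohort) <- unique(c("nutric_cohort", class(cohort)))
  invisible(cohort)
}

#' Read a patient cohort from a delimited text file
#'
#' Reads a CSV (UTF-8, header row) of one row per patient, applies an optional
#' schema mapping from file column names to the canonical names of
#' [cohort_columns()], parses the `energy_received_daily` list column
#' (values separated by `";"` within the cell), coerces numeric columns with
#' row/column-named parse errors, and checks the record invariants.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to file column names (e.g. `c(age = "AgeYears")`), or the path to
#'   a YAML file containing such a mapping.
#' @param na Strings interpreted as missing (default empty field and `"NA"`).
#' @param action Passed to [validate_cohort()].
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path, schema = NULL, na = c("", "NA"),
                        action = c("error", "drop")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = na, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(raw)) {
        stop("schema error: column '", file_col, "' (mapped to '", canon,
             "') not found in ", path)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  dict <- cohort_columns()
  missing_cols <- setdiff(required_cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw
  for (v in intersect(dict$name[dict$type %in% c("numeric", "integer")],
                      names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(is.na(parsed) & !is.na(raw[[v]]))
    if (length(bad)) {
      stop("parse error: non-numeric value in column '", v, "', row ",
           bad[1], ": '", raw[[v]][bad[1]], "'")
    }
    out[[v]] <- parsed
  }
  if ("energy_received_daily" %in% names(raw)) {
    out$energy_received_daily <- lapply(raw$energy_received_daily, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      vals <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
      if (anyNA(vals)) stop("parse error: non-numeric daily energy value: ", s)
      vals
    })
  }
  validate_cohort(out, action = action)
}

#' Write a patient cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: the list column `energy_received_daily` is
#' serialized with `";"` separators and full precision, missing values become
#' empty fields. `read_cohort(write_cohort(x))` reproduces `x` bit-exactly for
#' integer-valued fields and to better than 1e-9 for reals.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  class(out) <- "data.frame"
  if ("energy_received_daily" %in% names(out)) {
    out$energy_received_daily <- vapply(out$energy_received_daily, function(e) {
      if (is.null(e) || all(is.na(e))) return("")
      paste(format(e, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ";")
    }, character(1))
  }
  num <- vapply(out, is.numeric, logical(1))
  for (v in names(out)[num]) {
    out[[v]] <- ifelse(is.na(out[[v]]), "",
                       format(out[[v]], digits = 15, trim = TRUE,
                              scientific = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Ventilator-free days within 28 days
#'
#' VFD = 28 - min(mv_days, 28) for 28-day survivors. The source data do not
#' define VFD for decedents; the common convention VFD = 0 for 28-day
#' non-survivors is the default and is configurable via `death_vfd`.
#'
#' @param mv_days Days on mechanical ventilation (0-28), vector.
#' @param mort28 28-day mortality indicator (0/1), vector.
#' @param death_vfd VFD value assigned to non-survivors (default 0).
#' @return Integer-valued vector of VFD in `[0, 28]`.
#' @export
compute_vfd <- function(mv_days, mort28, death_vfd = 0) {
  if (any(mv_days < 0, na.rm = TRUE)) stop("invariant error: mv_days < 0")
  stopifnot(length(mv_days) == length(mort28))
  ifelse(mort28 == 1, death_vfd, 28 - pmin(mv_days, 28))
}
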