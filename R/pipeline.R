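#' Run the full analysis pipeline
#'
#' Ties the stages together: simulate (or load) a cohort, categorize the
#' candidate variables, derive the score, validate it, and run the outcome
#' analyses, writing a consolidated plain-text report and CSV/JSON artifacts
#' to an output directory. All randomness flows from the single configured
#' seed, so two runs with an equal configuration produce byte-identical
#' artifacts (wall-clock timings go to the console log only, never into
#' files). A stage failure is logged and its dependent stages are skipped.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `input` (path to a cohort CSV; `NULL` to simulate), `synthetic` (named
#'   overrides for [synthetic_config()]), `seed`, `stages` (logical toggles
#'   `simulate`, `prep`, `derive`, `validate`, `outcomes`), `sensitivity`,
#'   `tolerances` (`improvement`, `boundary_rel_tol`), `out_dir`.
#' @return Invisibly, a list of class `nutric_report` with per-stage results
#'   and a `failed` character vector of failed stage names.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    input = NULL, synthetic = list(), seed = 1,
    stages = list(simulate = TRUE, prep = TRUE, derive = TRUE,
                  validate = TRUE, outcomes = TRUE),
    sensitivity = FALSE,
    tolerances = list(improvement = 0.001, boundary_rel_tol = 0.05),
    out_dir = NULL
  )
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  config <- defaults
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, obj) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      if (grepl("\\.csv$", name)) {
        utils::write.csv(obj, path, row.names = FALSE)
      } else if (grepl("\\.json$", name)) {
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                             pretty = TRUE)
      } else {
        writeLines(obj, path)
      }
    }
  }
  results <- list(config = config)
  failed <- character(0)
  warnings_log <- character(0)
  stage <- function(name, deps, expr) {
    if (!isTRUE(config$stages[[name]]) && name %in% names(config$stages)) {
      message("stage ", name, ": disabled")
      return(NULL)
    }
    if (length(intersect(deps, failed))) {
      message("stage ", name, ": skipped (failed dependency)")
      failed <<- c(failed, name)
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        message("stage ", name, ": FAILED (", conditionMessage(e), ")")
        failed <<- c(failed, name)
        NULL
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    message(sprintf("stage %s: %.2f s", name, proc.time()[["elapsed"]] - t0))
    out
  }

  ## cohort: simulate or load
  cohort <- if (is.null(config$input)) {
    stage("simulate", character(0), {
      sc <- do.call(synthetic_config,
                    c(list(seed = config$seed), config$synthetic))
      x <- simulate_cohort(sc)
      if (!is.null(out_dir)) write_cohort(x, file.path(out_dir, "cohort.csv"))
      emit("provenance.yaml", yaml::as.yaml(list(
        seed = config$seed, n = sc$n,
        effect_mode = sc$outcome$effect_mode,
        per_point_logodds = sc$outcome$per_point_logodds,
        target_rate = sc$outcome$target_rate
      )))
      x
    })
  } else {
    stage("load", character(0), read_cohort(config$input))
  }
  if (is.null(cohort)) failed <- union(failed, "cohort")
  results$n <- if (!is.null(cohort)) nrow(cohort)

  results$prep <- stage("prep", "cohort", {
    categorized <- categorize_cohort(cohort, sensitivity = config$sensitivity)
    manifest <- categorization_manifest(categorized)
    emit("categorization_manifest.csv", manifest)
    manifest
  })

  results$derivation <- stage("derive", "cohort", {
    der <- derive_score(cohort, sensitivity = config$sensitivity,
                        improvement_tol = config$tolerances$improvement,
                        rel_tol = config$tolerances$boundary_rel_tol)
    emit("derived_table.csv", der$table$entries)
    der
  })

  results$validation <- stage("validate", "cohort", {
    val <- validate_score(cohort, seed = config$seed)
    emit("validation.json", list(
      c_index = val$c_index, r2_generalized = val$r2_generalized,
      r2_max_rescaled = val$r2_max_rescaled,
      hl_statistic = if (inherits(val$hl, "hl_test")) val$hl$statistic,
      hl_p = if (inherits(val$hl, "hl_test")) val$hl$p,
      max_vif = if (is.numeric(val$vif)) max(val$vif),
      split_out_of_sample_c = if (inherits(val$split, "split_cv")) {
        lapply(val$split$halves, function(h) h$c_out)
      }
    ))
    emit("calibration.csv", val$calibration)
    val
  })

  results$outcomes <- stage("outcomes", "cohort", {
    scored <- score_cohort(cohort)
    vfd <- compute_vfd(cohort$mv_days, cohort$mort28)
    sp <- spearman_test(scored$scores, vfd)
    surv <- !is.na(scored$scores) & cohort$mort28 == 0
    mv <- mv_duration_model(scored$scores[surv], cohort$mv_days[surv])
    adq <- adequacy(cohort)
    elig <- adq$eligible & !is.na(scored$scores)
    inter <- interaction_test(adq$pct_received[elig], scored$scores[elig],
                              cohort$mort28[elig])
    emit("interaction_curves.csv", inter$curves)
    emit("outcomes.json", list(
      spearman_score_vfd = list(rho = sp$rho, p = sp$p, n = sp$n),
      mv_duration = list(slope = mv$slope, slope_p = mv$slope_p,
                         lack_of_fit_p = mv$lof_p),
      interaction = list(coefficient = unname(inter$coefficients[["a:s"]]),
                         lrt_statistic = inter$lrt_statistic,
                         lrt_p = inter$lrt_p, n = inter$n)
    ))
    list(scores = scored, spearman = sp, mv = mv, adequacy = adq,
         interaction = inter)
  })

  results$failed <- failed
  results$warnings <- warnings_log

  report <- c(
    "Nutrition risk score pipeline report",
    paste0("seed: ", config$seed),
    paste0("patients: ", results$n),
    "",
    if (!is.null(results$prep)) c(
      "== Categorization ==",
      utils::capture.output(print(results$prep)), ""),
    if (!is.null(results$derivation)) c(
      "== Derived score ==",
      utils::capture.output(print(results$derivation)), ""),
    if (!is.null(results$validation)) c(
      "== Validation ==",
      utils::capture.output(print(results$validation)), ""),
    if (!is.null(results$outcomes)) c(
      "== Outcomes ==",
      utils::capture.output(print(results$outcomes$scores)),
      sprintf("Spearman(score, VFD): rho = %.3f (p = %s, n = %d)",
              results$outcomes$spearman$rho,
              format.pval(results$outcomes$spearman$p),
              results$outcomes$spearman$n),
      utils::capture.output(print(results$outcomes$mv)),
      utils::capture.output(print(results$outcomes$interaction)), ""),
    if (length(warnings_log)) c("== Warnings ==", warnings_log),
    if (length(failed)) c("== FAILED STAGES ==", failed)
  )
  emit("report.txt", report)
  results$report <- report
  class(results) <- "nutric_report"
  invisible(results)
}

#' @export
print.nutric_report <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}
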