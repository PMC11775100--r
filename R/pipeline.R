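#' Run the full simulate-to-decline pipeline
#'
#' Orchestrates the stages in dependency order: simulate (or accept provided
#' inputs) -> QC of raw eMR creatinine -> same-year pairing and per-year bias
#' estimation -> bias table with proxy factors -> correction -> eGFR
#' derivation -> cohort assembly and censoring -> annual-decline estimation
#' with risk-factor regressions and the peri-AKI analysis. All randomness
#' comes from `config$seed`; re-running with the same configuration
#' reproduces every number.
#'
#' @param config A [synthetic_config()] describing the simulated inputs, or
#'   `NULL` when `data` is supplied.
#' @param data Optional list with elements `covariates`, `sc_records`,
#'   `emr_records`, `events` (as produced by [simulate_dataset()] or the
#'   [records_io] readers) to run on real inputs instead of simulating.
#' @param qc A [qc_config()].
#' @param bias_correction Set `FALSE` to skip the correction (the
#'   uncorrected-versus-corrected contrast).
#' @param winsorize Winsorize log values at mean ± 3 SD before bias
#'   estimation.
#' @param min_pairs Minimum same-year pairs to estimate a year's factor.
#' @param unity_threshold Closeness to 1 at which trailing years get no
#'   correction.
#' @param out_dir Optional directory; when given, all outputs are written as
#'   TSV with a run manifest.
#' @return List: `qc_report`, `pairs`, `bias_estimates`, `bias_table`,
#'   `assessments`, `censored`, `declines`, `decline_summary`, `regressions`
#'   (tidied coefficient tables), `peri_aki` (NULL when too few qualifying
#'   persons), `summary`, `manifest` (NULL unless `out_dir` given).
#' @export
run_pipeline <- function(config = synthetic_config(), data = NULL,
                         qc = qc_config(), bias_correction = TRUE,
                         winsorize = FALSE, min_pairs = 100,
                         unity_threshold = 0.05, out_dir = NULL) {
  if (is.null(data)) {
    data <- simulate_dataset(config)
  }
  for (el in c("covariates", "sc_records", "emr_records", "events")) {
    if (is.null(data[[el]])) abort(sprintf("Input `%s` is missing.", el))
  }

  qc_res <- qc_emr_creatinine(data$emr_records, qc)
  emr_ok <- qc_passed(qc_res$records)
  sc_ok <- data$sc_records

  pairs <- pair_same_year(sc_ok, emr_ok)
  estimates <- estimate_year_bias(pairs, winsorize = winsorize,
                                  min_pairs = min_pairs)
  all_years <- range(as.integer(format(
    c(sc_ok$exam_date, emr_ok$exam_date), "%Y")))
  bias_table <- build_bias_table(estimates, year_range = all_years,
                                 unity_threshold = unity_threshold)

  emr_corr <- if (bias_correction) {
    apply_bias_correction(emr_ok, bias_table)
  } else {
    dplyr::mutate(emr_ok, value_raw = .data$value, correction_factor = 1,
                  bias_corrected = FALSE)
  }

  sc_assess <- derive_egfr(sc_ok, data$covariates)
  emr_assess <- derive_egfr(emr_corr, data$covariates)
  assessments <- merge_by_person_date(sc_assess, emr_assess)
  censored <- censor_for_decline(assessments, data$events)

  declines <- annual_decline(censored)
  decline_summary <- mean_decline_ci(declines)
  regressions <- purrr::map(
    rlang::set_names(names(REGRESSION_SPECS)),
    function(m) {
      fit <- tryCatch(decline_regression(declines, data$covariates, m),
                      error = function(e) NULL)
      if (is.null(fit)) NULL else dplyr::mutate(tidy(fit), model = m)
    }
  ) |> purrr::compact() |> purrr::list_rbind()
  peri <- tryCatch(aki_peri_decline(assessments, data$events),
                   error = function(e) NULL)
  cohort_summary <- descriptive_summary(assessments, data$covariates)

  manifest <- NULL
  if (!is.null(out_dir)) {
    outputs <- list(
      qc_report = qc_res$report,
      bias_table = as.data.frame(bias_table),
      corrected_records = emr_corr,
      assessments = assessments,
      declines = declines,
      decline_summary = decline_summary,
      regressions = regressions,
      cohort_summary = cohort_summary
    )
    if (!is.null(peri)) outputs$peri_aki <- peri
    manifest <- write_outputs(outputs, out_dir,
                              seed = if (is.null(config)) NA_integer_
                                     else config$seed,
                              config = config)
  }

  list(qc_report = qc_res$report, pairs = pairs, bias_estimates = estimates,
       bias_table = bias_table, assessments = assessments,
       censored = censored, declines = declines,
       decline_summary = decline_summary, regressions = regressions,
       peri_aki = peri, summary = cohort_summary, manifest = manifest)
}
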