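#' Merge SC and eMR eGFR assessments by person and date
#'
#' Combines the two assessment sources into one chronologically ordered
#' table. Same-date SC and eMR assessments are both kept (they are distinct
#' measurements from distinct sources); exact duplicates within a
#' (person, date, source) triple are collapsed to the first.
#'
#' @param sc_assessments,emr_assessments Assessment tibbles from
#'   [derive_egfr()].
#' @return Assessment tibble sorted by person and date.
#' @export
merge_by_person_date <- function(sc_assessments, emr_assessments) {
  dplyr::bind_rows(sc_assessments, emr_assessments) |>
    dplyr::distinct(.data$person_id, .data$exam_date, .data$source,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$person_id, .data$exam_date, .data$source)
}

#' Per-person trajectory eligibility flags
#'
#' @param assessments Merged assessment tibble.
#' @return One row per person: `n_assessments`, `span_years` (first to last),
#'   `ge2` (at least two assessments), `ge2_1yr` (at least two, at least one
#'   year apart), `ge10`, `gp_member` (has at least one eMR assessment).
#' @export
trajectory_flags <- function(assessments) {
  assessments |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_assessments = dplyr::n(),
      span_years = as_years(max(.data$exam_date) - min(.data$exam_date)),
      ge2 = dplyr::n() >= 2,
      ge2_1yr = dplyr::n() >= 2 &
        as.numeric(max(.data$exam_date) - min(.data$exam_date)) >= 365,
      ge10 = dplyr::n() >= 10,
      gp_member = any(.data$source == "eMR"),
      .groups = "drop"
    )
}

KIDNEY_CENSOR_CATEGORIES <- c("AKI", "ESKD", "dialysis", "transplant",
                              "nephrectomy")

#' Censor assessments for decline estimation
#'
#' Removes assessments that no longer reflect native kidney-function decline:
#' everything strictly after the earliest of (a) the person's first severe
#' kidney event (AKI, ESKD, dialysis, transplant, nephrectomy) and (b) the
#' first assessment with eGFR < 15 (that triggering assessment itself is
#' retained — it defines onset); plus every assessment within ±183 days of a
#' pregnancy event. Diabetes events never censor (covariate annotation only).
#' The result is always a subsequence of the input.
#'
#' @param assessments Merged assessment tibble.
#' @param events Diagnostic-event tibble from [read_events()].
#' @param pregnancy_window_days Half-width of the pregnancy exclusion window
#'   (default 183 days ~ 6 months).
#' @return Censored assessment tibble.
#' @export
censor_for_decline <- function(assessments, events,
                               pregnancy_window_days = 183) {
  cutoff_event <- events |>
    dplyr::filter(.data$category %in% KIDNEY_CENSOR_CATEGORIES) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(event_cutoff = suppressWarnings(min(.data$event_date)),
                     .groups = "drop")
  cutoff_low <- assessments |>
    dplyr::filter(.data$egfr < 15) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(low_cutoff = suppressWarnings(min(.data$exam_date)),
                     .groups = "drop")
  preg <- events |>
    dplyr::filter(.data$category == "pregnancy") |>
    dplyr::select("person_id", preg_date = "event_date")

  out <- assessments |>
    dplyr::left_join(cutoff_event, by = "person_id") |>
    dplyr::left_join(cutoff_low, by = "person_id") |>
    dplyr::mutate(cutoff = pmin(.data$event_cutoff, .data$low_cutoff,
                                na.rm = TRUE)) |>
    dplyr::filter(is.na(.data$cutoff) | .data$exam_date <= .data$cutoff) |>
    dplyr::select(-"event_cutoff", -"low_cutoff", -"cutoff")

  if (nrow(preg) > 0) {
    in_window <- out |>
      dplyr::inner_join(preg, by = "person_id",
                        relationship = "many-to-many") |>
      dplyr::filter(abs(as.numeric(.data$exam_date - .data$preg_date)) <=
                      pregnancy_window_days) |>
      dplyr::distinct(.data$person_id, .data$exam_date, .data$source)
    out <- dplyr::anti_join(out, in_window,
                            by = c("person_id", "exam_date", "source"))
  }
  out
}

summary_stats_row <- function(stratum, assessments, covariates) {
  ids <- unique(assessments$person_id)
  cov <- dplyr::filter(covariates, .data$person_id %in% ids)
  if (nrow(assessments) == 0) {
    # avoid dplyr's zero-row prototype evaluation of the summaries below
    return(tibble::tibble(
      stratum = stratum, n_persons = 0L, m_assessments = 0L,
      mean_age_first = NA_real_, sd_age_first = NA_real_,
      pct_female = NA_real_, pct_smoking = NA_real_, mean_bmi = NA_real_,
      pct_diabetes = NA_real_, mean_egfr_first = NA_real_,
      mean_egfr_last = NA_real_, pct_ckd_ever = NA_real_,
      median_span_years = NA_real_, max_span_years = NA_real_,
      median_n_assessments = NA_real_, iqr_lo_n_assessments = NA_real_,
      iqr_hi_n_assessments = NA_real_
    ))
  }
  per <- assessments |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      egfr_first = .data$egfr[which.min(.data$exam_date)],
      egfr_last = .data$egfr[which.max(.data$exam_date)],
      ckd_ever = any(.data$ckd),
      span_years = as_years(max(.data$exam_date) - min(.data$exam_date)),
      n_assess = dplyr::n(),
      age_first = .data$age_at_exam[which.min(.data$exam_date)],
      .groups = "drop"
    )
  n <- length(ids)
  na_if_empty <- function(x) if (n == 0) NA_real_ else x
  tibble::tibble(
    stratum = stratum,
    n_persons = n,
    m_assessments = nrow(assessments),
    mean_age_first = na_if_empty(mean(per$age_first)),
    sd_age_first = na_if_empty(sd(per$age_first)),
    pct_female = na_if_empty(100 * mean(cov$sex == 0, na.rm = TRUE)),
    pct_smoking = na_if_empty(100 * mean(cov$smoking, na.rm = TRUE)),
    mean_bmi = na_if_empty(mean(cov$bmi, na.rm = TRUE)),
    pct_diabetes = na_if_empty(100 * mean(cov$diabetes, na.rm = TRUE)),
    mean_egfr_first = na_if_empty(mean(per$egfr_first)),
    mean_egfr_last = na_if_empty(mean(per$egfr_last)),
    pct_ckd_ever = na_if_empty(100 * mean(per$ckd_ever)),
    median_span_years = na_if_empty(median(per$span_years)),
    max_span_years = na_if_empty(if (n == 0) NA_real_ else max(per$span_years)),
    median_n_assessments = na_if_empty(median(per$n_assess)),
    iqr_lo_n_assessments = na_if_empty(unname(quantile(per$n_assess, 0.25))),
    iqr_hi_n_assessments = na_if_empty(unname(quantile(per$n_assess, 0.75)))
  )
}

#' Descriptive summary of the assembled cohort by stratum
#'
#' One row per stratum — all persons, those with >= 2 assessments, >= 10
#' assessments, GP-clinical members (>= 1 eMR assessment) and non-members —
#' with the cohort characteristics used to assess selection: n, mean (SD) age
#' at first exam, % female, % ever-smoking, mean BMI, % diabetes, mean eGFR at
#' first and last exam, % ever-CKD, median (max) assessment span, and
#' median \[IQR\] assessments per person.
#'
#' @param assessments Merged assessment tibble.
#' @param covariates Covariate tibble from [read_covariates()].
#' @return Summary tibble, one row per stratum.
#' @export
descriptive_summary <- function(assessments, covariates) {
  flags <- trajectory_flags(assessments)
  sub <- function(keep) {
    dplyr::semi_join(assessments, dplyr::filter(flags, {{ keep }}),
                     by = "person_id")
  }
  dplyr::bind_rows(
    summary_stats_row("all", assessments, covariates),
    summary_stats_row("ge2", sub(.data$ge2), covariates),
    summary_stats_row("ge10", sub(.data$ge10), covariates),
    summary_stats_row("gp_member", sub(.data$gp_member), covariates),
    summary_stats_row("not_gp_member", sub(!.data$gp_member), covariates)
  )
}

#' Diagnostic-event counts before versus after the first assessment
#'
#' For each stratum and event category, counts persons with at least one
#' event strictly before their first eGFR assessment and at least one on/after
#' it (a person can appear in both columns). Mirrors how recorded
#' kidney-relevant codes are summarised relative to trajectory start.
#'
#' @param assessments Merged assessment tibble.
#' @param events Diagnostic-event tibble.
#' @return Tibble: `stratum`, `category`, `n_before`, `n_after`.
#' @export
event_split_summary <- function(assessments, events) {
  first_exam <- assessments |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_date = min(.data$exam_date), .groups = "drop")
  flags <- trajectory_flags(assessments)
  ev <- events |>
    dplyr::inner_join(first_exam, by = "person_id") |>
    dplyr::mutate(when = ifelse(.data$event_date < .data$first_date,
                                "before", "after"))
  one_stratum <- function(stratum, ids) {
    ev |>
      dplyr::filter(.data$person_id %in% ids) |>
      dplyr::distinct(.data$person_id, .data$category, .data$when) |>
      dplyr::count(.data$category, .data$when) |>
      tidyr::pivot_wider(names_from = "when", values_from = "n",
                         names_prefix = "n_", values_fill = 0) |>
      dplyr::mutate(stratum = stratum, .before = 1)
  }
  out <- dplyr::bind_rows(
    one_stratum("gp_member", flags$person_id[flags$gp_member]),
    one_stratum("ge2", flags$person_id[flags$ge2 & flags$gp_member]),
    one_stratum("ge10", flags$person_id[flags$ge10 & flags$gp_member])
  )
  for (col in c("n_before", "n_after")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out
}
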