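#' Person-specific annualized eGFR decline
#'
#' The two-point estimator: decline = (eGFR at first assessment - eGFR at
#' last assessment) / years between them, so a positive value means falling
#' kidney function. A person is eligible when, after censoring, at least two
#' assessments remain with first and last at least one year (365 days)
#' apart. Intermediate assessments do not enter the estimate.
#'
#' @param assessments Censored assessment tibble
#'   (see [censor_for_decline()]).
#' @param min_span_days Minimum first-to-last span for eligibility
#'   (default 365).
#' @return One row per person: `person_id`, `n_assessments`, `first_date`,
#'   `last_date`, `span_years`, `egfr_first`, `egfr_last`, `age_first`,
#'   `decline` (mL/min/1.73m^2 per year; NA when ineligible), `eligible`,
#'   `reason` (`"eligible"`, `"single_assessment"`, `"span_lt_1yr"`).
#' @export
annual_decline <- function(assessments, min_span_days = 365) {
  assessments |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_assessments = dplyr::n(),
      first_date = min(.data$exam_date),
      last_date = max(.data$exam_date),
      egfr_first = .data$egfr[which.min(.data$exam_date)],
      egfr_last = .data$egfr[which.max(.data$exam_date)],
      age_first = .data$age_at_exam[which.min(.data$exam_date)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      span_years = as_years(.data$last_date - .data$first_date),
      eligible = .data$n_assessments >= 2 &
        as.numeric(.data$last_date - .data$first_date) >= min_span_days,
      reason = dplyr::case_when(
        .data$n_assessments < 2 ~ "single_assessment",
        !.data$eligible ~ "span_lt_1yr",
        TRUE ~ "eligible"
      ),
      decline = ifelse(.data$eligible,
                       (.data$egfr_first - .data$egfr_last) / .data$span_years,
                       NA_real_)
    )
}

#' Cohort mean annual decline with 95% confidence interval
#'
#' Arithmetic mean of the eligible per-person declines with a normal-
#' approximation interval, mean ± 1.96 · SD/sqrt(n).
#'
#' @param declines Tibble from [annual_decline()] (or a numeric vector of
#'   per-person declines).
#' @return One-row tibble: `mean_decline`, `ci_low`, `ci_high`, `n_persons`,
#'   `m_assessments` (NA when assessment counts are unavailable).
#' @export
mean_decline_ci <- function(declines) {
  if (is.numeric(declines)) {
    d <- declines[!is.na(declines)]
    m_assess <- NA_integer_
  } else {
    el <- dplyr::filter(declines, .data$eligible)
    d <- el$decline
    m_assess <- sum(el$n_assessments)
  }
  n <- length(d)
  if (n < 2) abort("At least two eligible persons are required.")
  se <- sd(d) / sqrt(n)
  tibble::tibble(
    mean_decline = mean(d),
    ci_low = mean(d) - 1.96 * se,
    ci_high = mean(d) + 1.96 * se,
    n_persons = n,
    m_assessments = m_assess
  )
}

REGRESSION_SPECS <- list(
  genetic = c("age40", "sex", "variant_dosage"),
  lifestyle = c("age40", "sex", "smoking", "obesity", "diabetes")
)

#' Risk-factor regression on annual eGFR decline
#'
#' Ordinary least squares of per-person annual decline on a fixed covariate
#' set, with intercept. Two models are predefined: `"genetic"` (age at first
#' assessment centered at 40, sex, allele dosage of the decline-associated
#' variant) and `"lifestyle"` (age centered at 40, sex, ever-smoking, obesity
#' = BMI >= 30, diabetes). Persons with any missing covariate are dropped
#' (listwise deletion). A covariate with zero variance or a rank-deficient
#' design raises an error naming the offending columns.
#'
#' @param declines Tibble from [annual_decline()].
#' @param covariates Tibble from [read_covariates()].
#' @param model `"genetic"` or `"lifestyle"`.
#' @return A `decline_reg` object; see [tidy.decline_reg()] /
#'   [glance.decline_reg()].
#' @export
decline_regression <- function(declines, covariates,
                               model = c("genetic", "lifestyle")) {
  model <- match.arg(model)
  terms <- REGRESSION_SPECS[[model]]
  df <- declines |>
    dplyr::filter(.data$eligible) |>
    dplyr::inner_join(covariates, by = "person_id") |>
    dplyr::mutate(
      age40 = .data$age_first - 40,
      obesity = as.numeric(.data$bmi >= 30)
    ) |>
    dplyr::select("person_id", "decline", "n_assessments",
                  dplyr::all_of(terms)) |>
    dplyr::filter(complete.cases(dplyr::pick(dplyr::everything())))
  if (nrow(df) <= length(terms) + 1) {
    abort("Too few complete cases for the regression.")
  }
  const <- terms[purrr::map_lgl(terms, ~ length(unique(df[[.x]])) < 2)]
  if (length(const) > 0) {
    abort(sprintf("Covariate%s %s ha%s zero variance in the analysis sample.",
                  if (length(const) > 1) "s" else "",
                  paste0("`", const, "`", collapse = ", "),
                  if (length(const) > 1) "ve" else "s"))
  }
  form <- stats::reformulate(terms, response = "decline")
  mm <- model.matrix(form, data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(sprintf("Rank-deficient design: collinear column%s %s.",
                  if (length(dropped) > 1) "s" else "",
                  paste0("`", dropped, "`", collapse = ", ")))
  }
  fit <- lm(form, data = df)
  structure(
    list(fit = fit, model = model, terms = terms,
         n_persons = nrow(df), m_assessments = sum(df$n_assessments)),
    class = "decline_reg"
  )
}

#' @describeIn decline_regression Coefficients as a tibble with
#'   normal-approximation 95% intervals (beta ± 1.96 · SE).
#' @param x A `decline_reg` object.
#' @param ... Unused.
#' @export
tidy.decline_reg <- function(x, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(suppressWarnings(vcov(x$fit))))
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - 1.96 * se),
    conf.high = unname(est + 1.96 * se)
  )
}

#' @describeIn decline_regression One-row model summary.
#' @export
glance.decline_reg <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))  # zero-residual fits are legitimate
  tibble::tibble(model = x$model, n_persons = x$n_persons,
                 m_assessments = x$m_assessments,
                 r.squared = s$r.squared, sigma = s$sigma)
}

#' @export
print.decline_reg <- function(x, ...) {
  cat(sprintf("Annual eGFR decline regression (%s model), n = %d persons, m = %d assessments\n",
              x$model, x$n_persons, x$m_assessments))
  print(tidy(x))
  invisible(x)
}

#' Mean annual decline around incident acute kidney injury
#'
#' For each person with an incident AKI (first AKI record on/after the
#' person's first assessment), selects the assessment at least `window_days`
#' (183 ~ 6 months) before the event that is closest to that 6-month mark,
#' and likewise after, then annualizes the eGFR difference between the two
#' and aggregates as in [mean_decline_ci()]. Persons lacking a qualifying
#' assessment on either side are excluded. Pass uncensored assessments: the
#' post-AKI values are the point of this analysis.
#'
#' @param assessments Merged (uncensored) assessment tibble.
#' @param events Diagnostic-event tibble.
#' @param window_days Minimum distance from the event (default 183 days).
#' @return One-row tibble as in [mean_decline_ci()], with the per-person
#'   selections in `attr(, "persons")`.
#' @export
aki_peri_decline <- function(assessments, events, window_days = 183) {
  first_exam <- assessments |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_date = min(.data$exam_date), .groups = "drop")
  incident <- events |>
    dplyr::filter(.data$category == "AKI") |>
    dplyr::inner_join(first_exam, by = "person_id") |>
    dplyr::filter(.data$event_date >= .data$first_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(aki_date = suppressWarnings(min(.data$event_date)),
                     .groups = "drop")

  per <- assessments |>
    dplyr::inner_join(incident, by = "person_id") |>
    dplyr::mutate(offset = as.numeric(.data$exam_date - .data$aki_date)) |>
    dplyr::group_by(.data$person_id, .data$aki_date) |>
    dplyr::summarise(
      before_date = suppressWarnings(
        max(.data$exam_date[.data$offset <= -window_days])),
      after_date = suppressWarnings(
        min(.data$exam_date[.data$offset >= window_days])),
      egfr_before = .data$egfr[match(.data$before_date, .data$exam_date)],
      egfr_after = .data$egfr[match(.data$after_date, .data$exam_date)],
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(as.numeric(.data$before_date)),
                  is.finite(as.numeric(.data$after_date))) |>
    dplyr::mutate(
      span_years = as_years(.data$after_date - .data$before_date),
      decline = (.data$egfr_before - .data$egfr_after) / .data$span_years
    )
  if (nrow(per) < 2) {
    abort("Fewer than two persons with qualifying peri-AKI assessments.")
  }
  out <- mean_decline_ci(per$decline)
  attr(out, "persons") <- per
  out
}
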