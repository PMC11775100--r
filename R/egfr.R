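#' Estimated GFR from serum creatinine (CKD-EPI 2021, race-free)
#'
#' Computes eGFR in mL/min/1.73m^2 from serum creatinine, age and sex using
#' the 2021 race-free CKD-EPI creatinine equation:
#' \deqn{eGFR = 142 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.200} \cdot 0.9938^{age} \cdot 1.012[\mathrm{female}]}
#' with \eqn{\kappa} = 0.7 (women) / 0.9 (men), \eqn{\alpha} = -0.241 (women) /
#' -0.302 (men), and Scr in mg/dL. Input creatinine is in µmol/L and converted
#' with 1 mg/dL = 88.42 µmol/L.
#'
#' @param creatinine Serum creatinine in µmol/L (positive).
#' @param age Age at measurement in years (positive).
#' @param sex Sex coded 0 = female, 1 = male (the cohort-wide convention),
#'   or a character vector `"female"`/`"male"`.
#' @return Numeric vector of eGFR values, mL/min/1.73m^2.
#' @seealso [invert_ckd_epi()] for the closed-form inverse.
#' @export
#' @examples
#' ckd_epi_2021(61.894, age = 55, sex = 0)  # female at the kappa knot
ckd_epi_2021 <- function(creatinine, age, sex) {
  sex <- normalize_sex(sex)
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  bad <- !is.na(creatinine) & creatinine <= 0
  if (any(bad)) {
    abort(sprintf("`creatinine` must be positive (offending index %d).",
                  which(bad)[1]))
  }
  bad_age <- !is.na(age) & age <= 0
  if (any(bad_age)) {
    abort(sprintf("`age` must be positive (offending index %d).",
                  which(bad_age)[1]))
  }
  scr <- creatinine / UMOL_PER_MGDL
  kappa <- ifelse(sex == 1L, 0.9, 0.7)
  alpha <- ifelse(sex == 1L, -0.302, -0.241)
  fem <- ifelse(sex == 1L, 1, 1.012)
  142 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.200) *
    0.9938^age * fem
}

#' Closed-form inverse of the CKD-EPI 2021 equation
#'
#' Given a target eGFR, age and sex, returns the serum creatinine (µmol/L)
#' that the CKD-EPI 2021 equation maps to that eGFR. Each branch of the
#' piecewise equation is solved in closed form and the branch consistent with
#' its own Scr/kappa condition is selected; the equation is continuous and
#' strictly decreasing in creatinine, so the inverse is unique.
#'
#' @param egfr Target eGFR in mL/min/1.73m^2 (positive).
#' @inheritParams ckd_epi_2021
#' @return Serum creatinine in µmol/L.
#' @export
invert_ckd_epi <- function(egfr, age, sex) {
  sex <- normalize_sex(sex)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  if (any(egfr <= 0, na.rm = TRUE)) abort("`egfr` must be positive.")
  kappa <- ifelse(sex == 1L, 0.9, 0.7)
  alpha <- ifelse(sex == 1L, -0.302, -0.241)
  fem <- ifelse(sex == 1L, 1, 1.012)
  base <- 142 * 0.9938^age * fem
  r <- egfr / base
  # r >= 1: creatinine at or below the knot (min-branch active, exponent alpha)
  ratio <- ifelse(r >= 1, r^(1 / alpha), r^(-1 / 1.200))
  kappa * ratio * UMOL_PER_MGDL
}

UMOL_PER_MGDL <- 88.42

normalize_sex <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    s <- tolower(as.character(sex))
    out <- ifelse(s %in% c("male", "m", "1"), 1L,
                  ifelse(s %in% c("female", "f", "0"), 0L, NA_integer_))
    if (any(is.na(out) & !is.na(sex))) abort("`sex` must be female/male or 0/1.")
    return(out)
  }
  sex <- as.integer(sex)
  if (any(!sex %in% c(0L, 1L), na.rm = TRUE)) {
    abort("`sex` must be coded 0 (female) / 1 (male).")
  }
  sex
}

#' Age at examination from year and month of birth
#'
#' Birth day-of-month is imputed as the 15th (birth records carry year and
#' month only); age is the day count to the exam date divided by 365.25.
#'
#' @param birth_year,birth_month Integer year and month of birth.
#' @param exam_date Exam `Date` (or ISO-8601 string).
#' @return Age in years (real-valued).
#' @export
#' @examples
#' compute_age_at_exam(1950, 6, as.Date("2000-06-15"))  # exactly 50
compute_age_at_exam <- function(birth_year, birth_month, exam_date) {
  exam_date <- as.Date(exam_date)
  birth_date <- as.Date(sprintf("%04d-%02d-15", birth_year, birth_month))
  if (any(exam_date < birth_date, na.rm = TRUE)) {
    abort("`exam_date` precedes date of birth for at least one row.")
  }
  as_years(exam_date - birth_date)
}

#' Derive eGFR assessments from creatinine records
#'
#' Joins person-level sex and birth information onto dated creatinine records
#' and computes eGFR (CKD-EPI 2021) and the CKD flag (eGFR < 60).
#'
#' @param records Tibble of creatinine records with `person_id`, `exam_date`,
#'   `value` (µmol/L) and `source`; a `bias_corrected` column is carried
#'   through if present.
#' @param covariates Tibble with `person_id`, `sex`, `birth_year`,
#'   `birth_month`.
#' @return Tibble of assessments: `person_id`, `exam_date`, `source`,
#'   `creatinine`, `age_at_exam`, `sex`, `egfr`, `ckd`, `bias_corrected`.
#' @export
derive_egfr <- function(records, covariates) {
  require_columns(records, c("person_id", "exam_date", "value", "source"),
                  "records")
  require_columns(covariates, c("person_id", "sex", "birth_year", "birth_month"),
                  "covariates")
  out <- records |>
    dplyr::inner_join(
      dplyr::select(covariates, "person_id", "sex", "birth_year", "birth_month"),
      by = "person_id"
    ) |>
    dplyr::mutate(
      age_at_exam = compute_age_at_exam(.data$birth_year, .data$birth_month,
                                        .data$exam_date),
      egfr = ckd_epi_2021(.data$value, .data$age_at_exam, .data$sex),
      ckd = .data$egfr < 60
    )
  if (!"bias_corrected" %in% names(out)) out$bias_corrected <- FALSE
  out |>
    dplyr::transmute(
      .data$person_id, exam_date = as.Date(.data$exam_date), .data$source,
      creatinine = .data$value, .data$age_at_exam, .data$sex, .data$egfr,
      .data$ckd, .data$bias_corrected
    ) |>
    dplyr::arrange(.data$person_id, .data$exam_date)
}
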