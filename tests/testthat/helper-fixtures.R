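# Small in-code fixture builders shared across the suite.

make_creatinine <- function(person_id, exam_date, value, source = "eMR",
                            qc_status = if (source[1] == "SC") "pass" else "raw") {
  tibble::tibble(
    person_id = person_id,
    exam_date = as.Date(exam_date),
    value = value,
    source = source,
    qc_status = qc_status
  )
}

make_assessments <- function(person_id, exam_date, egfr, source = "SC",
                             sex = 0, age_at_exam = 60) {
  tibble::tibble(
    person_id = person_id,
    exam_date = as.Date(exam_date),
    source = source,
    creatinine = NA_real_,
    age_at_exam = age_at_exam,
    sex = sex,
    egfr = egfr,
    ckd = egfr < 60,
    bias_corrected = FALSE
  )
}

make_events <- function(person_id, event_date, category, raw_code = "X") {
  tibble::tibble(
    person_id = person_id,
    event_date = as.Date(event_date),
    category = category,
    raw_code = raw_code
  )
}

no_events <- function() make_events(character(), character(), character())[0, ]

# Independent closed-form evaluation of CKD-EPI 2021, written separately from
# the package implementation so it can serve as an oracle.
ckd_epi_reference <- function(crea_umol, age, sex_male) {
  scr <- crea_umol / 88.42
  k <- if (sex_male) 0.9 else 0.7
  a <- if (sex_male) -0.302 else -0.241
  val <- 142
  if (scr / k < 1) val <- val * (scr / k)^a
  if (scr / k > 1) val <- val * (scr / k)^(-1.2)
  val <- val * 0.9938^age
  if (!sex_male) val <- val * 1.012
  val
}

# Lognormal paired sample under the additive log-scale error model:
# ln(sc) ~ N(ln 75, 0.25^2), emr = sc / factor * exp(eps), eps ~ N(0, 0.05^2).
simulate_pairs <- function(n, factor, year = 2008, mu = log(75),
                           sigma = 0.25, noise = 0.05) {
  sc <- exp(rnorm(n, mu, sigma))
  emr <- sc / factor * exp(rnorm(n, 0, noise))
  tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    year = year,
    sc_date = as.Date(sprintf("%d-06-15", year)),
    emr_date = as.Date(sprintf("%d-06-20", year)),
    sc_value = sc,
    emr_value = emr
  )
}

write_fixture <- function(df, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  readr::write_delim(df, path, delim = if (ext == "csv") "," else "\t")
  path
}
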