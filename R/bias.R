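#' @title Calendar-year assay-bias model for eMR creatinine
#' @description eMR creatinine from routine care, measured by unknown assays
#'   before standardization improved (around 2009), carries a systematic
#'   multiplicative bias relative to gold-standard study-center (SC)
#'   creatinine. On the log scale the error model is additive:
#'   \deqn{X^* = X + s + E_r^*,\qquad X = \ln(\mathrm{crea}_{SC}),\;
#'         X^* = \ln(\mathrm{crea}_{eMR}),\; E_r^* \sim N(0, \sigma^{*2}),}
#'   so the per-calendar-year systematic bias is
#'   \eqn{s^{year} = \hat\mu^{*year} - \hat\mu^{year}}, a ratio of geometric
#'   means on the original scale. The correction factor reported and applied
#'   here follows the SC-over-eMR convention:
#'   \eqn{factor = GM(SC)/GM(eMR) = \exp(-s^{year})}, and corrected eMR
#'   creatinine is \eqn{eMR \times factor} (equivalently
#'   \eqn{X^* - s^{year}} on the log scale).
#' @name bias_model
NULL

#' Pair same-year SC and eMR creatinine measurements
#'
#' For each SC measurement, selects the eMR measurement of the same person
#' from the same calendar year closest in time to the SC blood draw (ties
#' broken by the earlier eMR date). Persons lacking a same-year eMR value
#' contribute no pair. At most one pair per person per SC visit.
#'
#' @param sc_records,emr_records QC-passed creatinine tibbles (`person_id`,
#'   `exam_date`, `value`).
#' @return Tibble: `person_id`, `year`, `sc_date`, `emr_date`, `sc_value`,
#'   `emr_value`.
#' @export
pair_same_year <- function(sc_records, emr_records) {
  require_columns(sc_records, c("person_id", "exam_date", "value"), "sc_records")
  require_columns(emr_records, c("person_id", "exam_date", "value"), "emr_records")
  sc <- sc_records |>
    dplyr::transmute(.data$person_id, sc_date = as.Date(.data$exam_date),
                     sc_value = .data$value,
                     year = as.integer(format(.data$exam_date, "%Y")))
  emr <- emr_records |>
    dplyr::transmute(.data$person_id, emr_date = as.Date(.data$exam_date),
                     emr_value = .data$value,
                     year = as.integer(format(.data$exam_date, "%Y")))
  dplyr::inner_join(sc, emr, by = c("person_id", "year"),
                    relationship = "many-to-many") |>
    dplyr::mutate(gap = abs(as.numeric(.data$emr_date - .data$sc_date))) |>
    dplyr::arrange(.data$person_id, .data$sc_date, .data$gap, .data$emr_date) |>
    dplyr::distinct(.data$person_id, .data$sc_date, .keep_all = TRUE) |>
    dplyr::select("person_id", "year", "sc_date", "emr_date", "sc_value",
                  "emr_value")
}

#' Estimate the per-calendar-year multiplicative bias factor
#'
#' For each year with at least `min_pairs` pairs, estimates
#' `factor = GM(sc) / GM(emr)` on the paired sample, together with the
#' log-scale bias `log_bias = mean(ln emr) - mean(ln sc)` (so
#' `factor = exp(-log_bias)`) and the Spearman correlation between the paired
#' values. With `winsorize = TRUE`, each of ln(SC) and ln(eMR) is first
#' clamped to its own within-year mean ± 3 SD — a robustness check against
#' extreme values.
#'
#' @param pairs Tibble from [pair_same_year()].
#' @param winsorize Clamp log values at mean ± 3 SD within year first.
#' @param min_pairs Minimum pairs required to estimate a year (default 100).
#' @return Tibble: `year`, `n_pairs`, `factor`, `log_bias`, `spearman`,
#'   `winsorized`.
#' @export
estimate_year_bias <- function(pairs, winsorize = FALSE, min_pairs = 100) {
  require_columns(pairs, c("year", "sc_value", "emr_value"), "pairs")
  clamp3 <- function(x) {
    m <- mean(x); s <- sd(x)
    if (is.na(s) || s == 0) return(x)
    pmin(pmax(x, m - 3 * s), m + 3 * s)
  }
  pairs |>
    dplyr::group_by(.data$year) |>
    dplyr::filter(dplyr::n() >= min_pairs) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      log_bias = {
        lsc <- log(.data$sc_value); lem <- log(.data$emr_value)
        if (winsorize) { lsc <- clamp3(lsc); lem <- clamp3(lem) }
        mean(lem) - mean(lsc)
      },
      spearman = suppressWarnings(
        cor(.data$sc_value, .data$emr_value, method = "spearman")),
      .groups = "drop"
    ) |>
    dplyr::mutate(factor = exp(-.data$log_bias), winsorized = winsorize) |>
    dplyr::select("year", "n_pairs", "factor", "log_bias", "spearman",
                  "winsorized")
}

#' Build a complete calendar-year bias table
#'
#' Extends per-year bias estimates to every year of the data span with proxy
#' factors: interior gap years get the exponential of the (linearly
#' interpolated) mean of the flanking estimated years' log biases
#' (`interpolated`); years before the first estimated year carry the first
#' year's factor (`boundary_carry`); years after the last estimated year get
#' factor 1.0 — no correction — when the last estimate is already close to
#' unity (`|factor - 1| <= unity_threshold`), else carry the last factor.
#'
#' @param estimates Tibble from [estimate_year_bias()] (`year`, `factor`;
#'   `log_bias`, `n_pairs`, `winsorized` used when present).
#' @param year_range Length-2 integer span the table must cover; defaults to
#'   the span of the estimates.
#' @param unity_threshold Closeness to 1 at which trailing years switch to no
#'   correction (default 0.05).
#' @return A `bias_table` tibble: `year`, `factor`, `log_bias`, `provenance`,
#'   `n_pairs`.
#' @export
build_bias_table <- function(estimates, year_range = NULL,
                             unity_threshold = 0.05) {
  require_columns(estimates, c("year", "factor"), "estimates")
  if (nrow(estimates) == 0) abort("No estimated years: cannot build a bias table.")
  est <- dplyr::arrange(estimates, .data$year)
  if (!"log_bias" %in% names(est)) est$log_bias <- -log(est$factor)
  if (!"n_pairs" %in% names(est)) est$n_pairs <- NA_integer_
  winsorized <- "winsorized" %in% names(est) && isTRUE(est$winsorized[1])
  year_range <- as.integer(year_range %||% range(est$year))
  years <- seq(min(year_range[1], min(est$year)),
               max(year_range[2], max(est$year)))

  log_f <- stats::setNames(rep(NA_real_, length(years)), years)
  log_f[as.character(est$year)] <- log(est$factor)
  prov <- stats::setNames(rep(NA_character_, length(years)), years)
  prov[as.character(est$year)] <-
    if (winsorized) "estimated_winsorized" else "estimated"

  first_y <- min(est$year); last_y <- max(est$year)
  interior <- years > first_y & years < last_y & is.na(log_f)
  if (any(interior)) {
    log_f[interior] <- approx(est$year, log(est$factor),
                              xout = years[interior])$y
    prov[interior] <- "interpolated"
  }
  before <- years < first_y
  log_f[before] <- log(est$factor[est$year == first_y])
  prov[before] <- "boundary_carry"
  after <- years > last_y
  last_factor <- est$factor[est$year == last_y]
  if (abs(last_factor - 1) <= unity_threshold) {
    log_f[after] <- 0
    prov[after] <- "unity"
  } else {
    log_f[after] <- log(last_factor)
    prov[after] <- "boundary_carry"
  }

  out <- tibble::tibble(
    year = years,
    factor = exp(unname(log_f)),
    log_bias = -unname(log_f),
    provenance = unname(prov),
    n_pairs = est$n_pairs[match(years, est$year)]
  )
  class(out) <- c("bias_table", class(out))
  out
}

#' Apply calendar-year bias correction to eMR creatinine
#'
#' Multiplies each eMR value by its calendar year's factor (equivalently,
#' subtracts the log-scale bias). SC records pass through untouched. The
#' original value and the factor used are retained per record.
#'
#' @param records Creatinine tibble (`person_id`, `exam_date`, `value`,
#'   `source`).
#' @param bias_table From [build_bias_table()]; must cover every eMR year.
#' @return `records` with `value` corrected for eMR rows and new columns
#'   `value_raw`, `correction_factor`, `bias_corrected`.
#' @export
apply_bias_correction <- function(records, bias_table) {
  require_columns(records, c("person_id", "exam_date", "value", "source"),
                  "records")
  require_columns(bias_table, c("year", "factor"), "bias_table")
  year <- as.integer(format(as.Date(records$exam_date), "%Y"))
  fac <- bias_table$factor[match(year, bias_table$year)]
  emr <- records$source == "eMR"
  uncovered <- emr & is.na(fac)
  if (any(uncovered)) {
    abort(sprintf("Bias table does not cover year%s %s.",
                  if (length(unique(year[uncovered])) > 1) "s" else "",
                  paste(sort(unique(year[uncovered])), collapse = ", ")))
  }
  records |>
    dplyr::mutate(
      value_raw = .data$value,
      correction_factor = ifelse(emr, fac, 1),
      value = .data$value * .data$correction_factor,
      bias_corrected = emr
    )
}
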