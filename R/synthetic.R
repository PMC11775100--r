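#' Default calendar-year bias schedule for the simulator
#'
#' The multiplicative assay-bias factors injected into simulated eMR
#' creatinine: the estimated ramp 0.84, 0.84, 0.90, 0.91, 0.93, 0.95, 0.97
#' over 2007-2013, 0.84 for all earlier years, and 1.0 (no bias) afterwards —
#' the schedule that characterizes pre-standardization creatinine assays.
#'
#' @param years Integer vector of calendar years to cover.
#' @return Named numeric vector, names = years.
#' @export
default_bias_schedule <- function(years) {
  ramp <- c(`2007` = 0.84, `2008` = 0.84, `2009` = 0.90, `2010` = 0.91,
            `2011` = 0.93, `2012` = 0.95, `2013` = 0.97)
  out <- setNames(rep(1, length(years)), years)
  out[years < 2007] <- 0.84
  hit <- as.character(years[years %in% 2007:2013])
  out[hit] <- ramp[hit]
  out
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the data-generating conditions the simulator emulates: lognormal
#' serum creatinine, a year-dependent multiplicative assay bias before ~2013,
#' SC measurements concentrated in the study-center visit years, eMR
#' measurements spread over decades with visit frequency increasing as latent
#' kidney function falls, sparse kidney-event codes, and a small rate of
#' deliberately corrupt rows for QC testing. The seed fully determines all
#' output.
#'
#' @param n_persons Cohort size.
#' @param seed Integer seed.
#' @param year_start,year_end Calendar span of eMR measurements.
#' @param sc_baseline_years Years the SC baseline visits fall in.
#' @param sc_followup_years Years of the SC follow-up visit.
#' @param followup_fraction Fraction of persons with an SC follow-up visit.
#' @param bias_schedule Named year -> true multiplicative bias factor
#'   (observed eMR = true creatinine / factor x noise).
#' @param noise_sd SD of the random measurement error on the log scale
#'   (both sources).
#' @param crea_ln_mean,crea_ln_sd Baseline ln-creatinine location (female,
#'   male) and scale.
#' @param mean_slope Population mean annual eGFR decline (mL/min/1.73m^2/yr).
#' @param slope_sd SD of the person-level slope deviation.
#' @param effects Named covariate effects on the slope (per unit), centered
#'   at the sample mean so the population mean slope stays `mean_slope`.
#' @param allele_freq Frequency of the decline-increasing allele.
#' @param age_entry_range Uniform age range at the SC baseline visit.
#' @param prop_male,smoking_prev,diabetes_prev Covariate prevalences.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param visit_base Expected eMR measurements per person-year at full
#'   calendar coverage and latent eGFR 90.
#' @param visit_egfr_coef Log-intensity increase per 10 mL/min/1.73m^2 of
#'   latent eGFR below 90 (the informative-visit mechanism).
#' @param visit_max Cap on the expected yearly visit count.
#' @param coverage_year,coverage_growth GP-record calendar coverage: the
#'   visit intensity is multiplied by
#'   `min(1, exp(coverage_growth * (year - coverage_year)))`, making early
#'   decades sparse and recent years dense, as routine EHR volumes are.
#' @param hazards Named per-person-year event hazards.
#' @param aki_drop Acute latent eGFR drop at an AKI event.
#' @param aki_recovery_frac Fraction of the drop recovered by one year.
#' @param corrupt_dup_rate,corrupt_above_rate,corrupt_below_rate Rates of
#'   injected duplicate / above-maximum / below-LOD eMR rows.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_persons = 2000,
                             seed = 1,
                             year_start = 1990,
                             year_end = 2017,
                             sc_baseline_years = 2007:2010,
                             sc_followup_years = c(2012, 2013),
                             followup_fraction = 0.4,
                             bias_schedule = default_bias_schedule(year_start:year_end),
                             noise_sd = 0.05,
                             crea_ln_mean = c(female = log(62), male = log(78)),
                             crea_ln_sd = 0.15,
                             mean_slope = 1.0,
                             slope_sd = 0.3,
                             effects = c(age = 0.005, male = 0.10,
                                         smoking = 0.026, obesity = 0.010,
                                         diabetes = 0.383, variant = 0.052),
                             allele_freq = 0.2,
                             age_entry_range = c(40, 69),
                             prop_male = 0.46,
                             smoking_prev = 0.45,
                             diabetes_prev = 0.05,
                             bmi_mean = 27.4,
                             bmi_sd = 4.8,
                             visit_base = 0.6,
                             visit_egfr_coef = 0.4,
                             visit_max = 12,
                             coverage_year = 2004,
                             coverage_growth = 0.12,
                             hazards = c(AKI = 0.001, ESKD = 5e-5,
                                         dialysis = 5e-5, transplant = 3e-5,
                                         nephrectomy = 2e-4,
                                         pregnancy = 0.02, diabetes = 0.004),
                             aki_drop = 20,
                             aki_recovery_frac = 0.7,
                             corrupt_dup_rate = 0.002,
                             corrupt_above_rate = 5e-4,
                             corrupt_below_rate = 5e-4) {
  cfg <- as.list(environment())
  if (cfg$n_persons < 1) abort("`n_persons` must be at least 1.")
  if (cfg$noise_sd < 0 || cfg$slope_sd < 0) abort("SDs must be non-negative.")
  if (any(cfg$bias_schedule <= 0)) abort("Bias factors must be positive.")
  if (any(cfg$hazards < 0)) abort("Event hazards must be non-negative.")
  if (cfg$allele_freq < 0 || cfg$allele_freq > 1) {
    abort("`allele_freq` must lie in [0, 1].")
  }
  if (any(c(cfg$corrupt_dup_rate, cfg$corrupt_above_rate,
            cfg$corrupt_below_rate) < 0)) {
    abort("Corruption rates must be non-negative.")
  }
  structure(cfg, class = "synthetic_config")
}

center <- function(x) x - mean(x)

#' Generate the synthetic cohort: covariates and latent truth
#'
#' Draws person-level covariates (sex, birth year/month, smoking, BMI,
#' diabetes, allele dosage) and the latent trajectory truth: a baseline eGFR
#' intercept (from sex-specific lognormal creatinine inverted through
#' CKD-EPI 2021 at the entry age) and a true annual slope
#' `mean_slope + sum(effect_j * centered covariate_j) + N(0, slope_sd)`.
#' Covariate contributions are centered at the sample mean so the cohort mean
#' slope equals `mean_slope` by construction; the truth table is retained for
#' parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return List of tibbles `covariates` (the input-format covariate table)
#'   and `truth` (`person_id`, `baseline_date`, `age_entry`, `intercept_egfr`,
#'   `slope`, `has_followup`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_persons
  person_id <- sprintf("P%06d", seq_len(n))
  sex <- rbinom(n, 1, config$prop_male)
  smoking <- rbinom(n, 1, config$smoking_prev)
  bmi <- pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 15)
  diabetes <- rbinom(n, 1, config$diabetes_prev)
  dosage <- rbinom(n, 2, config$allele_freq)

  age_entry <- runif(n, config$age_entry_range[1], config$age_entry_range[2])
  baseline_year <- sample(config$sc_baseline_years, n, replace = TRUE)
  baseline_date <- as.Date(sprintf("%d-01-01", baseline_year)) +
    sample.int(364, n, replace = TRUE)
  birth_date <- baseline_date - round(age_entry * DAYS_PER_YEAR)
  birth_year <- as.integer(format(birth_date, "%Y"))
  birth_month <- as.integer(format(birth_date, "%m"))
  # entry age recomputed under the analysis convention (birth day = 15th)
  age_entry <- compute_age_at_exam(birth_year, birth_month, baseline_date)

  ln_crea <- rnorm(n, config$crea_ln_mean[ifelse(sex == 1, "male", "female")],
                   config$crea_ln_sd)
  intercept <- ckd_epi_2021(exp(ln_crea), age_entry, sex)

  e <- config$effects
  slope <- config$mean_slope +
    e[["age"]] * center(age_entry - 40) +
    e[["male"]] * center(sex) +
    e[["smoking"]] * center(smoking) +
    e[["obesity"]] * center(as.numeric(bmi >= 30)) +
    e[["diabetes"]] * center(diabetes) +
    e[["variant"]] * center(dosage) +
    rnorm(n, 0, config$slope_sd)

  list(
    covariates = tibble::tibble(
      person_id, sex, birth_year, birth_month, smoking, bmi,
      diabetes, variant_dosage = as.numeric(dosage)
    ),
    truth = tibble::tibble(
      person_id, baseline_date, age_entry,
      intercept_egfr = intercept, slope,
      has_followup = runif(n) < config$followup_fraction
    )
  )
}

# latent eGFR at `dates` for persons indexed by `idx`, including AKI episodes
latent_egfr <- function(idx, dates, truth, aki, config) {
  t_years <- as_years(dates - truth$baseline_date[idx])
  egfr <- truth$intercept_egfr[idx] - truth$slope[idx] * t_years
  if (nrow(aki) > 0) {
    aki_date <- aki$event_date[match(truth$person_id[idx], aki$person_id)]
    dt <- as_years(dates - aki_date)
    drop <- config$aki_drop
    resid <- drop * (1 - config$aki_recovery_frac)
    effect <- dplyr::case_when(
      is.na(dt) | dt < 0 ~ 0,
      dt < 0.1 ~ -drop,
      dt < 1 ~ -(drop - (drop - resid) * (dt - 0.1) / 0.9),
      TRUE ~ -resid
    )
    egfr <- egfr + effect
  }
  pmax(egfr, 2)  # floor far below the censoring threshold
}

#' Generate measurements and diagnostic events for a synthetic cohort
#'
#' Produces the three raw input tables of the pipeline. The latent eGFR path
#' is linear in time (plus acute drop/partial-recovery episodes at AKI
#' events); true creatinine is the closed-form CKD-EPI 2021 inverse at the
#' person's age and sex on each date. SC values observe the truth with
#' lognormal noise and no bias; eMR values are additionally divided by the
#' calendar year's bias factor (pre-standardization assays read high). eMR
#' visit counts are Poisson per person-year with intensity increasing as
#' latent eGFR falls (informative observation). Corrupt rows (duplicates,
#' above-maximum, below-LOD) are appended at the configured rates.
#'
#' @param cohort List from [generate_cohort()].
#' @param config The same [synthetic_config()].
#' @return List of tibbles: `sc_records`, `emr_records` (input format, with
#'   `read_code`), `events` (raw-coded), each reproducible from the seed.
#' @export
generate_measurements <- function(cohort, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  truth <- cohort$truth
  cov <- cohort$covariates
  n <- nrow(truth)
  years <- config$year_start:config$year_end

  codelist <- default_codelist()
  pick_code <- function(category, k) {
    pool <- codelist$raw_code[codelist$category == category]
    sample(pool, k, replace = TRUE)
  }

  # --- diagnostic events on a person x year hazard grid ------------------
  grid <- tidyr::expand_grid(idx = seq_len(n), year = years)
  grid$age <- truth$age_entry[grid$idx] +
    (grid$year - as.integer(format(truth$baseline_date[grid$idx], "%Y")))
  grid <- grid[grid$age >= 18, ]
  ev_list <- purrr::imap(as.list(config$hazards), function(h, category) {
    eligible <- if (category == "pregnancy") {
      cov$sex[grid$idx] == 0 & grid$age >= 20 & grid$age <= 45
    } else {
      rep(TRUE, nrow(grid))
    }
    hit <- eligible & runif(nrow(grid)) < h
    if (!any(hit)) return(NULL)
    tibble::tibble(
      person_id = truth$person_id[grid$idx[hit]],
      event_date = as.Date(sprintf("%d-01-01", grid$year[hit])) +
        sample.int(364, sum(hit), replace = TRUE),
      category = category
    )
  })
  events <- purrr::list_rbind(purrr::compact(ev_list))
  if (nrow(events) == 0) {
    events <- tibble::tibble(person_id = character(),
                             event_date = as.Date(character()),
                             category = character())
  }
  # one AKI episode per person shapes the latent path (the first)
  aki <- events |>
    dplyr::filter(.data$category == "AKI") |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(event_date = suppressWarnings(min(.data$event_date)),
                     .groups = "drop")

  # --- SC records: baseline visit for everyone, follow-up for a fraction --
  sc_dates <- truth$baseline_date
  fu_idx <- which(truth$has_followup)
  fu_year <- sample(config$sc_followup_years, length(fu_idx), replace = TRUE)
  fu_dates <- as.Date(sprintf("%d-01-01", fu_year)) +
    sample.int(364, length(fu_idx), replace = TRUE)
  sc_idx <- c(seq_len(n), fu_idx)
  sc_when <- c(sc_dates, fu_dates)
  sc_true <- invert_ckd_epi(
    latent_egfr(sc_idx, sc_when, truth, aki, config),
    truth$age_entry[sc_idx] + as_years(sc_when - truth$baseline_date[sc_idx]),
    cov$sex[sc_idx]
  )
  sc_records <- tibble::tibble(
    person_id = truth$person_id[sc_idx],
    exam_date = sc_when,
    value = sc_true * exp(rnorm(length(sc_idx), 0, config$noise_sd))
  )

  # --- eMR records: informative Poisson visit process --------------------
  mid_year <- as.Date(sprintf("%d-07-01", grid$year))
  grid_egfr <- latent_egfr(grid$idx, mid_year, truth, aki, config)
  coverage <- pmin(1, exp(config$coverage_growth *
                            (grid$year - config$coverage_year)))
  lambda <- pmin(config$visit_max,
                 config$visit_base * coverage *
                   exp(config$visit_egfr_coef * (90 - grid_egfr) / 10))
  n_visits <- rpois(nrow(grid), lambda)
  keep <- n_visits > 0
  vis_idx <- rep(grid$idx[keep], n_visits[keep])
  vis_year <- rep(grid$year[keep], n_visits[keep])
  vis_date <- as.Date(sprintf("%d-01-01", vis_year)) +
    sample.int(364, length(vis_year), replace = TRUE)
  vis_age <- truth$age_entry[vis_idx] +
    as_years(vis_date - truth$baseline_date[vis_idx])
  vis_true <- invert_ckd_epi(
    latent_egfr(vis_idx, vis_date, truth, aki, config), vis_age,
    cov$sex[vis_idx])
  bias <- config$bias_schedule[as.character(vis_year)]
  emr_records <- tibble::tibble(
    person_id = truth$person_id[vis_idx],
    exam_date = vis_date,
    value = vis_true / bias * exp(rnorm(length(vis_idx), 0, config$noise_sd)),
    read_code = "44J3."
  )

  # --- corrupt rows for QC exercise --------------------------------------
  n_emr <- nrow(emr_records)
  n_dup <- rbinom(1, n_emr, config$corrupt_dup_rate)
  n_above <- rbinom(1, n_emr, config$corrupt_above_rate)
  n_below <- rbinom(1, n_emr, config$corrupt_below_rate)
  extra <- list()
  if (n_dup > 0) extra$dup <- emr_records[sample.int(n_emr, n_dup), ]
  if (n_above > 0) {
    extra$above <- emr_records[sample.int(n_emr, n_above), ] |>
      dplyr::mutate(value = runif(n_above, 6600, 9000))
  }
  if (n_below > 0) {
    extra$below <- emr_records[sample.int(n_emr, n_below), ] |>
      dplyr::mutate(value = runif(n_below, 0.5, 5))
  }
  emr_records <- dplyr::bind_rows(c(list(emr_records), extra)) |>
    dplyr::arrange(.data$person_id, .data$exam_date, .data$value)

  events_out <- if (is.null(events) || nrow(events) == 0) {
    tibble::tibble(person_id = character(), event_date = as.Date(character()),
                   code = character())
  } else {
    events |>
      dplyr::mutate(code = {
        out <- character(dplyr::n())
        for (cat in unique(events$category)) {
          sel <- events$category == cat
          out[sel] <- pick_code(cat, sum(sel))
        }
        out
      }) |>
      dplyr::select("person_id", "event_date", "code") |>
      dplyr::arrange(.data$person_id, .data$event_date)
  }

  list(sc_records = sc_records, emr_records = emr_records,
       events = events_out)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_cohort()] then [generate_measurements()],
#' with records returned in the typed in-memory form the pipeline consumes
#' (SC records `qc_status = "pass"`, eMR records `"raw"`).
#'
#' @param config A [synthetic_config()].
#' @return List: `covariates`, `truth`, `sc_records`, `emr_records`,
#'   `events` (categorized via the demo code list).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  cohort <- generate_cohort(config)
  meas <- generate_measurements(cohort, config)
  codelist <- default_codelist()
  events <- meas$events |>
    dplyr::inner_join(codelist, by = c(code = "raw_code")) |>
    dplyr::transmute(.data$person_id, .data$event_date, .data$category,
                     raw_code = .data$code) |>
    dplyr::distinct(.data$person_id, .data$event_date, .data$category,
                    .keep_all = TRUE)
  list(
    covariates = cohort$covariates,
    truth = cohort$truth,
    sc_records = meas$sc_records |>
      dplyr::mutate(source = "SC", qc_status = "pass"),
    emr_records = meas$emr_records |>
      dplyr::mutate(source = "eMR", qc_status = "raw"),
    events = events
  )
}
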