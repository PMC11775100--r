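test_that("the two-point annualized decline is endpoints-only with the stated sign", {
  a <- make_assessments("A", c("2008-01-01", "2013-01-01"), c(100, 90))
  d <- annual_decline(a)
  expect_equal(d$decline, 10 / as.numeric(diff(range(a$exam_date))) * 365.25,
               tolerance = 1e-10)
  expect_equal(round(d$decline, 2), 2)  # ten units over five years
  # intermediate assessments do not change the estimate
  a_mid <- dplyr::bind_rows(a, make_assessments("A", "2010-06-01", 40))
  expect_equal(annual_decline(a_mid)$decline, d$decline)
  # constant eGFR gives zero
  a_const <- make_assessments("B", c("2008-01-01", "2010-01-01"), c(95, 95))
  expect_equal(annual_decline(a_const)$decline, 0)
})

test_that("eligibility needs two assessments at least one year apart", {
  six_months <- make_assessments("A", c("2008-01-01", "2008-07-01"), c(100, 98))
  d <- annual_decline(six_months)
  expect_false(d$eligible)
  expect_equal(d$reason, "span_lt_1yr")
  single <- make_assessments("B", "2008-01-01", 100)
  expect_equal(annual_decline(single)$reason, "single_assessment")
  almost_year <- make_assessments("C", c("2009-01-01", "2009-12-31"), c(100, 98))
  expect_false(annual_decline(almost_year)$eligible)  # 364 days, not 365
  full_year <- make_assessments("D", c("2009-01-01", "2010-01-01"), c(100, 98))
  expect_true(annual_decline(full_year)$eligible)
})

test_that("the cohort mean and its normal CI are computed as stated", {
  expect_equal(mean_decline_ci(c(1, 1, 1))$mean_decline, 1)
  expect_equal(mean_decline_ci(c(1, 1, 1))$ci_low, 1)
  s <- mean_decline_ci(c(0, 2))
  expect_equal(s$mean_decline, 1)
  expect_equal(s$ci_high - s$mean_decline, 1.96 * sd(c(0, 2)) / sqrt(2))
  expect_error(mean_decline_ci(c(1)), "two eligible")
})

test_that("regression recovers an exact linear rule with zero noise", {
  set.seed(21)
  n <- 200
  cov <- tibble::tibble(
    person_id = sprintf("P%03d", 1:n), sex = rbinom(n, 1, 0.5),
    birth_year = 1950, birth_month = 6, smoking = rbinom(n, 1, 0.4),
    bmi = runif(n, 20, 40), diabetes = rbinom(n, 1, 0.2),
    variant_dosage = rbinom(n, 2, 0.3)
  )
  age_first <- runif(n, 45, 75)
  declines <- tibble::tibble(
    person_id = cov$person_id, n_assessments = 2L,
    first_date = as.Date("2008-01-01"), last_date = as.Date("2012-01-01"),
    egfr_first = 100, egfr_last = 90, age_first = age_first,
    span_years = 4, eligible = TRUE, reason = "eligible",
    decline = 0.9 + 0.005 * (age_first - 40)
  )
  fit <- decline_regression(declines, cov, "lifestyle")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "(Intercept)"], 0.9, tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "age40"], 0.005, tolerance = 1e-8)
  expect_equal(td$estimate[td$term %in% c("sex", "smoking", "obesity", "diabetes")],
               rep(0, 4), tolerance = 1e-8)
  g <- glance(fit)
  expect_equal(g$n_persons, n)
  expect_equal(g$m_assessments, 2L * n)
})

test_that("degenerate designs fail loudly with named columns", {
  n <- 50
  cov <- tibble::tibble(
    person_id = sprintf("P%03d", 1:n), sex = 1,  # zero variance
    birth_year = 1950, birth_month = 6, smoking = rbinom(n, 1, 0.4),
    bmi = runif(n, 20, 40), diabetes = rbinom(n, 1, 0.2),
    variant_dosage = rbinom(n, 2, 0.3)
  )
  declines <- tibble::tibble(
    person_id = cov$person_id, n_assessments = 2L,
    first_date = as.Date("2008-01-01"), last_date = as.Date("2012-01-01"),
    egfr_first = 100, egfr_last = 95, age_first = runif(n, 45, 75),
    span_years = 4, eligible = TRUE, reason = "eligible",
    decline = rnorm(n, 1, 0.2)
  )
  expect_error(decline_regression(declines, cov, "genetic"), "`sex`")
})

test_that("listwise deletion drops persons with missing covariates", {
  n <- 60
  set.seed(22)
  cov <- tibble::tibble(
    person_id = sprintf("P%03d", 1:n), sex = rbinom(n, 1, 0.5),
    birth_year = 1950, birth_month = 6, smoking = rbinom(n, 1, 0.4),
    bmi = c(NA, runif(n - 1, 20, 40)), diabetes = rbinom(n, 1, 0.2),
    variant_dosage = rbinom(n, 2, 0.3)
  )
  declines <- tibble::tibble(
    person_id = cov$person_id, n_assessments = 2L,
    first_date = as.Date("2008-01-01"), last_date = as.Date("2012-01-01"),
    egfr_first = 100, egfr_last = 95, age_first = runif(n, 45, 75),
    span_years = 4, eligible = TRUE, reason = "eligible",
    decline = rnorm(n, 1, 0.2)
  )
  fit <- decline_regression(declines, cov, "lifestyle")
  expect_equal(fit$n_persons, n - 1)
  # the genetic model does not use BMI, so nothing is dropped there
  expect_equal(decline_regression(declines, cov, "genetic")$n_persons, n)
})

test_that("peri-AKI selection takes the assessments closest to ±6 months", {
  aki_date <- as.Date("2012-01-01")
  offsets <- c(-12, -7, 8, 20) * 30.4375  # months in days
  a <- make_assessments("A", aki_date + offsets, c(100, 95, 70, 80))
  a2 <- make_assessments("B", aki_date + c(-400, 300), c(90, 70))
  ev <- make_events(c("A", "B"), c("2012-01-01", "2012-01-01"), c("AKI", "AKI"))
  # both persons need a first assessment on/before the event for incidence
  res <- aki_peri_decline(dplyr::bind_rows(a, a2), ev)
  per <- attr(res, "persons")
  pa <- per[per$person_id == "A", ]
  expect_equal(pa$egfr_before, 95)  # -7 months, not -12
  expect_equal(pa$egfr_after, 70)   # +8 months, not +20
  expect_equal(res$n_persons, 2)
})

test_that("persons lacking a qualifying pre- or post-AKI assessment are excluded", {
  aki_date <- as.Date("2012-01-01")
  ok <- make_assessments("B", aki_date + c(-400, -200, 300), c(90, 88, 70))
  near_only <- make_assessments("A", aki_date + c(-90, 240), c(100, 80))
  ev <- make_events(c("A", "B", "C"), rep("2012-01-01", 3), rep("AKI", 3))
  third <- make_assessments("C", aki_date + c(-300, 250), c(95, 80))
  res <- aki_peri_decline(dplyr::bind_rows(ok, near_only, third), ev)
  expect_setequal(attr(res, "persons")$person_id, c("B", "C"))
})

test_that("AKI events before the first assessment are not incident", {
  a <- make_assessments("A", as.Date("2012-01-01") + c(200, 600, 1000),
                        c(95, 90, 85))
  ev <- make_events("A", "2012-01-01", "AKI")
  expect_error(aki_peri_decline(a, ev), "Fewer than two")
})

test_that("the normal-approximation CI covers the true mean near its nominal rate", {
  set.seed(23)
  covered <- replicate(500, {
    d <- rnorm(50, mean = 1, sd = 0.4)
    s <- mean_decline_ci(d)
    s$ci_low <= 1 && 1 <= s$ci_high
  })
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.985)
})

test_that("permuting the outcome leaves no spurious associations", {
  set.seed(24)
  n <- 300
  cov <- tibble::tibble(
    person_id = sprintf("P%03d", 1:n), sex = rbinom(n, 1, 0.5),
    birth_year = 1950, birth_month = 6, smoking = rbinom(n, 1, 0.4),
    bmi = runif(n, 20, 40), diabetes = rbinom(n, 1, 0.2),
    variant_dosage = rbinom(n, 2, 0.3)
  )
  base <- tibble::tibble(
    person_id = cov$person_id, n_assessments = 2L,
    first_date = as.Date("2008-01-01"), last_date = as.Date("2012-01-01"),
    egfr_first = 100, egfr_last = 95, age_first = runif(n, 45, 75),
    span_years = 4, eligible = TRUE, reason = "eligible",
    decline = rnorm(n, 1, 0.3)
  )
  cover0 <- sapply(1:10, function(s) {
    perm <- dplyr::mutate(base, decline = sample(decline))
    td <- tidy(decline_regression(perm, cov, "lifestyle"))
    td <- td[td$term != "(Intercept)", ]
    mean(td$conf.low <= 0 & 0 <= td$conf.high)
  })
  expect_gte(mean(cover0), 0.9)
})
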