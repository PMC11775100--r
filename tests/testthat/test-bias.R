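test_that("pairing picks the same-year eMR value closest to the SC draw", {
  sc <- make_creatinine("A", "2008-06-01", 75, source = "SC")
  emr <- make_creatinine("A", c("2008-05-20", "2008-09-01"), c(80, 90))
  p <- pair_same_year(sc, emr)
  expect_equal(p$emr_date, as.Date("2008-05-20"))
  expect_equal(p$emr_value, 80)

  # tie in closeness broken by the earlier date
  emr_tie <- make_creatinine("A", c("2008-05-22", "2008-06-11"), c(81, 91))
  expect_equal(pair_same_year(sc, emr_tie)$emr_date, as.Date("2008-05-22"))

  # no cross-year pairing
  emr_06 <- make_creatinine("A", "2006-06-01", 80)
  expect_equal(nrow(pair_same_year(sc, emr_06)), 0)
})

test_that("persons without a same-year eMR value are omitted", {
  sc <- make_creatinine(LETTERS[1:5], rep("2008-06-01", 5), 70 + 1:5,
                       source = "SC")
  emr <- make_creatinine(c("A", "B", "C", "D"),
                         c("2008-03-01", "2008-04-01", "2009-05-01",
                           "2007-12-31"),
                         c(80, 81, 82, 83))
  p <- pair_same_year(sc, emr)
  expect_equal(nrow(p), 2)
  expect_setequal(p$person_id, c("A", "B"))
})

test_that("the factor is the ratio of geometric means (identity and forced cases)", {
  p_id <- simulate_pairs(200, factor = 1)
  p_id$emr_value <- p_id$sc_value
  est <- estimate_year_bias(p_id, min_pairs = 100)
  expect_equal(est$factor, 1, tolerance = 1e-12)
  expect_equal(est$spearman, 1)

  p_forced <- p_id
  p_forced$emr_value <- p_forced$sc_value / 0.84
  est2 <- estimate_year_bias(p_forced, min_pairs = 100)
  expect_equal(est2$factor, 0.84, tolerance = 1e-12)
  expect_equal(est2$log_bias, -log(0.84), tolerance = 1e-12)
})

test_that("the estimator recovers an injected factor from the lognormal model", {
  set.seed(101)
  p <- simulate_pairs(5000, factor = 0.90)
  est <- estimate_year_bias(p)
  expect_equal(est$factor, 0.90, tolerance = 0.011)  # within ±0.01
  expect_equal(est$n_pairs, 5000)
})

test_that("years below the minimum pair count are not estimated", {
  p <- dplyr::bind_rows(simulate_pairs(150, 0.9, year = 2008),
                        simulate_pairs(50, 0.95, year = 2009))
  est <- estimate_year_bias(p, min_pairs = 100)
  expect_equal(est$year, 2008)
})

test_that("winsorization tempers a gross outlier", {
  set.seed(102)
  clean <- simulate_pairs(500, factor = 0.90)
  est_clean <- estimate_year_bias(clean, min_pairs = 100)$factor
  dirty <- clean
  dirty$emr_value[1] <- dirty$emr_value[1] * 100
  est_plain <- estimate_year_bias(dirty, min_pairs = 100)$factor
  est_wins <- estimate_year_bias(dirty, winsorize = TRUE,
                                 min_pairs = 100)$factor
  expect_lt(abs(est_wins - est_clean), abs(est_plain - est_clean))
})

test_that("factors are invariant to a common rescaling of all values", {
  set.seed(103)
  p <- simulate_pairs(300, factor = 0.88)
  f1 <- estimate_year_bias(p, min_pairs = 100)$factor
  p2 <- dplyr::mutate(p, sc_value = sc_value * 7.3, emr_value = emr_value * 7.3)
  f2 <- estimate_year_bias(p2, min_pairs = 100)$factor
  expect_equal(f1, f2, tolerance = 1e-12)
})

printed_estimates <- function() {
  tibble::tibble(year = c(2007:2010, 2012, 2013),
                 factor = c(0.84, 0.84, 0.90, 0.91, 0.95, 0.97))
}

test_that("the bias table fills gaps and boundaries by the documented rules", {
  bt <- build_bias_table(printed_estimates(), year_range = c(1999, 2016))
  lookup <- function(y) bt[bt$year == y, ]
  # interior gap: exp of the mean of the adjacent log biases
  expect_equal(round(lookup(2011)$factor, 2), 0.93)
  expect_equal(lookup(2011)$factor, exp(mean(log(c(0.91, 0.95)))))
  expect_equal(lookup(2011)$provenance, "interpolated")
  # years before the first estimate carry its factor
  expect_equal(lookup(1999)$factor, 0.84)
  expect_equal(lookup(1999)$provenance, "boundary_carry")
  # trailing years: last estimate 0.97 is within 0.05 of unity -> no correction
  expect_equal(lookup(2015)$factor, 1.0)
  expect_equal(lookup(2016)$provenance, "unity")
  # every year of the span covered
  expect_equal(bt$year, 1999:2016)
  expect_true(all(bt$factor > 0))
})

test_that("trailing years carry the last factor when it is far from unity", {
  est <- tibble::tibble(year = c(2007, 2008), factor = c(0.84, 0.85))
  bt <- build_bias_table(est, year_range = c(2007, 2012))
  expect_equal(bt$factor[bt$year == 2012], 0.85)
  expect_equal(bt$provenance[bt$year == 2012], "boundary_carry")
})

test_that("interpolation is consistent and linear in log over multi-year gaps", {
  est <- tibble::tibble(year = c(2005, 2008), factor = c(0.9, 0.9))
  bt <- build_bias_table(est)
  expect_equal(bt$factor[bt$year %in% 2006:2007], c(0.9, 0.9))
  est2 <- tibble::tibble(year = c(2005, 2008), factor = c(0.8, 1.0))
  bt2 <- build_bias_table(est2)
  expect_equal(log(bt2$factor),
               seq(log(0.8), log(1.0), length.out = 4))
  expect_error(build_bias_table(printed_estimates()[0, ]), "No estimated years")
})

test_that("correction multiplies eMR values by the year factor and spares SC", {
  bt <- build_bias_table(printed_estimates(), year_range = c(1999, 2016))
  rec <- dplyr::bind_rows(
    make_creatinine("A", "2007-05-01", 100),
    make_creatinine("A", "2015-05-01", 100),
    make_creatinine("B", "2007-05-01", 100, source = "SC")
  )
  out <- apply_bias_correction(rec, bt)
  expect_equal(out$value, c(84, 100, 100))
  expect_equal(out$value_raw, c(100, 100, 100))
  expect_equal(out$bias_corrected, c(TRUE, TRUE, FALSE))
  # uncovered year errors and names the year
  rec_old <- make_creatinine("A", "1990-01-01", 100)
  expect_error(apply_bias_correction(rec_old, bt), "1990")
})

test_that("correct-then-re-estimate returns a factor of exactly one on the paired subset", {
  set.seed(104)
  p <- simulate_pairs(400, factor = 0.87)
  est <- estimate_year_bias(p, min_pairs = 100)
  p_corr <- dplyr::mutate(p, emr_value = emr_value * est$factor)
  expect_equal(estimate_year_bias(p_corr, min_pairs = 100)$factor, 1,
               tolerance = 1e-12)
})
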