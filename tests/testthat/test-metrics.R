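test_that("tabulation counts every pattern and conserves the total", {
  coh <- data.frame(status = rep(1L, 4), X = c(0, 1, 0, 1), Z = c(0, 0, 1, 1))
  tab <- tabulate_cohort(coh, c("X", "Z"))
  expect_equal(tab$n_case, rep(1L, 4))
  expect_equal(tab$n_control, rep(0L, 4))
  expect_equal(sum(tab$n_case + tab$n_control), nrow(coh))

  empty <- coh[0, ]
  tab0 <- tabulate_cohort(empty, c("X", "Z"))
  expect_equal(sum(tab0$n_case + tab0$n_control), 0)

  bad <- data.frame(status = 1L, X = 2, Z = 0)
  expect_error(tabulate_cohort(bad, c("X", "Z")), "binary")
})

test_that("odds ratios match the direct cross-product formula", {
  # cases (00,10,01,11) = (10,20,15,30), controls = (30,20,15,10)
  tab <- counts_table(cases = c(10, 20, 15, 30), controls = c(30, 20, 15, 10))
  est <- odds_ratios(tab)
  expect_equal(est$or_11, 9)
  expect_equal(est$or_10, 3)
  expect_equal(est$or_01, 3)
  expect_equal(est$expected_additive, 5)
  expect_equal(est$expected_multiplicative, 9)
  expect_equal(est$amles, 1)
  expect_true(est$valid)

  flat <- counts_table(cases = c(40, 10, 20, 5), controls = c(40, 10, 20, 5))
  f <- odds_ratios(flat)
  expect_equal(c(f$or_01, f$or_10, f$or_11), c(1, 1, 1))
})

test_that("the minimum-cell filter flags sparse tables", {
  tab <- counts_table(cases = c(10, 20, 15, 4), controls = c(30, 20, 15, 10))
  expect_false(odds_ratios(tab, min_cell = 5)$valid)
  expect_true(odds_ratios(tab, min_cell = 4)$valid)
  # ratios still reported when computable
  expect_false(is.na(odds_ratios(tab, min_cell = 5)$or_11))
})

test_that("relative risks are case-probability ratios", {
  # P(case|11) = 0.10, P(case|00) = 0.02 -> RR11 = 5
  tab <- counts_table(cases = c(20, 30, 30, 50), controls = c(980, 470, 470, 450))
  est <- relative_risks(tab)
  expect_equal(est$rr_11, 5)
  # at low prevalence RR approaches OR
  o <- odds_ratios(tab, min_cell = 0)
  expect_lt(abs(o$or_11 / est$rr_11 - 1), 0.12)
})

test_that("AMLES anchors at 0 for additive and 1 for multiplicative", {
  expect_equal(amles(6, 2, 3), 1)
  expect_equal(amles(4, 2, 3), 0)
  expect_equal(amles(5, 2, 3), 0.5)
  expect_true(is.na(amles(5, 1, 3)))       # degenerate denominator
  expect_true(is.na(amles(5, 1 + 1e-12, 3)))
})

test_that("f_est is the signed square and f_thr the scaled threshold", {
  expect_equal(f_est(c(1, 0, -0.5)), c(1, 0, -0.25))
  expect_equal(f_thr(1, 5)$f_thr, 0)
  expect_equal(f_thr(5, 5)$f_thr, 1)
  expect_equal(f_thr(3, 5)$f_thr, 0.5)
  expect_equal(f_thr(2, 2)$f_thr, 1)
  expect_error(f_thr(6, 5), "t <= F")
  # square-root relationship: AMLES = sqrt(f_thr) implies f_est = f_thr
  for (t in 1:5) expect_equal(f_est(sqrt(f_thr(t, 5)$f_thr)), f_thr(t, 5)$f_thr)
})

test_that("the interpolated OR11 runs from additive to multiplicative", {
  expect_equal(predicted_or11(2, 3, 0), 4)
  expect_equal(predicted_or11(2, 3, 1), 6)
  expect_equal(predicted_or11(2, 3, 0.25), 5)
  expect_error(predicted_or11(2, 3, 1.5), "0, 1")
  # monotone in f whenever (OR10-1)(OR01-1) > 0
  f_grid <- seq(0, 1, by = 0.05)
  vals <- predicted_or11(1.7, 2.4, f_grid)
  expect_true(all(diff(vals) > 0))
})

test_that("RERI vanishes under additivity and links to AMLES algebraically", {
  expect_equal(reri(6, 2, 3), 2)
  expect_equal(reri(4, 2, 3), 0)
  set.seed(97)
  for (i in 1:500) {
    or10 <- runif(1, 0.2, 6); or01 <- runif(1, 0.2, 6); or11 <- runif(1, 0.05, 30)
    a <- amles(or11, or10, or01, tol = 1e-6)
    if (is.na(a)) next
    expect_lt(abs((or11 - or10 - or01 + 1) - a * (or10 - 1) * (or01 - 1)), 1e-10)
    expect_equal(a, reri(or11, or10, or01) / ((or10 - 1) * (or01 - 1)))
  }
})

test_that("stratified correlations behave at the extremes", {
  dup <- data.frame(status = rep(c(1L, 0L), each = 50),
                    X = rep(c(0L, 1L), 50))
  dup$Z <- dup$X
  co <- stratified_correlation(dup, "X", "Z")
  expect_equal(unname(co), c(1, 1, 1))

  set.seed(13)
  ind <- data.frame(status = rbinom(20000, 1, 0.3),
                    X = rbinom(20000, 1, 0.2), Z = rbinom(20000, 1, 0.4))
  co2 <- stratified_correlation(ind, "X", "Z")
  expect_true(all(abs(co2) < 0.05))

  const <- data.frame(status = c(1L, 1L, 0L, 0L), X = c(1L, 1L, 1L, 0L), Z = c(0L, 1L, 0L, 1L))
  co3 <- stratified_correlation(const, "X", "Z")
  expect_true(is.na(co3[["cases"]]))  # X constant among cases
})
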