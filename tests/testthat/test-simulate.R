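test_that("identical spec and seed give byte-identical cohorts", {
  for (logic in c("AND", "CONFOUNDER_II", "ADDITIVE_O")) {
    set.seed(31)
    s1 <- scenario_spec(logic, 0.1, n_individuals = 5000)
    c1 <- simulate_cohort(s1)
    set.seed(31)
    s2 <- scenario_spec(logic, 0.1, n_individuals = 5000)
    c2 <- simulate_cohort(s2)
    expect_identical(c1, c2)
  }
})

test_that("the case-control split is exact for every scenario", {
  set.seed(17)
  for (logic in c("AND", "OR", "THRESHOLD", "THREE_FACTOR", "CONFOUNDER_I",
                  "ADDITIVE_O", "ADDITIVE_R")) {
    spec <- scenario_spec(logic, 0.03, n_individuals = 10000,
                          threshold = if (logic == "THRESHOLD") 3L else NULL)
    coh <- simulate_cohort(spec)
    expect_equal(sum(coh$status), round(10000 * 0.03))
    expect_equal(nrow(coh), 10000)
  }
})

test_that("an unattainable prevalence tolerance triggers a warning", {
  spec <- scenario_spec("AND", 0.0005, factors = fixed_factors(),
                        n_individuals = 100, prevalence_tolerance = 4e-4)
  expect_warning(simulate_cohort(spec), "realized prevalence")
})

test_that("factors with no frequency contrast are unassociated with the outcome", {
  set.seed(23)
  flat <- list(factor_spec("X", 0.2, 0.2, 1L), factor_spec("Z", 0.1, 0.1, 2L))
  spec <- scenario_spec("AND", 0.2, factors = flat, n_individuals = 50000)
  est <- odds_ratios(tabulate_cohort(simulate_cohort(spec)))
  expect_lt(abs(log(est$or_10)), 0.15)
  expect_lt(abs(log(est$or_01)), 0.15)
  expect_lt(abs(log(est$or_11)), 0.2)
})

test_that("simulated cell frequencies match the enumeration oracle", {
  # one representative component scenario and one pool scenario; the full
  # scenario sweep is exercised in the acceptance suite
  set.seed(41)
  for (logic in c("THRESHOLD", "CONFOUNDER_I")) {
    spec <- scenario_spec(logic, 0.05, n_individuals = 1e5,
                          threshold = if (logic == "THRESHOLD") 2L else NULL)
    coh <- simulate_cohort(spec)
    tab <- tabulate_cohort(coh)
    pr <- oracle_cell_probabilities(spec)
    obs <- c(tab$n_control, tab$n_case) / nrow(coh)
    expected <- c(pr$prob[pr$status == 0], pr$prob[pr$status == 1])
    se <- sqrt(expected * (1 - expected) / nrow(coh))
    expect_true(all(abs(obs - expected) <= 4 * se + 1e-12))
  }
})

test_that("synergism gives multiplicative and additive-R additive relations exactly on the oracle", {
  spec <- scenario_spec("AND", 0.2, factors = fixed_factors())
  rr <- relative_risks(oracle_expected_table(spec))
  expect_equal(rr$rr_11, rr$rr_10 * rr$rr_01, tolerance = 1e-12)

  add <- scenario_spec("ADDITIVE_R", 0.05,
                       factors = list(factor_spec("X", 0.1, 0.1), factor_spec("Z", 0.1, 0.1)),
                       rr_x = 1.8, rr_z = 2.5)
  rr2 <- relative_risks(oracle_expected_table(add))
  expect_equal(rr2$reri, 0, tolerance = 1e-12)
  expect_equal(rr2$rr_10, 1.8, tolerance = 1e-12)

  addo <- scenario_spec("ADDITIVE_O", 0.2, factors = fixed_factors())
  or2 <- odds_ratios(oracle_expected_table(addo), min_cell = 0)
  expect_equal(or2$or_11, or2$or_10 + or2$or_01 - 1, tolerance = 1e-12)
})

test_that("heterogeneity induces negative case-only correlation without subsampling", {
  set.seed(59)
  spec <- scenario_spec("OR", 0.01, factors = fixed_factors(z_high = 0.4),
                        n_individuals = 2e5)
  co <- stratified_correlation(simulate_cohort(spec))
  expect_lt(co[["cases"]], -0.01)
  expect_lt(abs(co[["controls"]]), 0.01)
})

test_that("confounder pools keep factors independent within status", {
  set.seed(61)
  spec <- scenario_spec("CONFOUNDER_I", 0.5, factors = fixed_factors(),
                        n_individuals = 1e5)
  co <- stratified_correlation(simulate_cohort(spec))
  expect_lt(abs(co[["cases"]]), 0.02)
  expect_lt(abs(co[["controls"]]), 0.02)
})

test_that("subsampling keeps all cases and equalizes group sizes", {
  set.seed(73)
  spec <- scenario_spec("AND", 0.1, factors = fixed_factors(), n_individuals = 5000)
  coh <- simulate_cohort(spec)
  sub <- subsample_case_control(coh)
  expect_equal(sum(sub$status == 1), sum(coh$status == 1))
  expect_equal(sum(sub$status == 0), sum(sub$status == 1))
  expect_true(all(sub$id[sub$status == 1] %in% coh$id[coh$status == 1]))

  few_controls <- coh[c(which(coh$status == 1), which(coh$status == 0)[1:10]), ]
  expect_error(subsample_case_control(few_controls), "fewer controls")
  no_cases <- coh[coh$status == 0, ]
  expect_error(subsample_case_control(no_cases), "no cases")
})

test_that("threshold logic collapses to OR at t=1 and AND at t=F on the oracle", {
  f <- fixed_factors()
  for (prev in c(0.01, 0.2)) {
    thr1 <- scenario_spec("THRESHOLD", prev, factors = f, n_components = 2, threshold = 1)
    or_s <- scenario_spec("OR", prev, factors = f)
    expect_equal(oracle_cell_probabilities(thr1)$prob,
                 oracle_cell_probabilities(or_s)$prob, tolerance = 1e-7)
    thr2 <- scenario_spec("THRESHOLD", prev, factors = f, n_components = 2, threshold = 2)
    and_s <- scenario_spec("AND", prev, factors = f)
    expect_equal(oracle_cell_probabilities(thr2)$prob,
                 oracle_cell_probabilities(and_s)$prob, tolerance = 1e-7)
  }
})
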