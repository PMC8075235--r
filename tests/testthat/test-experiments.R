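test_that("experiments are deterministic given the master seed", {
  e1 <- run_experiment("AND", prevalence_grid = 0.1, n_replicates = 2,
                       n_individuals = 2000, seed = 5)
  e2 <- run_experiment("AND", prevalence_grid = 0.1, n_replicates = 2,
                       n_individuals = 2000, seed = 5)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$summaries, e2$summaries)
  e3 <- run_experiment("AND", prevalence_grid = 0.1, n_replicates = 2,
                       n_individuals = 2000, seed = 6)
  expect_false(identical(e1$replicates$or_11, e3$replicates$or_11))
})

test_that("replicate rows carry both OR (subsampled) and RR (full) metrics", {
  ex <- run_experiment("OR", prevalence_grid = c(0.1, 0.3), n_replicates = 3,
                       n_individuals = 20000, seed = 2)
  expect_equal(nrow(ex$replicates), 6)
  expect_true(all(c("or_11", "rr_11", "amles", "amles_rr", "corr_all",
                    "corr_all_full", "valid") %in% names(ex$replicates)))
  expect_setequal(unique(ex$summaries$prevalence), c(0.1, 0.3))
})

test_that("bootstrap interval brackets the median and quartiles are ordered", {
  set.seed(3)
  x <- rlnorm(200)
  ci <- bootstrap_median_ci(x, n_boot = 500)
  expect_lte(ci$lower, ci$median)
  expect_gte(ci$upper, ci$median)
  s <- summarize_replicates(data.frame(prevalence = 0.1, amles = x, valid = TRUE))
  row <- s[s$metric == "amles", ]
  expect_lte(row$q1, row$median)
  expect_gte(row$q3, row$median)
})

test_that("invalid replicates are excluded from OR-based summaries with a warning when dominant", {
  reps <- data.frame(prevalence = 0.1, amles = c(0, 0, 100, 100),
                     valid = c(TRUE, TRUE, FALSE, FALSE))
  s <- summarize_replicates(reps, n_boot = 50)
  expect_equal(s$median[s$metric == "amles"], 0)
  expect_equal(s$n_excluded[s$metric == "amles"], 2)
  reps$valid <- c(TRUE, FALSE, FALSE, FALSE)
  expect_warning(summarize_replicates(reps, n_boot = 50), "minimum-cell")
})

test_that("the eight three-factor compositions follow their causal formulas", {
  r1 <- 2; r2 <- 3; r3 <- 4
  # exercised through three_factor_fit on a table with exactly known RRs:
  # risks 0.01 (ref), and RRs r1, r2, r3 for single exposures; triple set to
  # the X AND (Z OR V) composition so (mult,mult,add) is exact.
  n <- 1e6
  risks <- c(`000` = 0.01, `100` = 0.01 * r1, `010` = 0.01 * r2, `001` = 0.01 * r3,
             `110` = 0.01 * r1 * r2, `101` = 0.01 * r1 * r3, `011` = 0.01 * (r2 + r3 - 1),
             `111` = 0.01 * r1 * (r2 + r3 - 1))
  pat <- expand.grid(X = 0:1, Z = 0:1, V = 0:1)
  key <- apply(pat, 1, paste0, collapse = "")
  cell_n <- rep(n / 8, 8)
  tab3 <- structure(
    data.frame(pat, n_control = cell_n * (1 - risks[key]), n_case = cell_n * risks[key]),
    class = c("interaction_table", "data.frame"), factors = c("X", "Z", "V"))
  fit <- three_factor_fit(tab3)
  best <- fit[1, ]
  expect_equal(c(best$xz, best$xv, best$zv), c("mult", "mult", "add"))
  expect_equal(best$abs_log_error, 0, tolerance = 1e-12)
  pick <- function(a, b, c) fit$rr_111_expected[fit$xz == a & fit$xv == b & fit$zv == c]
  expect_equal(pick("mult", "mult", "mult"), r1 * r2 * r3)
  expect_equal(pick("add", "add", "add"), r1 + r2 + r3 - 2)
  expect_equal(pick("mult", "mult", "add"), r1 * (r2 + r3 - 1))
  expect_equal(pick("mult", "add", "mult"), r2 * (r1 + r3 - 1))
  expect_equal(pick("add", "mult", "mult"), r3 * (r1 + r2 - 1))
  expect_equal(pick("add", "add", "mult"), r1 + r2 * r3 - 1)
  expect_equal(pick("add", "mult", "add"), r2 + r1 * r3 - 1)
  expect_equal(pick("mult", "add", "add"), r3 + r1 * r2 - 1)
})

test_that("the (mult,mult,add) composition is centred on the noise-free truth at low prevalence", {
  # exact enumeration in place of simulation: the distribution of
  # log(observed/expected) for the correct decomposition across frequency
  # draws should be tightly centred near zero
  set.seed(47)
  errs <- vapply(1:100, function(i) {
    spec <- scenario_spec("THREE_FACTOR", 0.005)
    fit <- three_factor_fit(oracle_expected_table(spec))
    row <- fit[fit$xz == "mult" & fit$xv == "mult" & fit$zv == "add", ]
    log(row$rr_111_observed / row$rr_111_expected)
  }, 0)
  expect_lt(abs(median(errs)), 0.10)
  expect_lt(max(abs(errs)), 0.25)
})

test_that("a null three-factor table yields an eight-way tie", {
  pat <- expand.grid(X = 0:1, Z = 0:1, V = 0:1)
  tab3 <- structure(data.frame(pat, n_control = rep(90, 8), n_case = rep(10, 8)),
                    class = c("interaction_table", "data.frame"),
                    factors = c("X", "Z", "V"))
  fit <- three_factor_fit(tab3)
  expect_true(attr(fit, "tie"))
  expect_true(all(fit$rr_111_expected == 1))
})

test_that("correlation sign labels use the dead-band", {
  reps <- data.frame(prevalence = rep(0.1, 3),
                     corr_all = c(0.05, 0.06, 0.04),
                     corr_cases = c(-0.2, -0.25, -0.3),
                     corr_controls = c(0.001, -0.002, 0.003))
  s <- correlation_sign_summary(reps)
  expect_equal(s$sign[s$stratum == "all"], "+")
  expect_equal(s$sign[s$stratum == "cases"], "-")
  expect_equal(s$sign[s$stratum == "controls"], "0")
})

test_that("the threshold sweep reports f_thr alongside the medians", {
  sw <- threshold_sweep(F = 2, t_values = 1:2, prevalence = 0.1,
                        n_replicates = 2, n_individuals = 2000,
                        n_boot = 50, seed = 4)
  expect_equal(sw$f_thr, c(0, 1))
  expect_equal(sw$sqrt_f_thr, c(0, 1))
  expect_true(all(is.finite(sw$median_amles) | sw$n_used == 0))
})
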