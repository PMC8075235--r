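#' Bootstrap percentile confidence interval for the median
#'
#' Resamples the replicate-level values with replacement and returns the
#' percentile interval of the median, the boxplot-notch style summary used
#' throughout the experiment reports.
#'
#' @param x Numeric vector (NAs dropped).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @return A list with `median`, `lower`, `upper`, `n`.
#' @export
bootstrap_median_ci <- function(x, n_boot = 1000, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(list(median = NA_real_, lower = NA_real_, upper = NA_real_, n = 0L))
  med <- stats::median(x)
  if (n == 1L) return(list(median = med, lower = med, upper = med, n = 1L))
  boot <- vapply(seq_len(n_boot), function(i) {
    stats::median(x[sample.int(n, n, replace = TRUE)])
  }, 0)
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(median = med, lower = min(qs[1], med), upper = max(qs[2], med), n = n)
}

replicate_row <- function(spec, or_est, rr_est, corr_sub, corr_full, k, sub_seed) {
  fx <- spec$factors[[1]]; fz <- spec$factors[[2]]
  data.frame(
    prevalence = spec$prevalence, replicate = k, seed = sub_seed,
    x_low = fx$low_freq, x_high = fx$high_freq,
    z_low = fz$low_freq, z_high = fz$high_freq,
    clipped = any(vapply(spec$factors, `[[`, TRUE, "clipped")),
    or_01 = or_est$or_01, or_10 = or_est$or_10, or_11 = or_est$or_11,
    amles = or_est$amles, f_est = or_est$f_est, reri_or = or_est$reri,
    valid = or_est$valid, protective = or_est$protective,
    rr_01 = rr_est$rr_01, rr_10 = rr_est$rr_10, rr_11 = rr_est$rr_11,
    amles_rr = rr_est$amles, reri = rr_est$reri,
    corr_all = corr_sub[["all"]], corr_cases = corr_sub[["cases"]],
    corr_controls = corr_sub[["controls"]],
    corr_all_full = corr_full[["all"]], corr_cases_full = corr_full[["cases"]],
    corr_controls_full = corr_full[["controls"]]
  )
}

SUMMARY_METRICS <- c("or_11", "amles", "f_est", "reri_or", "rr_11", "amles_rr",
                     "reri", "corr_all", "corr_cases", "corr_controls",
                     "corr_all_full", "corr_cases_full", "corr_controls_full")
OR_BASED_METRICS <- c("or_11", "amles", "f_est", "reri_or")

#' Run replicate simulations over a prevalence grid
#'
#' For each prevalence in the grid, simulates `n_replicates` independent
#' cohorts with freshly drawn factor frequencies, computes relative-risk
#' metrics and correlations on the full cohort and odds-ratio metrics and
#' correlations on the equal-size subsampled cohort, and summarizes every
#' metric by its median, quartiles and a bootstrap confidence interval of
#' the median. Odds-ratio based metrics exclude replicates failing the
#' minimum cell-count filter.
#'
#' Each replicate runs in its own derived seed substream, so results are
#' deterministic given `seed` and any single replicate can be reproduced in
#' isolation.
#'
#' @param logic Scenario logic label (see [scenario_spec()]).
#' @param prevalence_grid Case fractions to simulate at.
#' @param n_replicates Replicates per grid point.
#' @param n_individuals Cohort size per replicate.
#' @param threshold Threshold t for THRESHOLD logic.
#' @param subsample Apply equal-size case-control subsampling before the
#'   odds-ratio metrics (default TRUE).
#' @param min_cell Minimum cell count for the odds-ratio validity filter.
#' @param n_boot Bootstrap resamples for the median confidence intervals.
#' @param seed Master seed.
#' @param prevalence_ratio Passed to CONFOUNDER_II scenarios.
#' @param compute_correlations Compute the stratified factor correlations
#'   per replicate (default TRUE; effect-scale-only experiments can skip
#'   them).
#' @return An `interaction_experiment`: list with `replicates` (one row per
#'   replicate) and `summaries` (one row per prevalence x metric).
#' @examples
#' exp <- run_experiment("AND", prevalence_grid = 0.05, n_replicates = 3,
#'                       n_individuals = 2000, seed = 1)
#' subset(exp$summaries, metric == "amles")
#' @export
run_experiment <- function(logic, prevalence_grid = c(0.005, 0.02, 0.10, 0.33, 0.50),
                           n_replicates = 1000, n_individuals = 1e6,
                           threshold = NULL, subsample = TRUE, min_cell = 5,
                           n_boot = 1000, seed = 1L, prevalence_ratio = 3,
                           compute_correlations = TRUE) {
  logic <- match.arg(logic, SCENARIO_LOGICS)
  if (logic == "THREE_FACTOR") {
    stop_input("use three_factor_experiment() for the three-factor scenario")
  }
  stopifnot(n_replicates >= 1, all(prevalence_grid > 0 & prevalence_grid < 1))
  reps <- vector("list", length(prevalence_grid) * n_replicates)
  r <- 0L
  for (i in seq_along(prevalence_grid)) {
    prev <- prevalence_grid[i]
    for (k in seq_len(n_replicates)) {
      sub_seed <- substream_seed(seed, i, k)
      set.seed(sub_seed)
      spec <- scenario_spec(logic, prev, n_individuals = n_individuals,
                            threshold = threshold, subsample = subsample,
                            prevalence_ratio = prevalence_ratio)
      coh <- simulate_cohort(spec)
      tab_full <- tabulate_cohort(coh)
      rr_est <- relative_risks(tab_full)
      no_corr <- c(all = NA_real_, cases = NA_real_, controls = NA_real_)
      corr_full <- if (compute_correlations) stratified_correlation(coh) else no_corr
      ana <- if (subsample) subsample_case_control(coh) else coh
      or_tab <- if (subsample) tabulate_cohort(ana) else tab_full
      or_est <- odds_ratios(or_tab, min_cell = min_cell)
      corr_sub <- if (compute_correlations) stratified_correlation(ana) else no_corr
      r <- r + 1L
      reps[[r]] <- replicate_row(spec, or_est, rr_est, corr_sub, corr_full, k, sub_seed)
    }
  }
  replicates <- do.call(rbind, reps)
  summaries <- summarize_replicates(replicates, n_boot = n_boot,
                                    seed = substream_seed(seed, 0L, 0L))
  structure(list(logic = logic, replicates = replicates, summaries = summaries,
                 n_individuals = n_individuals, subsample = subsample,
                 min_cell = min_cell, seed = seed),
            class = "interaction_experiment")
}

#' Summarize replicate metrics by prevalence
#'
#' Median, quartiles and bootstrap confidence interval of the median for
#' each metric at each prevalence. Odds-ratio based metrics use only
#' replicates passing the minimum-cell validity filter; excluded replicate
#' counts are reported. A grid point where more than half the replicates
#' are invalid triggers a warning.
#'
#' @param replicates Replicate data frame from [run_experiment()].
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame with one row per prevalence x metric.
#' @export
summarize_replicates <- function(replicates, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (prev in unique(replicates$prevalence)) {
    block <- replicates[replicates$prevalence == prev, , drop = FALSE]
    n_invalid <- sum(!block$valid)
    if (n_invalid > nrow(block) / 2) {
      warning(sprintf("prevalence %g: %d of %d replicates fail the minimum-cell filter",
                      prev, n_invalid, nrow(block)), call. = FALSE)
    }
    for (m in intersect(SUMMARY_METRICS, names(block))) {
      x <- block[[m]]
      if (m %in% OR_BASED_METRICS) x[!block$valid] <- NA
      ci <- bootstrap_median_ci(x, n_boot = n_boot)
      qs <- if (ci$n) stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE) else c(NA_real_, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        prevalence = prev, metric = m, median = ci$median,
        q1 = qs[1], q3 = qs[2], ci_lower = ci$lower, ci_upper = ci$upper,
        n_used = ci$n, n_excluded = nrow(block) - ci$n)
    }
  }
  do.call(rbind, out)
}

#' Sweep the multifactorial threshold t and track AMLES against sqrt(f_thr)
#'
#' Runs the THRESHOLD scenario for each t, at one prevalence, and reports
#' the median AMLES (with bootstrap confidence interval) next to the
#' threshold fraction `f_thr = (t-1)/(F-1)` and its square root — the
#' predicted position of the median on the additive-to-multiplicative
#' scale.
#'
#' @param F Number of components (default 5).
#' @param t_values Thresholds to sweep (default `1:F`).
#' @param prevalence Case fraction (default 0.005).
#' @param n_replicates Replicates per threshold (default 500, sized so the
#'   Monte Carlo error of each median is well below the scale's 0-to-1
#'   range; the intermediate thresholds have heavy-tailed replicate AMLES).
#' @param n_individuals Cohort size per replicate.
#' @param subsample Equal-size case-control subsampling before the odds
#'   ratios (default FALSE: the sweep uses the complete cohort, whose exact
#'   prevalence control and large control pool keep the heavy-tailed AMLES
#'   ratio stable enough for the median to track `sqrt(f_thr)`).
#' @param min_cell,n_boot,seed As in [run_experiment()].
#' @return Data frame with one row per t: `f_thr`, `sqrt_f_thr`,
#'   `median_amles`, quartiles, CI and replicate counts.
#' @export
threshold_sweep <- function(F = 5, t_values = seq_len(F), prevalence = 0.005,
                            n_replicates = 500, n_individuals = 1e6,
                            subsample = FALSE, min_cell = 5, n_boot = 1000,
                            seed = 1L) {
  rows <- lapply(seq_along(t_values), function(j) {
    t <- t_values[j]
    ex <- run_experiment("THRESHOLD", prevalence_grid = prevalence,
                         n_replicates = n_replicates,
                         n_individuals = n_individuals, threshold = t,
                         subsample = subsample, min_cell = min_cell,
                         n_boot = n_boot, seed = substream_seed(seed, 100L + j, 0L),
                         compute_correlations = FALSE)
    s <- ex$summaries[ex$summaries$metric == "amles", ]
    ft <- f_thr(t, F)$f_thr
    data.frame(t = t, F = F, f_thr = ft, sqrt_f_thr = sqrt(ft),
               median_amles = s$median, q1 = s$q1, q3 = s$q3,
               ci_lower = s$ci_lower, ci_upper = s$ci_upper,
               n_used = s$n_used, n_excluded = s$n_excluded)
  })
  do.call(rbind, rows)
}

# Expected RR_111 for a labelled triple (XZ, XV, ZV). Each of the eight
# label combinations corresponds to exactly one logical formula over the
# three factors, since mult stands for an AND relation and add for an OR:
# all-mult is X AND Z AND V, all-add is X OR Z OR V, two mults single out
# the factor shared by both mult pairs as the necessary one (e.g.
# (mult, mult, add) is X AND (Z OR V)), and two adds single out the factor
# shared by both add pairs as an independent alternative (e.g.
# (add, add, mult) is X OR (Z AND V)). AND arms compose by product of the
# relative risks, OR arms by sum minus one.
expected_rr111 <- function(rr_100, rr_010, rr_001, xz, xv, zv) {
  n_mult <- sum(c(xz, xv, zv) == "mult")
  r <- c(X = rr_100, Z = rr_010, V = rr_001)
  pair_members <- list(xz = c("X", "Z"), xv = c("X", "V"), zv = c("Z", "V"))
  labs <- c(xz = xz, xv = xv, zv = zv)
  if (n_mult == 3L) return(r[["X"]] * r[["Z"]] * r[["V"]])
  if (n_mult == 0L) return(r[["X"]] + r[["Z"]] + r[["V"]] - 2)
  if (n_mult == 2L) {
    hub <- Reduce(intersect, pair_members[labs == "mult"])
    others <- setdiff(names(r), hub)
    return(r[[hub]] * (r[[others[1]]] + r[[others[2]]] - 1))
  }
  hub <- Reduce(intersect, pair_members[labs == "add"])
  others <- setdiff(names(r), hub)
  r[[hub]] + r[[others[1]]] * r[[others[2]]] - 1
}

#' Rank the eight additive/multiplicative pairwise decompositions
#'
#' For a three-factor cohort, computes the relative risks of the single
#' exposures (`RR_100`, `RR_010`, `RR_001`) and the triple exposure
#' (`RR_111`), then scores each of the eight (XZ, XV, ZV) in {add, mult}^3
#' label combinations by composing an expected `RR_111` and measuring
#' `|log(observed / expected)|`. Under the scenario X AND (Z OR V) at low
#' prevalence the combination (mult, mult, add) should fit best.
#'
#' @param cohort A three-factor `cohort` (factors X, Z, V), or an
#'   `interaction_table` over three factors.
#' @return Data frame of the 8 combinations with expected values, absolute
#'   log errors, ranks, a `best` flag, and a `tie` attribute when the top
#'   score is shared.
#' @export
three_factor_fit <- function(cohort) {
  tab <- if (inherits(cohort, "interaction_table")) cohort else tabulate_cohort(cohort)
  cells <- table_cells(tab)
  if (cells$k != 3L) stop_input("three_factor_fit expects exactly three factors")
  ca <- cells$case; co <- cells$control
  risk <- function(key) ratio_or_na(ca[[key]], ca[[key]] + co[[key]])
  ref <- risk("000")
  rr <- function(key) ratio_or_na(risk(key), ref)
  rr_100 <- rr("100"); rr_010 <- rr("010"); rr_001 <- rr("001"); rr_111 <- rr("111")

  labels <- expand.grid(xz = c("add", "mult"), xv = c("add", "mult"),
                        zv = c("add", "mult"), stringsAsFactors = FALSE)
  expected <- mapply(function(xz, xv, zv) {
    if (anyNA(c(rr_100, rr_010, rr_001))) NA_real_
    else expected_rr111(rr_100, rr_010, rr_001, xz, xv, zv)
  }, labels$xz, labels$xv, labels$zv)
  err <- ifelse(is.na(expected) | expected <= 0 | is.na(rr_111) | rr_111 <= 0,
                NA_real_, abs(log(rr_111 / expected)))
  rk <- rank(err, ties.method = "min", na.last = "keep")
  rk[is.na(rk)] <- length(err) + 1L
  out <- data.frame(labels,
                    rr_100 = rr_100, rr_010 = rr_010, rr_001 = rr_001,
                    rr_111_observed = rr_111, rr_111_expected = expected,
                    abs_log_error = err, rank = rk,
                    best = rk == 1L & !is.na(err))
  tie <- sum(out$rank == 1L) > 1L
  attr(out, "tie") <- tie
  out[order(out$rank), ]
}

#' Replicate experiment for the three-factor decomposition
#'
#' Simulates the X AND (Z OR V) scenario repeatedly and records which of
#' the eight pairwise add/mult combinations fits the observed `RR_111`
#' best in each replicate, together with the fraction of replicates
#' recovering (mult, mult, add).
#'
#' @param n_replicates Number of replicates.
#' @param prevalence Case fraction (default 0.005).
#' @param n_individuals Cohort size per replicate.
#' @param seed Master seed.
#' @return List with `replicates` (best labels per replicate) and
#'   `fraction_mult_mult_add`.
#' @export
three_factor_experiment <- function(n_replicates = 100, prevalence = 0.005,
                                    n_individuals = 1e6, seed = 1L) {
  rows <- lapply(seq_len(n_replicates), function(k) {
    set.seed(substream_seed(seed, 1L, k))
    spec <- scenario_spec("THREE_FACTOR", prevalence, n_individuals = n_individuals)
    fit <- three_factor_fit(simulate_three_factor(spec))
    top <- fit[fit$rank == 1L, , drop = FALSE][1, ]
    data.frame(replicate = k, xz = top$xz, xv = top$xv, zv = top$zv,
               tie = attr(fit, "tie"), abs_log_error = top$abs_log_error)
  })
  replicates <- do.call(rbind, rows)
  hit <- with(replicates, xz == "mult" & xv == "mult" & zv == "add" & !tie)
  list(replicates = replicates, fraction_mult_mult_add = mean(hit))
}

#' Sign labels for median correlations
#'
#' Reduces the replicate correlation distributions of an experiment to the
#' sign of the median per stratum and prevalence: `"-"`, `"0"` or `"+"`,
#' with medians inside the dead-band reported as `"0"`.
#'
#' @param experiment An `interaction_experiment` (or its replicates data frame).
#' @param dead_band Absolute median below which the sign is called zero
#'   (default 0.01).
#' @param which `"subsampled"` for the analysis-sample correlations,
#'   `"full"` for the whole-cohort ones.
#' @return Data frame: prevalence, stratum, median correlation, sign.
#' @export
correlation_sign_summary <- function(experiment, dead_band = 0.01,
                                     which = c("subsampled", "full")) {
  which <- match.arg(which)
  reps <- if (inherits(experiment, "interaction_experiment")) experiment$replicates else experiment
  cols <- if (which == "full") {
    c(all = "corr_all_full", cases = "corr_cases_full", controls = "corr_controls_full")
  } else {
    c(all = "corr_all", cases = "corr_cases", controls = "corr_controls")
  }
  out <- list()
  for (prev in unique(reps$prevalence)) {
    block <- reps[reps$prevalence == prev, , drop = FALSE]
    for (s in names(cols)) {
      med <- stats::median(block[[cols[[s]]]], na.rm = TRUE)
      sign_lab <- if (is.na(med)) NA_character_
                  else if (abs(med) < dead_band) "0"
                  else if (med > 0) "+" else "-"
      out[[length(out) + 1L]] <- data.frame(
        prevalence = prev, stratum = s, median_correlation = med, sign = sign_lab)
    }
  }
  do.call(rbind, out)
}
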