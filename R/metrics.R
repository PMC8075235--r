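#' Tabulate a cohort into a factor-pattern by outcome table
#'
#' Counts individuals for every combination of the named binary factors,
#' split by case/control status. All 2^k patterns are present, including
#' empty cells.
#'
#' @param cohort A `cohort` or data frame with a 0/1 `status` column.
#' @param factors Character vector of factor column names (defaults to the
#'   cohort's recorded factors).
#' @return An `interaction_table`: a data frame with one 0/1 column per
#'   factor plus `n_control` and `n_case` counts.
#' @examples
#' coh <- data.frame(status = c(1, 1, 0, 0), X = c(1, 0, 1, 0), Z = c(1, 1, 0, 0))
#' tabulate_cohort(coh, c("X", "Z"))
#' @export
tabulate_cohort <- function(cohort, factors = attr(cohort, "factor_names")) {
  if (is.null(factors)) stop_input("factor column names must be supplied")
  missing_cols <- setdiff(c("status", factors), names(cohort))
  if (length(missing_cols)) {
    stop_input("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  k <- length(factors)
  vals <- as.matrix(cohort[, factors, drop = FALSE])
  if (nrow(vals) && any(vals != 0L & vals != 1L)) {
    stop_input("factor columns must be binary 0/1")
  }
  patterns <- factor_patterns(k, factors)
  idx <- if (nrow(vals)) 1L + as.integer(vals %*% 2^(seq_len(k) - 1L)) else integer(0)
  n_cells <- nrow(patterns)
  tab <- data.frame(patterns,
    n_control = tabulate(idx[cohort$status == 0L], n_cells),
    n_case = tabulate(idx[cohort$status == 1L], n_cells))
  structure(tab, class = c("interaction_table", "data.frame"), factors = factors)
}

table_cells <- function(tab) {
  k <- length(attr(tab, "factors"))
  key <- apply(tab[, seq_len(k), drop = FALSE], 1L, paste0, collapse = "")
  list(case = stats::setNames(tab$n_case, key),
       control = stats::setNames(tab$n_control, key), k = k)
}

ratio_or_na <- function(num, den) ifelse(is.na(den) | den == 0, NA_real_, num / den)

new_effect_estimates <- function(scale, e01, e10, e11, valid, reri_val = NA_real_) {
  exp_add <- e10 + e01 - 1
  exp_mult <- e10 * e01
  a <- amles(e11, e10, e01)
  aliases <- stats::setNames(list(e01, e10, e11), paste0(scale, c("_01", "_10", "_11")))
  structure(c(list(
    scale = scale,
    estimate_01 = e01, estimate_10 = e10, estimate_11 = e11), aliases, list(
    expected_additive = exp_add, expected_multiplicative = exp_mult,
    amles = a, f_est = f_est(a),
    reri = if (is.na(reri_val)) e11 - e10 - e01 + 1 else reri_val,
    protective = isTRUE(!is.na(e10) && !is.na(e01) && (e10 < 1 || e01 < 1)),
    valid = valid
  )), class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  lab <- toupper(x$scale)
  cat(sprintf("%s_10 = %.4f, %s_01 = %.4f, %s_11 = %.4f\n",
              lab, x$estimate_10, lab, x$estimate_01, lab, x$estimate_11))
  cat(sprintf("expected additive = %.4f, expected multiplicative = %.4f\n",
              x$expected_additive, x$expected_multiplicative))
  cat(sprintf("AMLES = %.4f, f_est = %.4f, RERI = %.4f, valid = %s\n",
              x$amles, x$f_est, x$reri, x$valid))
  if (x$protective) cat("note: a single-factor estimate is below 1; AMLES interpretation is not established for protective factors\n")
  invisible(x)
}

#' @export
as.data.frame.effect_estimates <- function(x, ...) {
  nm <- paste0(x$scale, c("_01", "_10", "_11"))
  out <- data.frame(x$estimate_01, x$estimate_10, x$estimate_11,
                    x$expected_additive, x$expected_multiplicative,
                    x$amles, x$f_est, x$reri, x$protective, x$valid)
  names(out) <- c(nm, "expected_additive", "expected_multiplicative",
                  "amles", "f_est", "reri", "protective", "valid")
  out
}

#' Odds ratios for the two-factor exposure combinations
#'
#' Computes `OR_01`, `OR_10` and `OR_11` against the doubly-unexposed
#' reference cell (`OR_00 = 1`), plus the additive and multiplicative
#' expectations, AMLES, its signed square and the OR-scale RERI. A minimum
#' cell-count filter is applied: if any of the 8 cells holds fewer than
#' `min_cell` individuals the estimate is flagged `valid = FALSE` (ratios
#' are still reported where computable).
#'
#' @param tab An `interaction_table` over exactly two factors.
#' @param min_cell Minimum count required in every cell (default 5).
#' @return An `effect_estimates` object.
#' @examples
#' coh <- data.frame(
#'   status = rep(c(1, 0), c(75, 75)),
#'   X = c(rep(c(1, 1, 0, 0), c(30, 20, 15, 10)), rep(c(1, 1, 0, 0), c(10, 20, 15, 30))),
#'   Z = c(rep(c(1, 0, 1, 0), c(30, 20, 15, 10)), rep(c(1, 0, 1, 0), c(10, 20, 15, 30))))
#' odds_ratios(tabulate_cohort(coh, c("X", "Z")))
#' @export
odds_ratios <- function(tab, min_cell = 5) {
  cells <- table_cells(tab)
  if (cells$k != 2L) stop_input("odds_ratios expects a two-factor table")
  ca <- cells$case; co <- cells$control
  valid <- all(c(ca, co) >= min_cell)
  ref_odds <- ratio_or_na(ca[["00"]], co[["00"]])
  or <- function(key) ratio_or_na(ratio_or_na(ca[[key]], co[[key]]), ref_odds)
  new_effect_estimates("or", or("01"), or("10"), or("11"), valid)
}

#' Relative risks for the two-factor exposure combinations
#'
#' Computes `RR_01`, `RR_10`, `RR_11` — the case probability of each
#' exposure pattern relative to the doubly-unexposed reference — plus the
#' additive and multiplicative expectations, AMLES and RERI. This is the
#' appropriate population-scale measure for cohorts that were not
#' subsampled by outcome.
#'
#' @param tab An `interaction_table` over exactly two factors.
#' @param min_cell Minimum count per cell for the validity flag (default 0,
#'   i.e. no filter).
#' @return An `effect_estimates` object.
#' @export
relative_risks <- function(tab, min_cell = 0) {
  cells <- table_cells(tab)
  if (cells$k != 2L) stop_input("relative_risks expects a two-factor table")
  ca <- cells$case; co <- cells$control
  valid <- all(c(ca, co) >= min_cell)
  risk <- function(key) ratio_or_na(ca[[key]], ca[[key]] + co[[key]])
  ref <- risk("00")
  rr <- function(key) ratio_or_na(risk(key), ref)
  new_effect_estimates("rr", rr("01"), rr("10"), rr("11"), valid)
}

#' Additive-to-multiplicative linear effect scale
#'
#' `AMLES = (OR11 - expected_additive) / (expected_multiplicative -
#' expected_additive)` with `expected_additive = OR10 + OR01 - 1` and
#' `expected_multiplicative = OR10 x OR01`. The scale is anchored at 0 for
#' an exactly additive joint effect and 1 for an exactly multiplicative
#' one; values outside \[0, 1\] are possible. The denominator equals
#' `(OR10 - 1) (OR01 - 1)`; when its magnitude falls below `tol` the
#' estimate is undefined and `NA` is returned.
#'
#' @param or_11,or_10,or_01 Observed ratios (OR or RR scale); vectorized.
#' @param tol Degenerate-denominator tolerance (default 1e-9).
#' @return AMLES value(s); `NA` where undefined.
#' @examples
#' amles(6, 2, 3)  # 1: multiplicative
#' amles(4, 2, 3)  # 0: additive
#' amles(5, 2, 3)  # 0.5
#' @export
amles <- function(or_11, or_10, or_01, tol = 1e-9) {
  den <- (or_10 - 1) * (or_01 - 1)
  num <- or_11 - (or_10 + or_01 - 1)
  out <- ifelse(is.na(den) | abs(den) < tol, NA_real_, num / den)
  unname(out)
}

#' Signed square of AMLES
#'
#' `f_est = sign(AMLES) x AMLES^2`, the estimate on the threshold-fraction
#' scale: when the median AMLES equals `sqrt(f_thr)`, the median `f_est`
#' recovers `f_thr` itself.
#'
#' @param amles_value AMLES value(s).
#' @return `f_est` value(s).
#' @examples
#' f_est(c(1, 0, -0.5))
#' @export
f_est <- function(amles_value) sign(amles_value) * amles_value^2

#' Scaled threshold fraction
#'
#' `f_thr = (t - 1) / (F - 1)` maps the multifactorial threshold t of F
#' components onto \[0, 1\]: 0 at t = 1 (any component suffices,
#' heterogeneity) and 1 at t = F (all required, synergism).
#'
#' @param t Threshold, integer with `1 <= t <= F`.
#' @param F Number of components, `F >= 2`.
#' @return A list with `t`, `F` and `f_thr`.
#' @examples
#' f_thr(3, 5)$f_thr  # 0.5
#' @export
f_thr <- function(t, F) {
  t <- as.integer(t); F <- as.integer(F)
  if (any(is.na(t)) || any(is.na(F)) || any(F < 2L) || any(t < 1L) || any(t > F)) {
    stop_input("need 1 <= t <= F and F >= 2")
  }
  list(t = t, F = F, f_thr = (t - 1) / (F - 1))
}

#' Predicted double-exposure ratio under a threshold fraction
#'
#' Interpolates between the additive and multiplicative expectations with
#' weight `sqrt(f)`:
#' `(1 - sqrt(f)) x (OR10 + OR01 - 1) + sqrt(f) x (OR10 x OR01)`.
#' At `f = 0` this is the additive expectation, at `f = 1` the
#' multiplicative one.
#'
#' @param or_10,or_01 Single-exposure ratios.
#' @param f Threshold fraction in \[0, 1\].
#' @return Predicted `OR_11`.
#' @examples
#' predicted_or11(2, 3, 0.25)  # 5
#' @export
predicted_or11 <- function(or_10, or_01, f) {
  if (any(f < 0 | f > 1, na.rm = TRUE)) stop_input("f must lie in [0, 1]")
  w <- sqrt(f)
  (1 - w) * (or_10 + or_01 - 1) + w * (or_10 * or_01)
}

#' Relative excess risk due to interaction
#'
#' `RERI = RR11 - RR10 - RR01 + 1`; zero under exact additivity. Related to
#' AMLES by `AMLES = RERI / ((OR10 - 1)(OR01 - 1))` when ORs and RRs
#' coincide.
#'
#' @param rr_11,rr_10,rr_01 Relative risks (vectorized).
#' @return RERI value(s).
#' @examples
#' reri(6, 2, 3)  # 2
#' reri(4, 2, 3)  # 0
#' @export
reri <- function(rr_11, rr_10, rr_01) rr_11 - rr_10 - rr_01 + 1

#' Pearson correlation of two factors within outcome strata
#'
#' Correlation between two binary factors computed in the full sample and
#' within cases and controls separately. A stratum with fewer than two
#' individuals or a constant factor yields `NA`.
#'
#' @param cohort A `cohort` or data frame with `status` and the factor columns.
#' @param factor_a,factor_b Column names (default the cohort's first two factors).
#' @return Named numeric vector `c(all = , cases = , controls = )`.
#' @export
stratified_correlation <- function(cohort,
                                   factor_a = attr(cohort, "factor_names")[1],
                                   factor_b = attr(cohort, "factor_names")[2]) {
  missing_cols <- setdiff(c("status", factor_a, factor_b), names(cohort))
  if (length(missing_cols)) stop_input("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  one <- function(rows) {
    a <- cohort[[factor_a]][rows]; b <- cohort[[factor_b]][rows]
    if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  c(all = one(seq_len(nrow(cohort))),
    cases = one(which(cohort$status == 1L)),
    controls = one(which(cohort$status == 0L)))
}
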