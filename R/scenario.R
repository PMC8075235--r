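SCENARIO_LOGICS <- c("AND", "OR", "THRESHOLD", "THREE_FACTOR",
                     "CONFOUNDER_I", "CONFOUNDER_II", "ADDITIVE_O", "ADDITIVE_R")

#' Describe one dichotomous risk factor
#'
#' A risk factor is carried with probability `high_freq` by individuals whose
#' linked causal component is in the "present" state and with probability
#' `low_freq` otherwise. In scenarios without causal components (confounders,
#' additive schemes) `low_freq`/`high_freq` are the background and
#' risk-associated frequencies and `linked_component` is `NA`.
#'
#' @param name Factor label, e.g. `"X"`, `"Z"`, `"V"`.
#' @param low_freq,high_freq Carrier probabilities in (0, 1) with
#'   `low_freq <= high_freq`.
#' @param linked_component Index of the causal component the factor tracks,
#'   or `NA` for scenarios without components.
#' @param clipped Whether `high_freq` was clipped below 1 during drawing.
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, low_freq, high_freq, linked_component = NA_integer_,
                        clipped = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("factor name must be a non-empty string")
  }
  if (!is_prob(low_freq) || !is_prob(high_freq)) {
    stop_input("factor frequencies must be probabilities strictly inside (0, 1)")
  }
  if (low_freq > high_freq) {
    stop_input("low_freq must not exceed high_freq (factor ", name, ")")
  }
  structure(
    list(name = name, low_freq = low_freq, high_freq = high_freq,
         linked_component = if (is.na(linked_component)) NA_integer_ else as.integer(linked_component),
         clipped = isTRUE(clipped)),
    class = "factor_spec"
  )
}

#' Specify a causal simulation scenario
#'
#' Bundles everything needed to simulate one cohort: the causal logic, the
#' number of latent components, the risk factors and their frequencies, the
#' target prevalence and the sampling design.
#'
#' Supported logics:
#' \describe{
#'   \item{AND}{synergism: all components must be present for a case.}
#'   \item{OR}{heterogeneity of causes: any one component suffices.}
#'   \item{THRESHOLD}{multifactorial threshold: at least `threshold` of
#'     `n_components` components present.}
#'   \item{THREE_FACTOR}{outcome = comp1 AND (comp2 OR comp3).}
#'   \item{CONFOUNDER_I}{cases and controls drawn from different genetic
#'     backgrounds; factors independent within each pool.}
#'   \item{CONFOUNDER_II}{mixture of two subpopulations differing in both
#'     factor frequencies and prevalence; factors carry no risk within a
#'     subpopulation.}
#'   \item{ADDITIVE_O}{two-group scheme yielding exactly additive odds
#'     ratios in expectation.}
#'   \item{ADDITIVE_R}{linear-probability risk yielding exactly additive
#'     relative risks in expectation.}
#' }
#'
#' @param logic One of the labels above.
#' @param prevalence Target case fraction in (0, 1).
#' @param factors List of [factor_spec()]; defaults are drawn with
#'   [draw_scenario_factors()] using the current RNG stream.
#' @param n_individuals Cohort size (default one million).
#' @param n_components Number of latent components (defaults: 2; 5 for
#'   THRESHOLD; 3 for THREE_FACTOR).
#' @param threshold Threshold t for THRESHOLD logic, `1 <= t <= n_components`.
#' @param prevalence_tolerance Maximum allowed |realized - target| prevalence.
#' @param subsample Whether downstream analysis intends equal-size
#'   case-control subsampling (stored for provenance; applied by
#'   [subsample_case_control()]).
#' @param prevalence_ratio CONFOUNDER_II only: ratio of subpopulation 2's
#'   prevalence to subpopulation 1's (default 3).
#' @param rr_x,rr_z ADDITIVE_R only: target single-factor relative risks;
#'   drawn from the standard multiplier ranges when `NULL`.
#' @return An object of class `scenario_spec`.
#' @examples
#' set.seed(7)
#' spec <- scenario_spec("AND", prevalence = 0.005, n_individuals = 1e4)
#' spec$component_prob
#' @export
scenario_spec <- function(logic, prevalence, factors = NULL,
                          n_individuals = 1e6, n_components = NULL,
                          threshold = NULL, prevalence_tolerance = 4e-4,
                          subsample = FALSE, prevalence_ratio = 3,
                          rr_x = NULL, rr_z = NULL) {
  logic <- match.arg(logic, SCENARIO_LOGICS)
  if (!is_prob(prevalence)) stop_input("prevalence must be in (0, 1)")
  if (!is.numeric(prevalence_tolerance) || prevalence_tolerance <= 0) {
    stop_input("prevalence_tolerance must be > 0")
  }
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L) stop_input("n_individuals must be a positive integer")

  if (is.null(n_components)) {
    n_components <- switch(logic, THRESHOLD = 5L, THREE_FACTOR = 3L, 2L)
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop_input("n_components must be >= 1")
  if (logic == "THREE_FACTOR" && n_components != 3L) {
    stop_input("THREE_FACTOR requires exactly 3 components")
  }

  if (logic == "THRESHOLD") {
    if (is.null(threshold)) stop_input("THRESHOLD logic requires a threshold t")
    threshold <- as.integer(threshold)
    if (threshold < 1L || threshold > n_components) {
      stop_input("threshold must satisfy 1 <= t <= n_components")
    }
  } else {
    threshold <- NA_integer_
  }

  if (is.null(factors)) factors <- draw_scenario_factors(logic)
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec"))) {
    stop_input("factors must be a list of factor_spec objects")
  }
  fnames <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(fnames)) stop_input("factor names must be unique")
  if (logic == "THREE_FACTOR" && length(factors) != 3L) {
    stop_input("THREE_FACTOR requires exactly 3 factors")
  }
  if (logic %in% c("AND", "OR", "THRESHOLD")) {
    links <- vapply(factors, `[[`, 0L, "linked_component")
    if (anyNA(links) || any(links < 1L) || any(links > n_components)) {
      stop_input("every factor must link to a component in 1..n_components")
    }
    if (anyDuplicated(links)) stop_input("a component can carry at most one observed factor")
  }

  extra <- list()
  if (logic == "CONFOUNDER_II") {
    if (!is.numeric(prevalence_ratio) || prevalence_ratio < 1) {
      stop_input("prevalence_ratio must be >= 1")
    }
    p1 <- 2 * prevalence / (1 + prevalence_ratio)
    p2 <- prevalence_ratio * p1
    if (p2 >= 1) stop_input("prevalence_ratio too large: subpopulation prevalence reaches 1")
    extra <- list(prevalence_ratio = prevalence_ratio, group_prevalence = c(p1, p2))
  }
  if (logic == "ADDITIVE_R") {
    if (is.null(rr_x)) rr_x <- stats::runif(1, 1.1, 2)
    if (is.null(rr_z)) rr_z <- stats::runif(1, 1.1, 4)
    if (rr_x <= 0 || rr_z <= 0) stop_input("target relative risks must be positive")
    fx <- factors[[1]]; fz <- factors[[2]]
    p0 <- prevalence / (1 + (rr_x - 1) * fx$low_freq + (rr_z - 1) * fz$low_freq)
    a <- p0 * (rr_x - 1); b <- p0 * (rr_z - 1)
    if (p0 + a + b >= 1) stop_input("linear risk exceeds 1: reduce prevalence or target relative risks")
    extra <- list(rr_x = rr_x, rr_z = rr_z, baseline_risk = p0, risk_x = a, risk_z = b)
  }

  component_prob <- switch(logic,
    AND = , OR = , THRESHOLD =
      solve_component_probability(logic, n_components, threshold, prevalence),
    THREE_FACTOR = three_factor_component_probs(prevalence),
    NULL
  )

  structure(
    c(list(logic = logic, prevalence = prevalence, factors = factors,
           n_individuals = n_individuals, n_components = n_components,
           threshold = threshold, prevalence_tolerance = prevalence_tolerance,
           subsample = isTRUE(subsample), component_prob = component_prob),
      extra),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$logic,
      if (!is.na(x$threshold)) paste0("(t = ", x$threshold, " of F = ", x$n_components, ")") else "",
      "\n  prevalence:", x$prevalence,
      " n:", x$n_individuals, "\n")
  for (f in x$factors) {
    cat(sprintf("  %s: low %.4f high %.4f%s%s\n", f$name, f$low_freq, f$high_freq,
                if (is.na(f$linked_component)) "" else paste0(" -> comp", f$linked_component),
                if (f$clipped) " (clipped)" else ""))
  }
  invisible(x)
}

#' Solve the per-component present-probability for a target prevalence
#'
#' All components share one probability p of being "present"; p is chosen so
#' that the outcome probability under the scenario logic equals the target
#' prevalence: `p = prevalence^(1/F)` for AND, `p = 1 - (1-prevalence)^(1/F)`
#' for OR, and for THRESHOLD the root of
#' `P(Binomial(F, p) >= t) = prevalence`, found by bisection to an outcome
#' probability error below 1e-10.
#'
#' @param logic `"AND"`, `"OR"` or `"THRESHOLD"`.
#' @param n_components Number of components F.
#' @param threshold Threshold t (THRESHOLD only).
#' @param prevalence Target outcome probability in (0, 1).
#' @return The common component probability p.
#' @examples
#' solve_component_probability("AND", 2, prevalence = 0.25)   # 0.5
#' solve_component_probability("THRESHOLD", 5, 3, 0.5)        # 0.5
#' @export
solve_component_probability <- function(logic, n_components, threshold = NULL,
                                        prevalence) {
  logic <- match.arg(logic, c("AND", "OR", "THRESHOLD"))
  if (!is_prob(prevalence)) stop_input("prevalence must be in (0, 1)")
  f <- as.integer(n_components)
  if (f < 1L) stop_input("n_components must be >= 1")
  if (logic == "AND") return(prevalence^(1 / f))
  if (logic == "OR") return(1 - (1 - prevalence)^(1 / f))
  t <- as.integer(threshold)
  if (is.na(t) || t < 1L || t > f) stop_input("threshold must satisfy 1 <= t <= n_components")
  lo <- 0; hi <- 1
  prev_at <- function(p) stats::pbinom(t - 1L, f, p, lower.tail = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- prev_at(mid)
    if (abs(val - prevalence) < 1e-10) break
    if (val < prevalence) lo <- mid else hi <- mid
  }
  if (abs(prev_at(mid) - prevalence) >= 1e-10) {
    stop_input("bisection failed to reach the target prevalence")
  }
  mid
}

# comp2 and comp3 share probability q; comp1 matches the probability of
# (comp2 OR comp3), so prevalence = P(comp1) * P(comp2 | comp3) = sqrt(prev)^2.
three_factor_component_probs <- function(prevalence) {
  p_or <- sqrt(prevalence)
  q <- 1 - sqrt(1 - p_or)
  c(p_or, q, q)
}
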