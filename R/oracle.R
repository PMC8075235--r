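# Exact enumeration over latent component states and factor patterns.
# This is both the engine behind outcome-conditional sampling and the
# analytic reference the simulators are tested against.

component_model <- function(spec) {
  f <- spec$n_components
  states <- as.matrix(expand.grid(rep(list(0:1), f)))
  colnames(states) <- paste0("comp", seq_len(f))
  probs <- spec$component_prob
  if (length(probs) == 1L) probs <- rep(probs, f)
  w <- exp(states %*% log(probs) + (1 - states) %*% log(1 - probs))[, 1]
  outcome <- switch(spec$logic,
    AND = as.integer(rowSums(states) == f),
    OR = as.integer(rowSums(states) > 0),
    THRESHOLD = as.integer(rowSums(states) >= spec$threshold),
    THREE_FACTOR = as.integer(states[, 1] == 1 & (states[, 2] == 1 | states[, 3] == 1)),
    stop_input("not a component-logic scenario: ", spec$logic)
  )
  list(states = states, weights = w, outcome = outcome)
}

factor_patterns <- function(k, names) {
  pat <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(pat) <- names
  pat
}

# P(factor pattern | component state) for one state row.
pattern_probs_given_state <- function(state, factors, patterns) {
  p <- vapply(factors, function(fs) {
    if (is.na(fs$linked_component)) fs$low_freq
    else if (state[fs$linked_component] == 1) fs$high_freq else fs$low_freq
  }, 0)
  apply(patterns, 1L, function(x) prod(ifelse(x == 1, p, 1 - p)))
}

#' Exact cell probabilities for a scenario
#'
#' Computes the joint probability of every (factor pattern, case/control)
#' cell by exact enumeration: for component-logic scenarios by summing over
#' all 2^F latent component states, and for the confounder and additive
#' schemes from their closed-form construction. The total is 1; simulated
#' cohort frequencies converge to these values.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame with one 0/1 column per factor, a `status` column
#'   (1 = case) and a `prob` column summing to 1.
#' @examples
#' set.seed(1)
#' spec <- scenario_spec("AND", prevalence = 0.25)
#' pr <- oracle_cell_probabilities(spec)
#' sum(pr$prob[pr$status == 1])  # 0.25
#' @export
oracle_cell_probabilities <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  fnames <- vapply(spec$factors, `[[`, "", "name")
  k <- length(fnames)
  patterns <- factor_patterns(k, fnames)
  prev <- spec$prevalence

  if (spec$logic %in% c("AND", "OR", "THRESHOLD", "THREE_FACTOR")) {
    cm <- component_model(spec)
    cell <- matrix(0, nrow(patterns), 2)
    for (s in seq_along(cm$weights)) {
      pp <- pattern_probs_given_state(cm$states[s, ], spec$factors, patterns)
      col <- cm$outcome[s] + 1L
      cell[, col] <- cell[, col] + cm$weights[s] * pp
    }
    out <- data.frame(patterns, status = rep(c(0L, 1L), each = nrow(patterns)),
                      prob = c(cell[, 1], cell[, 2]))
    rownames(out) <- NULL
    return(out)
  }

  cond <- pattern_status_probs(spec, patterns)
  out <- data.frame(rbind(patterns, patterns),
                    status = rep(c(0L, 1L), each = nrow(patterns)),
                    prob = c(cond$control * (1 - prev), cond$case * prev))
  rownames(out) <- NULL
  out
}

# P(pattern | status) for scenarios defined directly on case/control pools.
pattern_status_probs <- function(spec, patterns) {
  fx <- spec$factors[[1]]; fz <- spec$factors[[2]]
  bern2 <- function(px, pz) {
    apply(patterns, 1L, function(x) {
      prod(ifelse(x == 1, c(px, pz), 1 - c(px, pz)))
    })
  }
  switch(spec$logic,
    CONFOUNDER_I = list(
      case = bern2(fx$high_freq, fz$high_freq),
      control = bern2(fx$low_freq, fz$low_freq)
    ),
    CONFOUNDER_II = {
      gp <- spec$group_prevalence
      prev <- spec$prevalence
      g1 <- bern2(fx$low_freq, fz$low_freq)
      g2 <- bern2(fx$high_freq, fz$high_freq)
      list(
        case = (0.5 * gp[1] * g1 + 0.5 * gp[2] * g2) / prev,
        control = (0.5 * (1 - gp[1]) * g1 + 0.5 * (1 - gp[2]) * g2) / (1 - prev)
      )
    },
    ADDITIVE_O = list(
      case = 0.5 * bern2(fx$low_freq, fz$high_freq) + 0.5 * bern2(fx$high_freq, fz$low_freq),
      control = bern2(fx$low_freq, fz$low_freq)
    ),
    ADDITIVE_R = {
      base <- bern2(fx$low_freq, fz$low_freq)
      risk <- spec$baseline_risk + spec$risk_x * patterns[, 1] + spec$risk_z * patterns[, 2]
      joint_case <- base * risk
      list(case = joint_case / sum(joint_case),
           control = base * (1 - risk) / sum(base * (1 - risk)))
    },
    stop_input("no closed-form cell probabilities for logic ", spec$logic)
  )
}

#' Expected contingency table under a scenario
#'
#' Multiplies the exact cell probabilities by the cohort size, giving the
#' expected (generally non-integer) counts of every factor pattern by
#' outcome. Useful as an analytic reference for [odds_ratios()] and
#' [relative_risks()].
#'
#' @param spec A [scenario_spec()].
#' @param n Total count to distribute (default `spec$n_individuals`).
#' @return An `interaction_table` of expected counts.
#' @export
oracle_expected_table <- function(spec, n = spec$n_individuals) {
  pr <- oracle_cell_probabilities(spec)
  k <- ncol(pr) - 2L
  pat <- unique(pr[, seq_len(k), drop = FALSE])
  tab <- data.frame(pat,
    n_control = pr$prob[pr$status == 0] * n,
    n_case = pr$prob[pr$status == 1] * n)
  rownames(tab) <- NULL
  structure(tab, class = c("interaction_table", "data.frame"),
            factors = colnames(pr)[seq_len(k)])
}
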