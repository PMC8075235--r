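#' Simulate a cohort under any scenario
#'
#' Dispatches to the simulator matching `spec$logic`. All simulators share
#' the same design: the case/control split is drawn exactly (the case count
#' is `round(n * prevalence)`), and individual-level states are sampled from
#' the exact outcome-conditional distribution given by
#' [oracle_cell_probabilities()]'s enumeration, so the realized prevalence
#' is always within 1/n of the target. Uses the current RNG stream; call
#' [set.seed()] first for reproducible cohorts.
#'
#' @param spec A [scenario_spec()].
#' @return A `cohort`: a data frame with columns `id`, `status`
#'   (1 = case, 0 = control), one 0/1 column per factor and, for
#'   subpopulation scenarios, `group`. Attributes record the generating
#'   spec and the realized prevalence.
#' @examples
#' set.seed(1)
#' coh <- simulate_cohort(scenario_spec("AND", 0.25, n_individuals = 1000))
#' mean(coh$status)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  switch(spec$logic,
    AND = , OR = , THRESHOLD = simulate_population(spec),
    THREE_FACTOR = simulate_three_factor(spec),
    CONFOUNDER_I = simulate_confounder_i(spec),
    CONFOUNDER_II = simulate_confounder_ii(spec),
    ADDITIVE_O = simulate_additive_scheme("O", spec),
    ADDITIVE_R = simulate_additive_scheme("R", spec)
  )
}

resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

split_case_count <- function(n, prevalence, tolerance) {
  n_case <- as.integer(round(n * prevalence))
  n_case <- max(0L, min(n, n_case))
  realized <- n_case / n
  if (abs(realized - prevalence) > tolerance) {
    warning(sprintf(
      "realized prevalence %.6f deviates from target %.6f by more than the tolerance %.2g at n = %d",
      realized, prevalence, tolerance, n), call. = FALSE)
  }
  n_case
}

as_cohort <- function(df, spec, extra_factors = NULL) {
  fnames <- vapply(spec$factors, `[[`, "", "name")
  structure(df,
            class = c("cohort", "data.frame"),
            scenario = spec,
            factor_names = fnames,
            realized_prevalence = mean(df$status))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals (%d cases, %d controls), factors: %s\n",
              nrow(x), sum(x$status == 1), sum(x$status == 0),
              paste(attr(x, "factor_names"), collapse = ", ")))
  NextMethod()
}

draw_factor_columns <- function(states, factors, n) {
  cols <- lapply(factors, function(fs) {
    p <- if (is.na(fs$linked_component)) fs$low_freq
         else fs$low_freq + (fs$high_freq - fs$low_freq) * states[, fs$linked_component]
    as.integer(stats::runif(n) < p)
  })
  names(cols) <- vapply(factors, `[[`, "", "name")
  cols
}

sim_component_cohort <- function(spec) {
  cm <- component_model(spec)
  n <- spec$n_individuals
  n_case <- split_case_count(n, spec$prevalence, spec$prevalence_tolerance)
  n_ctrl <- n - n_case
  i_case <- which(cm$outcome == 1L)
  i_ctrl <- which(cm$outcome == 0L)
  if (length(i_case) == 0L || length(i_ctrl) == 0L) {
    stop_input("scenario logic admits no ", if (length(i_case) == 0L) "case" else "control", " states")
  }
  idx <- c(resample(i_case, n_case, cm$weights[i_case]),
           resample(i_ctrl, n_ctrl, cm$weights[i_ctrl]))
  states <- cm$states[idx, , drop = FALSE]
  status <- rep(c(1L, 0L), c(n_case, n_ctrl))
  df <- data.frame(id = seq_len(n), status = status,
                   draw_factor_columns(states, spec$factors, n))
  as_cohort(df, spec)
}

#' Simulate the synergism, heterogeneity or threshold scenario
#'
#' Latent components are independently "present" with the probability solved
#' by [solve_component_probability()]; the outcome applies the scenario
#' logic (AND, OR, or at-least-t-of-F) to the component states; each risk
#' factor is carried with its high frequency when its linked component is
#' present and with its low frequency otherwise.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort`; see [simulate_cohort()].
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"),
            spec$logic %in% c("AND", "OR", "THRESHOLD"))
  sim_component_cohort(spec)
}

#' Simulate the three-factor scenario X AND (Z OR V)
#'
#' Three components: the outcome requires component 1 (tracked by X)
#' together with either component 2 (Z) or component 3 (V). Components 2
#' and 3 share one probability, and component 1's probability equals that of
#' their OR-combination, so the two arms of the AND are balanced.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort` with factors X, Z, V.
#' @export
simulate_three_factor <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"), spec$logic == "THREE_FACTOR")
  sim_component_cohort(spec)
}

sim_pattern_cohort <- function(spec, group = NULL) {
  fnames <- vapply(spec$factors, `[[`, "", "name")
  patterns <- factor_patterns(length(fnames), fnames)
  cond <- pattern_status_probs(spec, patterns)
  n <- spec$n_individuals
  n_case <- split_case_count(n, spec$prevalence, spec$prevalence_tolerance)
  n_ctrl <- n - n_case
  rows <- c(resample(seq_len(nrow(patterns)), n_case, cond$case),
            resample(seq_len(nrow(patterns)), n_ctrl, cond$control))
  df <- data.frame(id = seq_len(n), status = rep(c(1L, 0L), c(n_case, n_ctrl)),
                   patterns[rows, , drop = FALSE], row.names = NULL)
  as_cohort(df, spec)
}

#' Simulate the Confounder I scenario (mismatched genetic backgrounds)
#'
#' Cases and controls are drawn as two separate pools: within each pool the
#' two factors are carried independently, with the high frequencies in the
#' case pool and the low frequencies in the control pool. No causal link
#' between the factors exists, yet the expected odds ratios satisfy
#' `OR11 = OR10 x OR01` exactly, mimicking synergism.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort`; see [simulate_cohort()].
#' @export
simulate_confounder_i <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"), spec$logic == "CONFOUNDER_I")
  sim_pattern_cohort(spec)
}

#' Simulate the Confounder II scenario (population stratification)
#'
#' Two equal-size subpopulations differ in both factor frequencies
#' (`low_freq` in group 1, `high_freq` in group 2) and prevalence (group 2's
#' prevalence is `prevalence_ratio` times group 1's, with the mixture
#' matching the target). Within each subpopulation the factors are
#' independent of each other and of the outcome; all association is an
#' artifact of the mixture.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort` with a `group` column (1 or 2).
#' @export
simulate_confounder_ii <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"), spec$logic == "CONFOUNDER_II")
  n <- spec$n_individuals
  n1 <- n %/% 2L; n2 <- n - n1
  gp <- spec$group_prevalence
  sim_group <- function(ng, pg, use_high) {
    n_case <- as.integer(round(ng * pg))
    status <- rep(c(1L, 0L), c(n_case, ng - n_case))
    cols <- lapply(spec$factors, function(fs) {
      p <- if (use_high) fs$high_freq else fs$low_freq
      as.integer(stats::runif(ng) < p)
    })
    names(cols) <- vapply(spec$factors, `[[`, "", "name")
    data.frame(status = status, cols)
  }
  df <- rbind(sim_group(n1, gp[1], FALSE), sim_group(n2, gp[2], TRUE))
  df <- data.frame(id = seq_len(n), df, group = rep(c(1L, 2L), c(n1, n2)))
  realized <- mean(df$status)
  if (abs(realized - spec$prevalence) > spec$prevalence_tolerance) {
    warning(sprintf("realized prevalence %.6f deviates from target %.6f beyond tolerance",
                    realized, spec$prevalence), call. = FALSE)
  }
  as_cohort(df, spec)
}

#' Simulate one of the two additive-effect schemes
#'
#' Variant `"R"` (additive relative risks): factors are carried at their
#' background frequencies and the case probability is linear,
#' `P(case | X, Z) = p0 + a X + b Z`, which forces
#' `RR11 = RR10 + RR01 - 1` in expectation.
#'
#' Variant `"O"` (additive odds ratios): individuals are split into two
#' equal groups; in group 1 only Z is associated with the outcome (X stays
#' at its background frequency) and in group 2 only X is; both groups share
#' the target prevalence. The expected odds ratios then satisfy
#' `OR11 = OR10 + OR01 - 1` exactly.
#'
#' @param variant `"O"` or `"R"`.
#' @inheritParams simulate_cohort
#' @return A `cohort`; variant O carries a `group` column.
#' @export
simulate_additive_scheme <- function(variant = c("O", "R"), spec) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "scenario_spec"),
            spec$logic == paste0("ADDITIVE_", variant))
  if (variant == "R") return(sim_pattern_cohort(spec))

  n <- spec$n_individuals
  n1 <- n %/% 2L; n2 <- n - n1
  fx <- spec$factors[[1]]; fz <- spec$factors[[2]]
  sim_group <- function(ng, risky) {
    n_case <- as.integer(round(ng * spec$prevalence))
    status <- rep(c(1L, 0L), c(n_case, ng - n_case))
    px <- if (risky == "X") fx$low_freq + (fx$high_freq - fx$low_freq) * (status == 1L) else fx$low_freq
    pz <- if (risky == "Z") fz$low_freq + (fz$high_freq - fz$low_freq) * (status == 1L) else fz$low_freq
    df <- data.frame(status = status,
                     as.integer(stats::runif(ng) < px),
                     as.integer(stats::runif(ng) < pz))
    names(df) <- c("status", fx$name, fz$name)
    df
  }
  df <- rbind(sim_group(n1, "Z"), sim_group(n2, "X"))
  df <- data.frame(id = seq_len(n), df, group = rep(c(1L, 2L), c(n1, n2)))
  as_cohort(df, spec)
}

#' Subsample controls to match the number of cases
#'
#' Keeps every case and draws, uniformly without replacement, as many
#' controls as there are cases — the biased sampling step of a balanced
#' case-control study. Odds ratios are invariant to this step in
#' expectation; correlations between risk factors in the combined sample
#' are not.
#'
#' @param cohort A `cohort` (or any data frame with a 0/1 `status` column).
#' @return A `cohort` with equal case and control counts.
#' @export
subsample_case_control <- function(cohort) {
  n_case <- sum(cohort$status == 1L)
  ctrl_idx <- which(cohort$status == 0L)
  if (n_case < 1L) stop_input("cohort has no cases to match")
  if (length(ctrl_idx) < n_case) stop_input("fewer controls than cases; cannot subsample")
  keep <- c(which(cohort$status == 1L), ctrl_idx[sample.int(length(ctrl_idx), n_case)])
  out <- cohort[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("scenario", "factor_names")) attr(out, a) <- attr(cohort, a)
  attr(out, "realized_prevalence") <- 0.5
  out
}
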