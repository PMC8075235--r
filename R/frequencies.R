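#' Draw low/high frequencies for a risk factor
#'
#' Frequencies are drawn by the protocol used throughout the simulation
#' scenarios: a low (background) frequency is drawn uniformly from a
#' role-specific range, and the high (risk-associated) frequency is the low
#' frequency times a uniform multiplier.
#'
#' * `"Z-like"`: low frequency uniform on \[0.05, 0.15\], multiplier uniform
#'   on \[1.1, 4\].
#' * `"X-like"`: low frequency uniform on \[0.05, 0.25\], multiplier uniform
#'   on \[1.1, 2\].
#'
#' The high frequency is clipped at 0.99 if the multiplier pushes it to 1 or
#' above; `clipped` records when that happened.
#'
#' Draws use the current R random number stream; call [set.seed()] first for
#' reproducibility.
#'
#' @param role `"Z-like"` or `"X-like"`.
#' @return A list with `low_freq`, `high_freq`, `multiplier`, `clipped`.
#' @examples
#' set.seed(1)
#' draw_factor_frequencies("Z-like")
#' @export
draw_factor_frequencies <- function(role = c("Z-like", "X-like")) {
  if (!is.character(role) || length(role) != 1L || !role %in% c("Z-like", "X-like")) {
    stop_input("unknown factor role: ", paste(role, collapse = ", "),
               " (expected \"Z-like\" or \"X-like\")")
  }
  rng <- switch(role,
    "Z-like" = list(low = c(0.05, 0.15), mult = c(1.1, 4)),
    "X-like" = list(low = c(0.05, 0.25), mult = c(1.1, 2))
  )
  low <- stats::runif(1, rng$low[1], rng$low[2])
  m <- stats::runif(1, rng$mult[1], rng$mult[2])
  high <- low * m
  clipped <- high >= 1
  if (clipped) high <- 0.99
  list(low_freq = low, high_freq = high, multiplier = m, clipped = clipped)
}

#' Draw the default factor set for a scenario
#'
#' Builds the risk factors each scenario uses, with freshly drawn
#' frequencies: an X-like factor linked to component 1 and a Z-like factor
#' linked to component 2; the three-factor scenario adds a second Z-like
#' factor (V) linked to component 3. Confounder and additive scenarios use
#' the same draw protocol, with `low_freq` as the background (control /
#' group 1) frequency and `high_freq` as the risk-associated (case /
#' group 2) frequency.
#'
#' @param logic Scenario logic label (see [scenario_spec()]).
#' @return A list of [factor_spec()] objects.
#' @export
draw_scenario_factors <- function(logic) {
  x <- draw_factor_frequencies("X-like")
  z <- draw_factor_frequencies("Z-like")
  fx <- factor_spec("X", x$low_freq, x$high_freq, linked_component = 1L, clipped = x$clipped)
  fz <- factor_spec("Z", z$low_freq, z$high_freq, linked_component = 2L, clipped = z$clipped)
  if (identical(logic, "THREE_FACTOR")) {
    v <- draw_factor_frequencies("Z-like")
    fv <- factor_spec("V", v$low_freq, v$high_freq, linked_component = 3L, clipped = v$clipped)
    return(list(fx, fz, fv))
  }
  list(fx, fz)
}
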