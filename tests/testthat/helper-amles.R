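# Shared fixtures built in code.

# Fixed-frequency factor pair with a strong, known contrast.
fixed_factors <- function(x_low = 0.10, x_high = 0.25, z_low = 0.10, z_high = 0.30,
                          three = FALSE) {
  out <- list(factor_spec("X", x_low, x_high, 1L),
              factor_spec("Z", z_low, z_high, 2L))
  if (three) out <- c(out, list(factor_spec("V", 0.08, 0.24, 3L)))
  out
}

# A 2x2x2 table from explicit cell counts, cases then controls in the
# pattern order (00, 10, 01, 11).
counts_table <- function(cases, controls, factors = c("X", "Z")) {
  pat <- expand.grid(a = 0:1, b = 0:1)
  names(pat) <- factors
  structure(data.frame(pat, n_control = controls, n_case = cases),
            class = c("interaction_table", "data.frame"), factors = factors)
}
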