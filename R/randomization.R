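factor_columns <- function(table) {
  setdiff(names(table), c("id", "status", "group"))
}

check_factor_table <- function(table) {
  if (!"status" %in% names(table)) stop_input("factor table needs a status column")
  if (!all(table$status %in% c(0L, 1L))) stop_input("status must be 0/1")
  cols <- factor_columns(table)
  if (!length(cols)) stop_input("factor table has no factor columns")
  for (cl in cols) {
    if (!all(table[[cl]] %in% c(0L, 1L))) stop_input("factor column ", cl, " must be 0/1")
  }
  cols
}

#' Randomization 1: shuffle factors within cases and within controls
#'
#' Permutes every factor column independently within the case stratum and
#' within the control stratum. Per-status marginal counts of every factor
#' are preserved exactly, while any dependence between factors (conditional
#' on status) is destroyed — reproducing the Confounder I structure and
#' therefore acting as a positive control for multiplicative odds ratios.
#'
#' @param table A factor table: data frame with `status` (0/1) and binary
#'   factor columns.
#' @return The table with shuffled factor columns.
#' @export
rand1_shuffle_within_status <- function(table) {
  cols <- check_factor_table(table)
  i_case <- which(table$status == 1L)
  i_ctrl <- which(table$status == 0L)
  for (cl in cols) {
    table[[cl]][i_case] <- table[[cl]][i_case][sample.int(length(i_case))]
    table[[cl]][i_ctrl] <- table[[cl]][i_ctrl][sample.int(length(i_ctrl))]
  }
  table
}

#' Randomization 2: two-group control-resampling null
#'
#' Splits individuals randomly into two equal groups. In group 1 the anchor
#' factor is resampled (per individual, with replacement) from its
#' control-stratum empirical distribution; in group 2 every other factor is
#' resampled likewise from its own control distribution. In each group one
#' of the pair is thereby disconnected from the outcome, emulating the
#' two-group additive-odds-ratio scheme. Status is never modified, so
#' case/control counts are preserved.
#'
#' @param table A factor table.
#' @param anchor Name of the anchor factor column.
#' @return The randomized table.
#' @export
rand2_group_split_null <- function(table, anchor) {
  cols <- check_factor_table(table)
  if (!anchor %in% cols) stop_input("anchor column ", anchor, " not found")
  n <- nrow(table)
  in_g1 <- sample.int(n) <= n %/% 2L
  i_ctrl <- which(table$status == 0L)
  if (!length(i_ctrl)) stop_input("no controls to resample from")
  draw_ctrl <- function(cl, size) {
    pool <- table[[cl]][i_ctrl]
    pool[sample.int(length(pool), size, replace = TRUE)]
  }
  table[[anchor]][in_g1] <- draw_ctrl(anchor, sum(in_g1))
  for (cl in setdiff(cols, anchor)) {
    table[[cl]][!in_g1] <- draw_ctrl(cl, sum(!in_g1))
  }
  table
}

#' Pairwise interaction scan of an anchor factor against all others
#'
#' Computes the full set of effect estimates ([odds_ratios()]) for the
#' anchor paired with every other factor column. Rows failing the
#' minimum-cell filter are kept and flagged invalid rather than dropped, so
#' downstream counts stay auditable.
#'
#' @param table A factor table.
#' @param anchor Name of the anchor factor column.
#' @param min_cell Minimum count per cell (default 5).
#' @return Data frame with one row per tested factor: odds ratios, expected
#'   additive/multiplicative values, AMLES, f_est, RERI and validity flag.
#' @export
pairwise_scan <- function(table, anchor, min_cell = 5) {
  cols <- check_factor_table(table)
  if (!anchor %in% cols) stop_input("anchor column ", anchor, " not found")
  tests <- setdiff(cols, anchor)
  if (!length(tests)) stop_input("no factors to test against the anchor")
  rows <- lapply(tests, function(cl) {
    tab <- tabulate_cohort(table, factors = c(anchor, cl))
    est <- odds_ratios(tab, min_cell = min_cell)
    cbind(data.frame(factor = cl), as.data.frame(est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
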