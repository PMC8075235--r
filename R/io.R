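#' Read a cohort / factor table from TSV
#'
#' Expects a tab-separated file with header `id`, `status`, then one column
#' per binary factor and optionally `group`. `status` must be 0 (control)
#' or 1 (case) and factors must be 0/1; violations are rejected with the
#' offending file line number. An empty file with only the header yields an
#' empty cohort.
#'
#' @param path Path to the TSV file.
#' @return A `cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "status")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_input("cohort file lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  factors <- setdiff(names(df), c("id", "status", "group"))
  if (!length(factors)) stop_input("cohort file has no factor columns")
  bad_status <- which(!df$status %in% c(0L, 1L))
  if (length(bad_status)) {
    stop_input("invalid status value at line ", bad_status[1] + 1L,
               " (must be 0 or 1)")
  }
  for (cl in factors) {
    bad <- which(!df[[cl]] %in% c(0L, 1L))
    if (length(bad)) {
      stop_input("non-binary value in column ", cl, " at line ", bad[1] + 1L)
    }
    df[[cl]] <- as.integer(df[[cl]])
  }
  df$status <- as.integer(df$status)
  structure(df, class = c("cohort", "data.frame"),
            factor_names = factors,
            realized_prevalence = if (nrow(df)) mean(df$status) else NA_real_)
}

spec_to_list <- function(spec) {
  if (is.null(spec)) return(NULL)
  out <- unclass(spec)
  out$factors <- lapply(out$factors, unclass)
  out
}

#' Write a cohort / factor table to TSV
#'
#' Writes the tab-separated representation read back by [read_cohort()].
#' When provenance is available (the generating scenario recorded on the
#' cohort, or a list passed via `provenance`), it is written alongside as
#' `<path>.json` so every output file carries the configuration and seed
#' that produced it.
#'
#' @param cohort A `cohort` or factor table data frame.
#' @param path Output TSV path.
#' @param provenance Optional named list (e.g. seed, command) merged into
#'   the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, provenance = NULL) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- c(list(scenario = spec_to_list(attr(cohort, "scenario")),
                 realized_prevalence = attr(cohort, "realized_prevalence")),
            provenance)
  prov <- prov[!vapply(prov, is.null, TRUE)]
  if (length(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#' Keys mirror the [scenario_spec()] and [run_experiment()] arguments.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(path))
  if (ext == "json") return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  stop_input("unsupported config extension: .", ext, " (use .yaml/.yml or .json)")
}

#' Generate a multi-locus factor-table fixture
#'
#' Builds a case-control factor table with one anchor factor and many test
#' loci, with known ground truth, for exercising [pairwise_scan()] and the
#' randomization controls.
#'
#' * `"confounder1"`: every locus (and the anchor) is drawn independently
#'   within cases at its high frequency and within controls at its low
#'   frequency — the mismatched-background structure whose expected odds
#'   ratios are exactly multiplicative.
#' * `"null"`: every column is drawn at a single frequency regardless of
#'   status, so no locus is associated with the outcome.
#'
#' Frequencies use the standard draw protocol (anchor X-like, loci Z-like).
#'
#' @param kind `"confounder1"` or `"null"`.
#' @param n_individuals Number of individuals (default 20000).
#' @param n_loci Number of test loci (default 50).
#' @param prevalence Case fraction (default 0.5, a balanced case-control set).
#' @param seed Seed; the same seed reproduces the fixture exactly.
#' @return A factor table data frame (`id`, `status`, `anchor`,
#'   `locus_001`, ...) with a `ground_truth` attribute.
#' @export
generate_fixture <- function(kind = c("confounder1", "null"),
                             n_individuals = 20000, n_loci = 50,
                             prevalence = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  n <- as.integer(n_individuals)
  n_case <- as.integer(round(n * prevalence))
  status <- rep(c(1L, 0L), c(n_case, n - n_case))
  draw_col <- function(freqs) {
    p <- ifelse(status == 1L, freqs$high_freq, freqs$low_freq)
    as.integer(stats::runif(n) < p)
  }
  anchor_freqs <- draw_factor_frequencies("X-like")
  if (kind == "null") anchor_freqs$high_freq <- anchor_freqs$low_freq
  cols <- list(anchor = draw_col(anchor_freqs))
  truth <- list(anchor = anchor_freqs)
  for (j in seq_len(n_loci)) {
    fr <- draw_factor_frequencies("Z-like")
    if (kind == "null") fr$high_freq <- fr$low_freq
    nm <- sprintf("locus_%03d", j)
    cols[[nm]] <- draw_col(fr)
    truth[[nm]] <- fr
  }
  out <- data.frame(id = seq_len(n), status = status, cols)
  attr(out, "ground_truth") <- truth
  attr(out, "kind") <- kind
  out
}
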