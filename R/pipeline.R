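#' Simulate a cohort to trace files
#'
#' Runs [simulate_cohort()] and writes one trace file per synthetic
#' subject plus a run manifest (`manifest.json`: configuration snapshot,
#' master seed, policy roster, output file list, package version).
#' Re-running with the same manifest inputs reproduces byte-identical
#' files.
#'
#' @param config A [game_config()] or path to a config file.
#' @param policies A list of [policy()] objects or path to a roster file;
#'   `NULL` for the [default_cohort_policies()] roster.
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_simulate <- function(config = game_config(), policies = NULL, seed = 1L,
                         out_dir = ".") {
  if (is.character(config)) config <- read_game_config(config)
  validate_game_config(config)
  if (is.null(policies)) policies <- default_cohort_policies()
  if (is.character(policies)) policies <- read_policies(policies)
  traces <- simulate_cohort(config, policies, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(traces, function(tr) {
    f <- file.path(out_dir, paste0("trace_", tr$subject_id, ".csv"))
    write_trace(tr, f)
    basename(f)
  }, character(1))
  manifest <- list(
    tool = "mouselabq",
    version = as.character(utils::packageVersion("mouselabq")),
    seed = as.integer(seed),
    config = unclass(config),
    policies = lapply(policies, function(p) {
      s <- unclass(p); s[!vapply(s, is.null, logical(1))]
    }),
    traces = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Score a directory of trace files
#'
#' Reads every `trace_*.csv` in a directory, computes [subject_metrics()]
#' for each, and writes the per-subject metrics table. Invalid trace files
#' are reported (as warnings and in the return value) and skipped; valid
#' ones are still scored.
#'
#' @param trace_dir Directory containing trace files.
#' @param out_path Path of the metrics CSV to write (`NULL` to skip
#'   writing).
#' @return A list with `metrics` (data.frame) and `failures` (named
#'   character vector of per-file error messages).
#' @export
run_score <- function(trace_dir, out_path = NULL) {
  files <- sort(list.files(trace_dir, pattern = "^trace_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no trace files (trace_*.csv) in ", trace_dir)
  rows <- list()
  failures <- character(0)
  for (f in files) {
    res <- tryCatch(subject_metrics(read_trace(f)), error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", basename(f), ": ", conditionMessage(res))
      failures[basename(f)] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) stop("no valid trace files in ", trace_dir)
  metrics <- do.call(rbind, rows)
  if (!is.null(out_path)) {
    utils::write.csv(metrics, out_path, row.names = FALSE)
  }
  list(metrics = metrics, failures = failures)
}

#' Build and write cohort tables from a metrics table
#'
#' @param metrics A metrics data.frame (from [run_score()] or
#'   [cohort_metrics()]) or the path of a metrics CSV.
#' @param out_dir Output directory for the table files (see
#'   [write_cohort_tables()]).
#' @return The `mlq_cohort_tables`, invisibly.
#' @export
run_tables <- function(metrics, out_dir) {
  if (is.character(metrics)) {
    if (!file.exists(metrics)) stop("metrics file not found: ", metrics)
    metrics <- utils::read.csv(metrics, stringsAsFactors = FALSE)
  }
  tables <- build_tables(metrics)
  write_cohort_tables(tables, out_dir)
  invisible(tables)
}
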