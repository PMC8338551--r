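#' @title Report writers and run manifest
#' @description Machine-readable CSV/JSON outputs with fixed headers
#'   (two-decimal euro amounts, no thousands separators) and a manifest that
#'   makes a run reproducible from its configuration digest and seed.
#' @name report
NULL

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

round_cents <- function(x) round(x, 2)

#' Write a cost breakdown as CSV
#'
#' Columns: `arm, category, item, payer, quantity, unit_cost, cost`.
#'
#' @param breakdowns a `cost_breakdown` or list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cost_breakdown_csv <- function(breakdowns, path) {
  if (inherits(breakdowns, "cost_breakdown")) breakdowns <- list(breakdowns)
  df <- do.call(rbind, lapply(breakdowns, as.data.frame))
  df$unit_cost <- round_cents(df$unit_cost)
  df$cost <- round_cents(df$cost)
  write_csv_plain(df, path)
}

#' Write a CEA result as CSV or JSON
#'
#' CSV columns: `scenario, comparator, treatment, cost_comparator,
#' cost_treatment, effect_comparator, effect_treatment, delta_cost,
#' delta_effect, icer, icer_ratio`.
#'
#' @param result a `cea_result`.
#' @param path output file; `.json` extension selects JSON.
#' @return the path, invisibly.
#' @export
write_cea_result <- function(result, path) {
  df <- as.data.frame(result)
  df$cost_comparator <- round_cents(df$cost_comparator)
  df$cost_treatment <- round_cents(df$cost_treatment)
  df$delta_cost <- round_cents(df$delta_cost)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
  } else {
    write_csv_plain(df, path)
  }
}

#' Write PSA draws as CSV
#'
#' Columns: `iteration, delta_cost, delta_effect, quadrant`.
#'
#' @param psa a `psa_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  df <- psa$draws[, c("iteration", "delta_cost", "delta_effect", "quadrant")]
  write_csv_plain(df, path)
}

#' Write an acceptability curve as CSV
#'
#' Columns: `lambda, p_treatment, p_comparator, frontier_strategy,
#' frontier_probability`.
#'
#' @param curve a `ceac_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ceac_csv <- function(curve, path) {
  write_csv_plain(as.data.frame(curve), path)
}

#' Write a tornado table as CSV
#'
#' Columns: `parameter, bound, value, icer, icer_ratio, pct_deviation`,
#' sorted widest-first.
#'
#' @param tor a `tornado_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tornado_csv <- function(tor, path) {
  write_csv_plain(as.data.frame(tor), path)
}

#' Write the scenario table as CSV
#'
#' @param scen data.frame from [scenarios_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scenarios_csv <- function(scen, path) {
  scen$cost_comparator <- round_cents(scen$cost_comparator)
  scen$cost_treatment <- round_cents(scen$cost_treatment)
  scen$delta_cost <- round_cents(scen$delta_cost)
  write_csv_plain(scen, path)
}

#' Run manifest
#'
#' Records what produced a set of outputs: package version, schema version,
#' canonical configuration digest, seed, iteration count, timestamp and the
#' output file list. The digest changes iff the canonicalized configuration
#' changes, so `(digest, seed)` reproduces a run end-to-end.
#'
#' @param config the [model_config()] used.
#' @param seed integer seed (`NA` for deterministic runs).
#' @param iterations iteration count (`NA` for deterministic runs).
#' @param outputs character vector of output file paths.
#' @param path optional JSON file to write the manifest to.
#' @return the manifest as a list, invisibly if written.
#' @export
run_manifest <- function(config, seed = NA_integer_, iterations = NA_integer_,
                         outputs = character(), path = NULL) {
  m <- list(
    tool = "mobcea",
    tool_version = as.character(utils::packageVersion("mobcea")),
    schema_version = config$schema_version,
    config_digest = config_digest(config),
    seed = seed,
    iterations = iterations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(basename(outputs))
  )
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(m))
  }
  m
}

#' Path of the packaged base-case configuration document
#'
#' The built-in fixture is also shipped as a YAML document so the command-line
#' interface can run with no arguments.
#'
#' @return a file path inside the installed package.
#' @export
base_case_config_path <- function() {
  system.file("extdata", "base_case.yaml", package = "mobcea", mustWork = TRUE)
}
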