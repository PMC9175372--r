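## File interfaces: JSON reports with provenance, CSV decision tables and
## patient tables with a JSON sidecar, and small readers for interim /
## two-arm count files and simulator configuration.

provenance <- function(params = list(), seed = NULL) {
  list(package = "ppostrial",
       version = as.character(utils::packageVersion("ppostrial")),
       parameters = params, seed = seed)
}

#' Write a JSON report with a provenance header
#'
#' Results are wrapped as `{provenance: {package, version, parameters,
#' seed}, results: ...}` so every output records how it was produced.
#' No timestamps are embedded: identical inputs give byte-identical
#' files.
#'
#' @param results A list (or other jsonlite-serializable object).
#' @param path Output path.
#' @param params Named list of the parameters that produced the result.
#' @param seed Seed used, if any.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(results, path, params = list(), seed = NULL) {
  jsonlite::write_json(list(provenance = provenance(params, seed),
                            results = results),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write an interim decision table as CSV
#'
#' Emits comment lines (`#`) carrying provenance and the table's
#' parameters, then the `x1, ppos, decision` table.
#'
#' @param rules An [bayesian_interim_rules()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decision_table_csv <- function(rules, path) {
  stopifnot(inherits(rules, "interim_decision_table"))
  hdr <- c(
    sprintf("# package: ppostrial %s",
            as.character(utils::packageVersion("ppostrial"))),
    sprintf("# n1: %d", attr(rules, "n1")),
    sprintf("# n_total: %d", attr(rules, "n_total")),
    sprintf("# r_total: %s", attr(rules, "r_total")),
    sprintf("# futility_cut: %g", attr(rules, "futility_cut")),
    sprintf("# efficacy_cut: %g", attr(rules, "efficacy_cut")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(rules), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a decision table written by [write_decision_table_csv()]
#' @param path CSV path.
#' @return A data frame with columns `x1`, `ppos`, `decision`.
#' @export
read_decision_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read interim counts from a two-column CSV
#'
#' @param path CSV with columns `responders` and `evaluable` (one row).
#' @return A [binomial_data()].
#' @export
read_interim_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("responders", "evaluable")
  if (!all(need %in% names(df)))
    stopf("interim CSV must have columns: %s", paste(need, collapse = ", "))
  binomial_data(df$responders[1L], df$evaluable[1L])
}

#' Read two-arm counts from a CSV
#'
#' @param path CSV with columns `arm` (values `B` and `C`),
#'   `responders` and `evaluable`.
#' @return A [two_arm_data()].
#' @export
read_two_arm_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("arm", "responders", "evaluable")
  if (!all(need %in% names(df)))
    stopf("two-arm CSV must have columns: %s", paste(need, collapse = ", "))
  pick <- function(a) {
    i <- which(df$arm == a)
    if (!length(i)) stopf("two-arm CSV is missing a row for arm %s", a)
    i[1L]
  }
  ib <- pick("B"); ic <- pick("C")
  two_arm_data(df$responders[ib], df$evaluable[ib],
               df$responders[ic], df$evaluable[ic])
}

#' Write a simulated patient table with a JSON sidecar
#'
#' The CSV holds the patient records; `<path>.json` records the
#' generating configuration (including the seed) so the table can be
#' reproduced exactly.
#'
#' @param patients A [simulate_trial()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  stopifnot(inherits(patients, "trial_patients"))
  utils::write.csv(as.data.frame(patients), path, row.names = FALSE,
                   quote = FALSE)
  cfg <- attr(patients, "config")
  write_json_report(unclass(cfg), paste0(path, ".json"),
                    params = list(subcommand = "simulate"), seed = cfg$seed)
  invisible(path)
}

patient_table_columns <- c(
  "patient_id", "arm", "baseline_sum_mm", "week6_sum_mm", "new_lesions",
  "radiological_category", "radiological_response", "biological_change_pct",
  "biological_response", "composite_responder")

#' Read a patient table CSV, enforcing the documented schema
#' @param path CSV path written by [write_patient_table()].
#' @return A data frame.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(patient_table_columns, names(df))
  if (length(missing))
    stopf("patient table is missing columns: %s",
          paste(missing, collapse = ", "))
  df
}

#' Read simulator configuration from YAML or key=value text
#'
#' Keys match the arguments of [simulation_config()]; unknown keys are
#' rejected with a message listing them. Files ending in `.yaml`/`.yml`
#' are parsed as YAML, anything else as `key = value` lines.
#'
#' @param path Configuration file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
    kv <- strsplit(lines, "\\s*[=:]\\s*")
    bad <- lengths(kv) != 2L
    if (any(bad)) stopf("cannot parse config line(s): %s",
                        paste(lines[bad], collapse = "; "))
    stats::setNames(lapply(kv, function(p) {
      v <- strsplit(p[2L], "\\s*,\\s*")[[1L]]
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) num else v
    }), vapply(kv, `[`, "", 1L))
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}
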