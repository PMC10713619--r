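#' Read a configuration file
#'
#' Reads a YAML or JSON key-value file whose keys mirror the parameter
#' symbols (`R`, `N_C`, `N_T`, `v_T`, `v_D`, `v_G`, `delta_t`, `r_min`,
#' `r_haz`, `r_learn`, `T_hunt`, `T_rest`, `T_max`, `model`, `seed`, ...)
#' and builds a validated [chase_config()]; unknown keys are an error,
#' missing ones take the defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param overrides Named list applied on top of the file's values (used by
#'   the command-line interface for flag overrides).
#' @return A `chase_config`.
#' @export
read_chase_config <- function(path, overrides = list()) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(chase_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(paste("unknown configuration keys:",
                       paste(unknown, collapse = ", ")),
                 class = "chase_invalid_parameter")
  }
  do.call(chase_config, vals)
}

#' Write the capture log
#'
#' CSV with header `t,chaser_id,strategy,target_id,x,y,n_G,n_D`, one row
#' per capture event.
#'
#' @param run A `chase_run` (or a capture tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_capture_log <- function(run, path) {
  df <- if (inherits(run, "chase_run")) run$captures else run
  readr::write_csv(df[, c("t", "chaser_id", "strategy", "target_id",
                          "x", "y", "n_G", "n_D")], path)
  invisible(path)
}

#' Write the strategy-count time series
#'
#' CSV with header `t,n_gcs,n_dcs`.
#'
#' @inheritParams write_capture_log
#' @export
write_strategy_series <- function(run, path) {
  df <- if (inherits(run, "chase_run")) run$series else run
  readr::write_csv(df[, c("t", "n_gcs", "n_dcs")], path)
  invisible(path)
}

#' Write the fitness table
#'
#' CSV with header `n_G,n_D,N,H_G,H_D,f_G,f_D`; undefined fitness values
#' are written as empty fields.
#'
#' @param table A `chase_fitness_table`.
#' @param path Output path.
#' @export
write_fitness_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table)[, c("n_G", "n_D", "N", "H_G",
                                                "H_D", "f_G", "f_D")],
                   path, na = "")
  invisible(path)
}

#' Write the run summary
#'
#' JSON with the configuration echo, seed, capture totals per strategy, and
#' the fixation outcome; together with the seed it suffices to regenerate
#' the run bit-exactly.
#'
#' @inheritParams write_capture_log
#' @export
write_run_summary <- function(run, path) {
  stopifnot(inherits(run, "chase_run"))
  summary <- list(
    config = unclass(run$cfg),
    seed = run$seed,
    t_final = run$world$t,
    captures_total = nrow(run$captures),
    captures_gcs = sum(run$captures$strategy == "GCS"),
    captures_dcs = sum(run$captures$strategy == "DCS"),
    fixation = run$fixation$outcome,
    fixation_time = run$fixation$time
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
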