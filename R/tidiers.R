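#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run
#'
#' @param x A `chase_run`.
#' @param ... Unused.
#' @return The capture log as a tibble (one row per capture event).
#' @export
tidy.chase_run <- function(x, ...) x$captures

#' One-row summary of a simulation run
#'
#' @param x A `chase_run`.
#' @param ... Unused.
#' @return A one-row tibble: seed, model, horizon, capture totals per
#'   strategy, final strategy counts, fixation outcome and time.
#' @export
glance.chase_run <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    model = x$cfg$model,
    t_max = x$cfg$T_max,
    n_captures = nrow(x$captures),
    captures_per_chaser = nrow(x$captures) / x$cfg$N_C,
    n_gcs_final = sum(x$world$strategy == 1L),
    n_dcs_final = sum(x$world$strategy == 0L),
    fixation = x$fixation$outcome,
    fixation_time = x$fixation$time
  )
}

#' Tidy an ensemble
#'
#' @param x A `chase_ensemble`.
#' @param ... Unused.
#' @return One [glance.chase_run()] row per member run, with a `run` column.
#' @export
tidy.chase_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$runs, function(r, k) {
    dplyr::mutate(glance(r), run = k, .before = 1)
  })
}

#' One-row summary of an ensemble
#'
#' @param x A `chase_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: number of runs, total captures, and the
#'   fixation counts/probabilities.
#' @export
glance.chase_ensemble <- function(x, ...) {
  fx <- fixation_probability(x)
  tibble::tibble(
    n_runs = length(x$runs),
    model = x$cfg$model,
    n_captures = sum(purrr::map_int(x$runs, function(r) nrow(r$captures))),
    p_fix_gcs = fx$p_fix[fx$outcome == "GCS"],
    p_fix_dcs = fx$p_fix[fx$outcome == "DCS"],
    p_no_fix = fx$p_fix[fx$outcome == "none"]
  )
}
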