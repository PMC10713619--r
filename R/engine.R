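#' Advance a world with the compiled engine
#'
#' Runs `n` steps of the optimized per-step update, consuming R's global RNG
#' stream exactly as [reference_step()] does (so a `set.seed()` replay is
#' bitwise identical between the two implementations).
#'
#' @param world A `chase_world`.
#' @param n Number of steps.
#' @return A list: the new `world` and the `captures` tibble for the steps
#'   taken.
#' @examples
#' set.seed(1)
#' w <- initialize_world(chase_config(N_C = 10, N_T = 5, T_max = 100))
#' s <- sim_step(w, 10)
#' s$world$t
#' @export
sim_step <- function(world, n = 1L) {
  stopifnot(inherits(world, "chase_world"), n >= 1)
  res <- .cpp_run(world, as.integer(n))
  list(world = res$world, captures = .captures_tibble(res$captures))
}

.captures_tibble <- function(cl) {
  tibble::tibble(
    t = as.numeric(cl$t),
    chaser_id = as.integer(cl$chaser_id) + 1L,
    strategy = ifelse(as.integer(cl$strategy) == 1L, "GCS", "DCS"),
    target_id = as.integer(cl$target_id) + 1L,
    x = as.numeric(cl$x), y = as.numeric(cl$y),
    n_G = as.integer(cl$n_G), n_D = as.integer(cl$n_D),
    in_set = as.integer(cl$in_set) == 1L
  )
}

#' Run one simulation
#'
#' Seeds the RNG, places the initial population, and iterates the per-step
#' update until `t` reaches `T_max` (`T_max / delta_t` steps), accumulating
#' every observable along the way: the capture log, the strategy-count time
#' series, set-class counts and per-class capture counts inside the
#' steady-state window, windowed hunting-performance accumulators, and (for
#' model C) the fixation record. A population that starts homogeneous under
#' model C is recorded as fixed at `t = 0`.
#'
#' @param cfg A [chase_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return A `chase_run` object: list with `cfg`, `seed`, `world` (final
#'   state), `captures`, `series` (tibble `t, n_gcs, n_dcs`),
#'   `class_counts` (tibble `n_G, n_D, N, H_G, H_D`), `h_bins` (per-window
#'   accumulators), `fixation` (list `outcome`, `time`), and `n_unclassed`
#'   (captures whose capturer was not in the start-of-step set; excluded
#'   from the fitness accumulators).
#' @examples
#' run <- run_simulation(chase_config(N_C = 20, N_T = 10, T_max = 2000,
#'                                    ss_window = c(0, 2000)), seed = 1)
#' nrow(run$captures)
#' @export
run_simulation <- function(cfg, seed = cfg$seed) {
  cfg <- validate_config(cfg)
  set.seed(seed)
  world <- initialize_world(cfg)
  nsteps <- as.integer(round(cfg$T_max / cfg$delta_t))
  res <- .cpp_run(world, nsteps)
  fx <- res$fixation_strategy
  structure(list(
    cfg = cfg,
    seed = as.integer(seed),
    world = res$world,
    captures = .captures_tibble(res$captures),
    series = tibble::tibble(
      t = as.numeric(res$series_t),
      n_gcs = as.integer(res$series_gcs),
      n_dcs = cfg$N_C - as.integer(res$series_gcs)
    ),
    class_counts = tibble::tibble(
      n_G = as.integer(res$class_counts$n_G),
      n_D = as.integer(res$class_counts$n_D),
      N = as.numeric(res$class_counts$N),
      H_G = as.numeric(res$class_counts$H_G),
      H_D = as.numeric(res$class_counts$H_D)
    ),
    h_bins = tibble::as_tibble(res$h_bins),
    fixation = list(
      outcome = if (fx < 0) "none" else if (fx == 1L) "GCS" else "DCS",
      time = if (res$fixation_time < 0) NA_real_ else res$fixation_time
    ),
    n_unclassed = as.numeric(res$n_unclassed)
  ), class = "chase_run")
}

#' @export
print.chase_run <- function(x, ...) {
  cat(sprintf("<chase_run> model %s, seed %d, t=%g\n",
              x$cfg$model, x$seed, x$world$t))
  cat(sprintf("  %d captures; final %d GCS / %d DCS\n",
              nrow(x$captures), sum(x$world$strategy == 1L),
              sum(x$world$strategy == 0L)))
  if (x$cfg$model == "C") {
    cat(sprintf("  fixation: %s at t=%s\n", x$fixation$outcome,
                format(x$fixation$time)))
  }
  invisible(x)
}

#' Run an ensemble of independent simulations
#'
#' Member `k` (1-based) uses seed `base_seed + k - 1`; members are mutually
#' independent and the aggregate does not depend on execution order.
#'
#' @param cfg A [chase_config()].
#' @param n_runs Number of independent runs.
#' @param base_seed First seed; defaults to `cfg$seed`.
#' @param .progress Passed to [purrr::map()].
#' @return A `chase_ensemble`: list with `cfg`, `seeds`, `runs` (list of
#'   `chase_run`), and `class_counts` (counts summed over runs).
#' @export
run_ensemble <- function(cfg, n_runs, base_seed = cfg$seed,
                         .progress = FALSE) {
  stopifnot(n_runs >= 1)
  seeds <- base_seed + seq_len(n_runs) - 1L
  runs <- purrr::map(seeds, function(s) run_simulation(cfg, seed = s),
                     .progress = .progress)
  cc <- purrr::map_dfr(runs, "class_counts") |>
    dplyr::group_by(.data$n_G, .data$n_D) |>
    dplyr::summarise(N = sum(.data$N), H_G = sum(.data$H_G),
                     H_D = sum(.data$H_D), .groups = "drop")
  structure(list(cfg = cfg, seeds = as.integer(seeds), runs = runs,
                 class_counts = cc),
            class = "chase_ensemble")
}

#' @export
print.chase_ensemble <- function(x, ...) {
  cat(sprintf("<chase_ensemble> %d runs, model %s, seeds %d..%d\n",
              length(x$runs), x$cfg$model, min(x$seeds), max(x$seeds)))
  invisible(x)
}
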