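#' Build a simulation configuration
#'
#' Assembles and validates the full parameter set of a group chase-and-escape
#' simulation: a disk habitat of radius `R` containing `N_T` targets (prey)
#' and `N_C` chasers (predators). Chasers follow one of two pursuit rules
#' while in hunting mode: the direct chasing strategy (DCS) moves straight at
#' the nearest target at speed `v_D`; the group chasing strategy (GCS) moves
#' so that the nearest target would sit at the centroid of all chasers at
#' least as close to it, at the reduced speed `v_G` (the cost of the
#' cognitive load). Targets flee the nearest hazard (chaser or habitat
#' boundary) within recognition range `r_haz`, otherwise they random-walk.
#'
#' The defaults are the reference parameter set of the study conditions:
#' `R = 500`, `N_C = 100`, `N_T = 50`, `v_G = 0.07`, `v_T = 0.1`,
#' `v_D` in \[0.072, 0.098\] (default 0.082), `delta_t = 1`, `r_min = 0.15`,
#' `r_haz = 50`, `r_learn = 200`, `T_hunt = T_rest = 1e3`, `T_max = 1e6`.
#' All lengths share one arbitrary length unit; times are in units of
#' `delta_t`; speeds in length per time.
#'
#' @param R Habitat (disk) radius.
#' @param N_C,N_T Number of chasers and targets. Both stay constant during a
#'   run: a captured target is immediately replaced at a random position.
#' @param v_T,v_D,v_G Speeds of targets, DCS chasers, and GCS chasers. The
#'   model requires the strict ordering `v_G < v_D < v_T` (cooperation costs
#'   speed; prey outrun any single predator).
#' @param delta_t Time step; the minimum duration of straight-line motion.
#' @param r_min Minimal separation between agents of the same species; moves
#'   that would violate it are rejected.
#' @param r_haz Range within which a target recognizes a hazard.
#' @param r_learn Learning radius of model C: after a capture, chasers within
#'   `r_learn` of the captured target adopt the capturer's strategy.
#' @param T_hunt,T_rest Maximal hunting and resting spell durations; the
#'   switch probability ramps linearly as `min(t/T, 1)`.
#' @param T_max Simulation horizon; a run executes `T_max / delta_t` steps.
#' @param model Variant: `"A_DCS"` and `"A_GCS"` are single-strategy
#'   populations, `"B"` mixes both without learning, `"C"` adds imitation
#'   learning.
#' @param gcs_fraction Fraction of chasers initialized as GCS. Forced to 0
#'   for `A_DCS` and 1 for `A_GCS`; defaults to 0.5 for models B and C.
#' @param seed Default RNG seed used by [run_simulation()].
#' @param eps_capture Capture coincidence tolerance: a target is captured
#'   when an updated chaser position lies within `eps_capture` of it. The
#'   snap rule copies coordinates exactly, so this only absorbs transport
#'   rounding; it must be far below `r_min`.
#' @param max_placement_attempts Cap on rejection-sampling attempts when
#'   placing an agent at least `r_min` from its neighbours.
#' @param sample_every Stride (in steps) of the strategy-count time series.
#' @param ss_window Length-2 numeric, steady-state measurement window
#'   `[t_start, t_end]` used for the set-class/fitness accumulators.
#' @param h_window Width of the hunting-performance windows.
#' @param resting_are_hazards Should resting chasers frighten targets? The
#'   flight rule names "chasers" without a mode qualifier, so the default is
#'   `TRUE`; exposed for sensitivity analysis.
#' @param resting_in_gamma Should resting chasers count as members of a GCS
#'   chaser's reference group? Default `TRUE`, same reasoning.
#' @param resting_in_sets Should resting chasers count as members of
#'   pursuing sets for the observables? Default `FALSE` (a resting chaser
#'   is not pursuing); exposed for sensitivity analysis.
#' @param enforce_speed_order Require `v_G < v_D < v_T` strictly. Disabling
#'   it permits deliberately degenerate configurations such as the
#'   equal-ability null calibration `v_D = v_G`.
#'
#' @return A validated `chase_config` object (a named list).
#' @seealso [run_simulation()], [initialize_world()]
#' @examples
#' cfg <- chase_config(model = "B", T_max = 1e4)
#' cfg$v_D
#' @export
chase_config <- function(R = 500, N_C = 100L, N_T = 50L,
                         v_T = 0.1, v_D = 0.082, v_G = 0.07,
                         delta_t = 1, r_min = 0.15, r_haz = 50, r_learn = 200,
                         T_hunt = 1e3, T_rest = 1e3, T_max = 1e6,
                         model = c("B", "A_DCS", "A_GCS", "C"),
                         gcs_fraction = NULL, seed = 1L,
                         eps_capture = 1e-6, max_placement_attempts = 10000L,
                         sample_every = 1000L, ss_window = c(5e5, 9e5),
                         h_window = 2e4,
                         resting_are_hazards = TRUE, resting_in_gamma = TRUE,
                         resting_in_sets = FALSE,
                         enforce_speed_order = TRUE) {
  model <- match.arg(model)
  if (is.null(gcs_fraction)) {
    gcs_fraction <- switch(model, A_DCS = 0, A_GCS = 1, 0.5)
  }
  cfg <- structure(list(
    R = as.numeric(R), N_C = as.integer(N_C), N_T = as.integer(N_T),
    v_T = as.numeric(v_T), v_D = as.numeric(v_D), v_G = as.numeric(v_G),
    delta_t = as.numeric(delta_t), r_min = as.numeric(r_min),
    r_haz = as.numeric(r_haz), r_learn = as.numeric(r_learn),
    T_hunt = as.numeric(T_hunt), T_rest = as.numeric(T_rest),
    T_max = as.numeric(T_max), model = model,
    gcs_fraction = as.numeric(gcs_fraction), seed = as.integer(seed),
    eps_capture = as.numeric(eps_capture),
    max_placement_attempts = as.integer(max_placement_attempts),
    sample_every = as.integer(sample_every),
    ss_window = as.numeric(ss_window), h_window = as.numeric(h_window),
    resting_are_hazards = isTRUE(resting_are_hazards),
    resting_in_gamma = isTRUE(resting_in_gamma),
    resting_in_sets = isTRUE(resting_in_sets),
    enforce_speed_order = isTRUE(enforce_speed_order)
  ), class = "chase_config")
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of a `chase_config`: positive lengths and speeds,
#' the strict speed ordering `v_G < v_D < v_T` (unless
#' `enforce_speed_order = FALSE`), `r_min < r_haz < R`, at least one agent of
#' each species, a horizon of at least one step, and a strategy composition
#' consistent with the model variant.
#'
#' @param cfg A `chase_config` (or a plain named list with the same fields).
#' @return `cfg`, unchanged, if valid; otherwise an error is signalled with
#'   class `chase_speed_order_error` ("speed-ordering violation") or
#'   `chase_invalid_parameter`.
#' @examples
#' validate_config(chase_config())
#' @export
validate_config <- function(cfg) {
  bad <- function(msg) {
    rlang::abort(paste0("invalid parameter: ", msg),
                 class = "chase_invalid_parameter")
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("R", "v_T", "v_D", "v_G", "delta_t", "r_min", "r_haz",
              "r_learn", "T_hunt", "T_rest", "T_max", "eps_capture")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0) bad(paste0(f, " must be positive"))
  }
  if (!cfg$model %in% c("A_DCS", "A_GCS", "B", "C")) bad("unknown model")
  if (isTRUE(cfg$enforce_speed_order) &&
      !(cfg$v_G < cfg$v_D && cfg$v_D < cfg$v_T)) {
    rlang::abort("speed-ordering violation: v_G < v_D < v_T is required",
                 class = "chase_speed_order_error")
  }
  if (!(cfg$r_min < cfg$r_haz && cfg$r_haz < cfg$R)) {
    bad("r_min < r_haz < R is required")
  }
  if (!num1(as.numeric(cfg$N_C)) || cfg$N_C < 1L) bad("N_C must be >= 1")
  if (!num1(as.numeric(cfg$N_T)) || cfg$N_T < 1L) bad("N_T must be >= 1")
  if (cfg$T_max < cfg$delta_t) bad("T_max must be at least delta_t")
  if (!num1(cfg$gcs_fraction) || cfg$gcs_fraction < 0 ||
      cfg$gcs_fraction > 1) bad("gcs_fraction must lie in [0, 1]")
  if (cfg$model == "A_DCS" && cfg$gcs_fraction != 0) {
    bad("model A_DCS requires gcs_fraction = 0")
  }
  if (cfg$model == "A_GCS" && cfg$gcs_fraction != 1) {
    bad("model A_GCS requires gcs_fraction = 1")
  }
  if (cfg$max_placement_attempts < 1L) bad("max_placement_attempts")
  if (cfg$sample_every < 1L) bad("sample_every must be >= 1")
  if (length(cfg$ss_window) != 2L || !all(is.finite(cfg$ss_window)) ||
      cfg$ss_window[1] < 0 || cfg$ss_window[1] >= cfg$ss_window[2]) {
    bad("ss_window must be an increasing pair of times")
  }
  if (!num1(cfg$h_window) || cfg$h_window <= 0) bad("h_window")
  cfg
}

#' @export
print.chase_config <- function(x, ...) {
  cat("<chase_config> model", x$model, "\n")
  cat(sprintf("  disk R=%g, N_C=%d, N_T=%d\n", x$R, x$N_C, x$N_T))
  cat(sprintf("  speeds v_G=%g < v_D=%g < v_T=%g\n", x$v_G, x$v_D, x$v_T))
  cat(sprintf("  r_min=%g r_haz=%g r_learn=%g\n", x$r_min, x$r_haz, x$r_learn))
  cat(sprintf("  T_hunt=%g T_rest=%g T_max=%g delta_t=%g\n",
              x$T_hunt, x$T_rest, x$T_max, x$delta_t))
  cat(sprintf("  gcs_fraction=%g seed=%d\n", x$gcs_fraction, x$seed))
  invisible(x)
}

# one area-uniform draw inside the disk, by rejection from the bounding
# square; the draw sequence must match the C++ engine exactly
.disk_point <- function(R) {
  repeat {
    x <- (2 * stats::runif(1) - 1) * R
    y <- (2 * stats::runif(1) - 1) * R
    if (x * x + y * y <= R * R) return(c(x, y))
  }
}

# random unit vector via one uniform angle draw (matches the C++ engine)
.runit <- function() {
  th <- 2 * pi * stats::runif(1)
  c(cos(th), sin(th))
}

# Fisher-Yates permutation driven by raw uniforms, identical to the C++
# implementation (base::sample would not reproduce the same stream)
.fy_perm <- function(n) {
  p <- seq_len(n)
  if (n >= 2L) {
    for (k in seq(n, 2L)) {
      j <- floor(stats::runif(1) * k) + 1
      if (j > k) j <- k
      tmp <- p[k]; p[k] <- p[j]; p[j] <- tmp
    }
  }
  p
}

#' Draw points uniformly by area in a disk
#'
#' Rejection-samples from the bounding square, giving the exact area-uniform
#' law on the closed disk of radius `R` centred at the origin
#' (so `E|r|^2 = R^2/2` and the angle is uniform).
#'
#' @param n Number of points.
#' @param R Disk radius (> 0).
#' @return An `n` x 2 matrix of coordinates.
#' @examples
#' set.seed(1)
#' p <- uniform_point_in_disk(100, 500)
#' max(sqrt(rowSums(p^2))) <= 500
#' @export
uniform_point_in_disk <- function(n, R) {
  stopifnot(is.numeric(R), length(R) == 1L, R > 0, n >= 0)
  out <- matrix(0, nrow = n, ncol = 2)
  for (i in seq_len(n)) out[i, ] <- .disk_point(R)
  out
}

#' Clamp points radially onto a disk
#'
#' Points outside the disk of radius `R` are scaled radially back onto the
#' boundary circle; interior points are returned untouched. This is the
#' boundary safety net of the movement engine (targets already flee the
#' boundary within `r_haz`, so clamping is rarely exercised).
#'
#' @param p A length-2 numeric vector or an n x 2 matrix.
#' @param R Disk radius.
#' @return Same shape as `p`.
#' @examples
#' clamp_to_disk(c(600, 0), 500)
#' @export
clamp_to_disk <- function(p, R) {
  if (is.matrix(p)) {
    for (i in seq_len(nrow(p))) p[i, ] <- clamp_to_disk(p[i, ], R)
    p
  } else {
    # iterate: one scaling can leave |p| a rounding error above R, and the
    # clamp must be exactly idempotent; after two passes force a strict
    # shrink so a half-ulp tie cannot stall the loop
    n2 <- p[1]^2 + p[2]^2
    iter <- 0L
    while (n2 > R * R) {
      s <- R / sqrt(n2)
      if (iter >= 2L) s <- s * (1 - 2.220446049250313e-16)
      p <- p * s
      n2 <- p[1]^2 + p[2]^2
      iter <- iter + 1L
    }
    p
  }
}
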