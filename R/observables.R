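#' Identify pursuing sets
#'
#' A set is the group of hunting-mode chasers whose nearest target is the
#' same target; resting chasers pursue nothing and appear in no set. Ties in
#' the nearest-target scan break to the lowest target id, matching the
#' engine.
#'
#' @param world A `chase_world`.
#' @return A tibble with one row per pursuing chaser: `target_id`,
#'   `chaser_id`, `strategy`, plus the per-set composition columns `n_G`,
#'   `n_D`.
#' @export
identify_sets <- function(world) {
  dec <- .decompose(world)
  keep <- which(!is.na(dec$nt))
  out <- tibble::tibble(
    target_id = dec$nt[keep],
    chaser_id = keep,
    strategy = ifelse(world$strategy[keep] == 1L, "GCS", "DCS")
  )
  out$n_G <- dec$n_g[out$target_id]
  out$n_D <- dec$n_d[out$target_id]
  dplyr::arrange(out, .data$target_id, .data$chaser_id)
}

#' Windowed hunting performance
#'
#' The hunting performance `h(t)` is the number of targets captured during
#' the window `(t - dt_w/2, t + dt_w/2)` per chaser, on non-overlapping
#' windows of width `dt_w = h_window` centred at `t = dt_w/2, 3 dt_w/2, ...`
#' For a single-strategy population the denominator is `N_C`. The stratified
#' variant (models B/C) splits captures by the capturer's strategy and by
#' whether the pursuing set was homogeneous or heterogeneous, and divides by
#' the time-averaged number of chasers of that strategy in sets of that
#' category over the window; windows with an empty denominator yield `NA`.
#'
#' @param x A `chase_run`, `chase_ensemble`, or a capture-log data frame.
#' @param ... Passed between methods.
#' @return A tibble with columns `t`, `h` (plus `strategy`, `category` when
#'   stratified, and `run` for ensembles).
#' @export
hunting_performance <- function(x, ...) UseMethod("hunting_performance")

#' @rdname hunting_performance
#' @param stratified Split by strategy and set category (models B/C)?
#' @export
hunting_performance.chase_run <- function(x, stratified = FALSE, ...) {
  hb <- x$h_bins
  hb <- hb[hb$steps > 0, , drop = FALSE]
  if (!stratified) {
    return(tibble::tibble(t = hb$t, h = hb$capt_total / x$cfg$N_C))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(t = hb$t, steps = hb$steps, strategy = "GCS",
                   category = "homogeneous",
                   capt = hb$capt_G_hom, occ = hb$occ_G_hom),
    tibble::tibble(t = hb$t, steps = hb$steps, strategy = "GCS",
                   category = "heterogeneous",
                   capt = hb$capt_G_het, occ = hb$occ_G_het),
    tibble::tibble(t = hb$t, steps = hb$steps, strategy = "DCS",
                   category = "homogeneous",
                   capt = hb$capt_D_hom, occ = hb$occ_D_hom),
    tibble::tibble(t = hb$t, steps = hb$steps, strategy = "DCS",
                   category = "heterogeneous",
                   capt = hb$capt_D_het, occ = hb$occ_D_het)
  )
  long$h <- ifelse(long$occ > 0, long$capt / (long$occ / long$steps),
                   NA_real_)
  dplyr::select(long, "t", "strategy", "category", "h")
}

#' @rdname hunting_performance
#' @export
hunting_performance.chase_ensemble <- function(x, stratified = FALSE, ...) {
  purrr::imap_dfr(x$runs, function(r, k) {
    dplyr::mutate(hunting_performance(r, stratified = stratified),
                  run = k, .before = 1)
  })
}

#' @rdname hunting_performance
#' @param n_chasers Denominator for the data-frame method.
#' @param h_window Window width for the data-frame method.
#' @param t_max Horizon defining the window grid.
#' @export
hunting_performance.data.frame <- function(x, n_chasers, h_window, t_max,
                                           ...) {
  stopifnot(h_window > 0, n_chasers >= 1)
  nb <- max(1L, as.integer(ceiling(t_max / h_window)))
  b <- pmin(pmax(floor(x$t / h_window), 0), nb - 1)
  counts <- tabulate(b + 1L, nbins = nb)
  tibble::tibble(t = (seq_len(nb) - 0.5) * h_window,
                 h = counts / n_chasers)
}

#' Set-class fitness table
#'
#' Classifies pursuing sets by their strategy composition `(n_G, n_D)` and
#' computes each strategy's relative hunting performance per class:
#' `f_G = (H_G / H_total) / (N_G / NC_total)` with `N_G = n_G * N`, where
#' `N` counts the class's set observations (one per set per step inside the
#' steady-state window), `H_G` the captures by GCS chasers in such sets,
#' `H_total` the table-wide capture count, and `NC_total` the table-wide
#' chaser-observation count; `f_D` symmetrically. A fitness of 1 means
#' average ability; classes with no members of a strategy get `NA`.
#'
#' @param x A `chase_run`, `chase_ensemble`, or a data frame with columns
#'   `n_G, n_D, N, H_G, H_D`.
#' @param ... Unused.
#' @return A `chase_fitness_table` tibble with `f_G`, `f_D` added and
#'   attributes `H_total`, `NC_total`.
#' @export
fitness_table <- function(x, ...) UseMethod("fitness_table")

#' @rdname fitness_table
#' @export
fitness_table.chase_run <- function(x, ...) {
  compute_fitness_table(x$class_counts)
}

#' @rdname fitness_table
#' @export
fitness_table.chase_ensemble <- function(x, ...) {
  compute_fitness_table(x$class_counts)
}

#' @rdname fitness_table
#' @export
fitness_table.data.frame <- function(x, ...) compute_fitness_table(x)

#' @rdname fitness_table
#' @param counts Data frame of accumulated counts (`n_G, n_D, N, H_G, H_D`).
#' @export
compute_fitness_table <- function(counts) {
  stopifnot(all(c("n_G", "n_D", "N", "H_G", "H_D") %in% names(counts)))
  counts <- tibble::as_tibble(counts)
  h_total <- sum(counts$H_G + counts$H_D)
  nc_total <- sum((counts$n_G + counts$n_D) * counts$N)
  if (h_total <= 0) {
    rlang::abort("no captures accumulated: fitness is undefined",
                 class = "chase_no_captures")
  }
  n_g <- counts$n_G * counts$N
  n_d <- counts$n_D * counts$N
  counts$f_G <- ifelse(n_g > 0, (counts$H_G / h_total) / (n_g / nc_total),
                       NA_real_)
  counts$f_D <- ifelse(n_d > 0, (counts$H_D / h_total) / (n_d / nc_total),
                       NA_real_)
  structure(counts, H_total = h_total, NC_total = nc_total,
            class = c("chase_fitness_table", class(counts)))
}

#' Nash-arrow analysis of a fitness table
#'
#' A GCS chaser in an `(n_G, n_D)`-set that switched to DCS would sit in an
#' `(n_G - 1, n_D + 1)`-set; an arrow `G2D` at `(n_G, n_D)` marks
#' `f_G(n_G, n_D) < f_D(n_G - 1, n_D + 1)`, a profitable defection. `D2G`
#' arrows are the mirror case. A cell is an equilibrium cell when none of
#' its occupants can gain by switching (both strict inequalities fail),
#' holding the set size `n_G + n_D` fixed. Comparisons touching an
#' undefined fitness are skipped and reported.
#'
#' @param table A `chase_fitness_table` (or compatible data frame).
#' @param max_n Largest `n_G` and `n_D` displayed/compared.
#' @return A `chase_nash` list: `arrows` (tibble `n_G, n_D, arrow`),
#'   `equilibria` (tibble of cells), `skipped` (tibble of untestable
#'   comparisons).
#' @export
nash_arrows <- function(table, max_n = 9L) {
  f_g <- function(g, d) {
    i <- which(table$n_G == g & table$n_D == d)
    if (length(i) == 0L) NA_real_ else table$f_G[i[1]]
  }
  f_d <- function(g, d) {
    i <- which(table$n_G == g & table$n_D == d)
    if (length(i) == 0L) NA_real_ else table$f_D[i[1]]
  }
  arrows <- list(); eq <- list(); skipped <- list()
  for (g in 0:max_n) {
    for (d in 0:max_n) {
      if (g + d == 0L) next
      g2d <- NA; d2g <- NA
      if (g >= 1L) {
        a <- f_g(g, d); b <- f_d(g - 1L, d + 1L)
        if (is.na(a) || is.na(b)) {
          skipped[[length(skipped) + 1L]] <- c(g, d, 1L)
        } else {
          g2d <- a < b
          if (isTRUE(g2d)) arrows[[length(arrows) + 1L]] <- c(g, d, 1L)
        }
      }
      if (d >= 1L) {
        a <- f_d(g, d); b <- f_g(g + 1L, d - 1L)
        if (is.na(a) || is.na(b)) {
          skipped[[length(skipped) + 1L]] <- c(g, d, 2L)
        } else {
          d2g <- a < b
          if (isTRUE(d2g)) arrows[[length(arrows) + 1L]] <- c(g, d, 2L)
        }
      }
      occupied_checks <- c(if (g >= 1L) g2d, if (d >= 1L) d2g)
      if (length(occupied_checks) > 0 && !anyNA(occupied_checks) &&
          !any(unlist(occupied_checks))) {
        eq[[length(eq) + 1L]] <- c(g, d)
      }
    }
  }
  to_tbl <- function(lst, lab) {
    if (length(lst) == 0L) {
      return(tibble::tibble(n_G = integer(0), n_D = integer(0),
                            arrow = character(0)))
    }
    m <- do.call(rbind, lst)
    tibble::tibble(n_G = as.integer(m[, 1]), n_D = as.integer(m[, 2]),
                   arrow = c("G2D", "D2G")[m[, 3]])
  }
  eq_tbl <- if (length(eq) == 0L) {
    tibble::tibble(n_G = integer(0), n_D = integer(0))
  } else {
    m <- do.call(rbind, eq)
    tibble::tibble(n_G = as.integer(m[, 1]), n_D = as.integer(m[, 2]))
  }
  structure(list(arrows = to_tbl(arrows), equilibria = eq_tbl,
                 skipped = to_tbl(skipped)),
            class = "chase_nash")
}

#' @export
print.chase_nash <- function(x, ...) {
  cat(sprintf("<chase_nash> %d arrows, %d equilibrium cells, %d skipped\n",
              nrow(x$arrows), nrow(x$equilibria), nrow(x$skipped)))
  invisible(x)
}

#' Detect fixation in a strategy time series
#'
#' Fixation is the absorption of the learning dynamics (model C) at an
#' all-GCS or all-DCS chaser population.
#'
#' @param series Tibble with columns `t` and `n_gcs`.
#' @param n_chasers Population size `N_C`.
#' @return A list: `outcome` in `{"GCS", "DCS", "none"}` and `time` (`NA`
#'   when no fixation occurred).
#' @export
detect_fixation <- function(series, n_chasers) {
  hit <- which(series$n_gcs == n_chasers | series$n_gcs == 0L)
  if (length(hit) == 0L) return(list(outcome = "none", time = NA_real_))
  i <- hit[1]
  list(outcome = if (series$n_gcs[i] == n_chasers) "GCS" else "DCS",
       time = series$t[i])
}

#' Fixation probabilities over an ensemble
#'
#' `P_fix(s)` is the number of runs that fixed to strategy `s` divided by
#' the total number of runs; unfixed runs count only in the denominator.
#' Binomial standard errors are attached.
#'
#' @param x A `chase_ensemble`, or a character vector / data frame of
#'   per-run outcomes (`"GCS"`, `"DCS"`, `"none"`).
#' @return A tibble with one row per outcome: `outcome`, `n`, `p_fix`,
#'   `se`, and mean fixation time where defined.
#' @export
fixation_probability <- function(x) {
  if (inherits(x, "chase_ensemble")) {
    outcomes <- purrr::map_chr(x$runs, function(r) r$fixation$outcome)
    times <- purrr::map_dbl(x$runs, function(r) {
      t <- r$fixation$time
      if (is.null(t)) NA_real_ else t
    })
  } else if (is.data.frame(x)) {
    outcomes <- x$outcome
    times <- if ("time" %in% names(x)) x$time else rep(NA_real_, nrow(x))
  } else {
    outcomes <- as.character(x)
    times <- rep(NA_real_, length(outcomes))
  }
  n_runs <- length(outcomes)
  purrr::map_dfr(c("GCS", "DCS", "none"), function(o) {
    k <- sum(outcomes == o)
    p <- k / n_runs
    tibble::tibble(outcome = o, n = k, p_fix = p,
                   se = sqrt(p * (1 - p) / n_runs),
                   mean_time = if (k > 0) mean(times[outcomes == o],
                                               na.rm = TRUE) else NA_real_)
  })
}

#' Steady-state mean of a windowed series
#'
#' Averages a series over the steady-state window. With a `run` column
#' (ensemble output) the estimate is the mean of per-run means and the
#' standard error comes from the between-run spread (`sd / sqrt(n_runs)`);
#' without one it is a plain mean with the within-series standard error.
#' Grouping columns other than `t`, `run`, and the value column (e.g.
#' `strategy`, `category`) are respected.
#'
#' @param series A tibble containing a time column `t` and a value column.
#' @param window Length-2 numeric `[t_start, t_end]`, both inclusive.
#' @param value Name of the value column (default `"h"`).
#' @return A tibble with the grouping columns plus `mean`, `se`, `n`.
#' @export
steady_state_mean <- function(series, window, value = "h") {
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- series$t >= window[1] & series$t <= window[2]
  if (!any(keep)) {
    rlang::abort("steady-state window contains no observations",
                 class = "chase_empty_window")
  }
  df <- series[keep, , drop = FALSE]
  groups <- setdiff(names(df), c("t", "run", value))
  if ("run" %in% names(df)) {
    per_run <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "run")))) |>
      dplyr::summarise(m = mean(.data[[value]], na.rm = TRUE),
                       .groups = "drop")
    per_run |>
      dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
      dplyr::summarise(mean = mean(.data$m),
                       se = stats::sd(.data$m) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
  } else {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
      dplyr::summarise(mean = mean(.data[[value]], na.rm = TRUE),
                       se = if (dplyr::n() > 1) {
                         stats::sd(.data[[value]], na.rm = TRUE) /
                           sqrt(dplyr::n())
                       } else 0,
                       n = dplyr::n(), .groups = "drop")
  }
}
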