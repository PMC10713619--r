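#' Initialize a world state
#'
#' Places `N_C` chasers and `N_T` targets uniformly in the disk by rejection
#' sampling so that every pair of same-species agents starts at least
#' `r_min` apart (cross-species overlap is permitted; captures only occur
#' through the snap rule). Strategies are assigned per model variant:
#' all-DCS for `A_DCS`, all-GCS for `A_GCS`, and for models B and C a
#' uniformly random subset of `round(gcs_fraction * N_C)` chasers becomes
#' GCS. All chasers start in hunting mode with zeroed timers at `t = 0`.
#'
#' Placement, strategy assignment, and every later stochastic choice draw
#' from R's global RNG stream, so `set.seed()` before this call makes a whole
#' run bitwise reproducible.
#'
#' @param cfg A validated [chase_config()].
#' @return A `chase_world` object: a list with elements `t`, `pos_c`
#'   (`N_C` x 2), `strategy` (integer, 1 = GCS, 0 = DCS), `mode` (integer,
#'   1 = hunt, 0 = rest), `t_hunt`, `t_rest`, `pos_t` (`N_T` x 2), and the
#'   `cfg` that produced it.
#' @examples
#' set.seed(1)
#' w <- initialize_world(chase_config(N_C = 10, N_T = 5))
#' nrow(w$pos_c)
#' @export
initialize_world <- function(cfg) {
  cfg <- validate_config(cfg)
  pos_c <- .place_species(cfg$N_C, cfg)
  pos_t <- .place_species(cfg$N_T, cfg)
  strategy <- integer(cfg$N_C)
  if (cfg$model == "A_GCS") {
    strategy[] <- 1L
  } else if (cfg$model != "A_DCS") {
    n_g <- as.integer(round(cfg$gcs_fraction * cfg$N_C))
    if (n_g > 0L) {
      perm <- .fy_perm(cfg$N_C)
      strategy[perm[seq_len(n_g)]] <- 1L
    }
  }
  structure(list(
    t = 0,
    pos_c = pos_c,
    strategy = strategy,
    mode = rep(1L, cfg$N_C),
    t_hunt = rep(0, cfg$N_C),
    t_rest = rep(0, cfg$N_C),
    pos_t = pos_t,
    cfg = cfg
  ), class = "chase_world")
}

# sequential rejection placement with same-species spacing >= r_min
.place_species <- function(n, cfg) {
  pos <- matrix(0, nrow = n, ncol = 2)
  rmin2 <- cfg$r_min * cfg$r_min
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(cfg$max_placement_attempts)) {
      p <- .disk_point(cfg$R)
      clear <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          dx <- p[1] - pos[j, 1]; dy <- p[2] - pos[j, 2]
          if (dx * dx + dy * dy < rmin2) { clear <- FALSE; break }
        }
      }
      if (clear) { pos[i, ] <- p; ok <- TRUE; break }
    }
    if (!ok) {
      rlang::abort("placement failure: max_placement_attempts exceeded",
                   class = "chase_placement_error")
    }
  }
  pos
}

#' @export
print.chase_world <- function(x, ...) {
  cat(sprintf("<chase_world> t=%g, %d chasers (%d GCS), %d targets\n",
              x$t, nrow(x$pos_c), sum(x$strategy == 1L), nrow(x$pos_t)))
  invisible(x)
}

#' Tabulate a world state
#'
#' @param x A `chase_world`.
#' @param ... Unused.
#' @return A tibble with one row per agent: `species`, `id`, `x`, `y`,
#'   `strategy`, `mode`, `t_hunt`, `t_rest`.
#' @export
tidy.chase_world <- function(x, ...) {
  w <- x
  ch <- tibble::tibble(
    species = "chaser",
    id = seq_len(nrow(w$pos_c)),
    x = w$pos_c[, 1], y = w$pos_c[, 2],
    strategy = ifelse(w$strategy == 1L, "GCS", "DCS"),
    mode = ifelse(w$mode == 1L, "HUNT", "REST"),
    t_hunt = w$t_hunt, t_rest = w$t_rest
  )
  tg <- tibble::tibble(
    species = "target",
    id = seq_len(nrow(w$pos_t)),
    x = w$pos_t[, 1], y = w$pos_t[, 2],
    strategy = NA_character_, mode = NA_character_,
    t_hunt = NA_real_, t_rest = NA_real_
  )
  dplyr::bind_rows(ch, tg)
}
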