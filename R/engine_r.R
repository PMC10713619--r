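#' @name reference_engine
#' @title Reference (pure R) step implementation
#' @description
#' A deliberately slow, loop-by-loop R implementation of the per-step update
#' used as an independent oracle for the compiled engine: both consume R's
#' global RNG stream in the identical order and must produce bitwise
#' identical world states. The step executes, in order: mode draws, set
#' decomposition, chaser move proposals, target move proposals, chaser
#' commits with same-species exclusion in random order, target commits with
#' capture detection and replacement in random order, imitation learning
#' (model C only), and the time increment.
NULL

# start-of-step set decomposition: nearest target per hunting chaser
# (post mode-draw modes, pre-movement positions) and per-target strategy
# composition counts
.decompose <- function(world) {
  n_c <- nrow(world$pos_c); n_t <- nrow(world$pos_t)
  in_sets <- isTRUE(world$cfg$resting_in_sets)
  nt <- rep(NA_integer_, n_c); d2 <- rep(NA_real_, n_c)
  n_g <- integer(n_t); n_d <- integer(n_t)
  for (i in seq_len(n_c)) {
    if (world$mode[i] != 1L && !in_sets) next
    r <- .nearest_target(world, i)
    nt[i] <- r$target_id; d2[i] <- r$d2
    if (world$strategy[i] == 1L) {
      n_g[r$target_id] <- n_g[r$target_id] + 1L
    } else {
      n_d[r$target_id] <- n_d[r$target_id] + 1L
    }
  }
  list(nt = nt, d2 = d2, n_g = n_g, n_d = n_d)
}

#' Propose one chaser's move
#'
#' Resting chasers step `v delta_t` in a random direction. Hunting chasers
#' whose nearest target is within `v delta_t` snap exactly onto the target's
#' position; otherwise they step along their strategy's direction rule. The
#' speed `v` is `v_D` for DCS and `v_G` for GCS, and the attempted position
#' is radially clamped into the disk.
#'
#' @param world A `chase_world` whose modes were already advanced this step.
#' @param chaser_id Chaser index.
#' @return A list with `attempted` (length-2) and `snap_target_id`
#'   (`NA` when the snap rule did not fire).
#' @export
propose_chaser_move <- function(world, chaser_id) {
  cfg <- world$cfg
  i <- chaser_id
  vdt <- (if (world$strategy[i] == 1L) cfg$v_G else cfg$v_D) * cfg$delta_t
  snap <- NA_integer_
  if (world$mode[i] != 1L) {
    dir <- .runit()
    att <- c(world$pos_c[i, 1] + vdt * dir[1],
             world$pos_c[i, 2] + vdt * dir[2])
  } else {
    ntg <- .nearest_target(world, i)
    d <- sqrt(ntg$d2)
    if (d <= vdt) {
      att <- c(world$pos_t[ntg$target_id, 1], world$pos_t[ntg$target_id, 2])
      snap <- ntg$target_id
    } else {
      dir <- if (world$strategy[i] == 1L) {
        gcs_direction(world, i)
      } else {
        dcs_direction(world, i)
      }
      att <- c(world$pos_c[i, 1] + vdt * dir[1],
               world$pos_c[i, 2] + vdt * dir[2])
    }
  }
  list(attempted = clamp_to_disk(att, cfg$R), snap_target_id = snap)
}

#' Propose one target's move
#'
#' A step of length `v_T delta_t` along the flight direction (random when no
#' hazard is within `r_haz`), clamped into the disk.
#'
#' @param world A `chase_world`.
#' @param target_id Target index.
#' @return A list with `attempted` (length-2).
#' @export
propose_target_move <- function(world, target_id) {
  cfg <- world$cfg
  dir <- target_direction(world, target_id)
  vdt <- cfg$v_T * cfg$delta_t
  att <- c(world$pos_t[target_id, 1] + vdt * dir[1],
           world$pos_t[target_id, 2] + vdt * dir[2])
  list(attempted = clamp_to_disk(att, cfg$R))
}

#' Commit chaser moves with same-species exclusion
#'
#' Processes chasers in a uniformly random order; each moves to its
#' attempted position unless any other chaser's position -- current at that
#' moment of the sweep, i.e. possibly already updated -- lies within `r_min`
#' of it, in which case the chaser stays put and a pending snap is voided.
#'
#' @param world A `chase_world`.
#' @param proposals List of proposals from [propose_chaser_move()], one per
#'   chaser in id order.
#' @return A list: the updated `world` and `snap` (integer vector of
#'   surviving snap target ids, `NA` elsewhere).
#' @export
commit_chaser_moves <- function(world, proposals) {
  cfg <- world$cfg
  n_c <- nrow(world$pos_c)
  rmin2 <- cfg$r_min * cfg$r_min
  snap <- vapply(proposals, function(p) p$snap_target_id, integer(1))
  perm <- .fy_perm(n_c)
  for (idx in seq_len(n_c)) {
    i <- perm[idx]
    ax <- proposals[[i]]$attempted[1]; ay <- proposals[[i]]$attempted[2]
    ok <- TRUE
    for (k in seq_len(n_c)) {
      if (k == i) next
      dx <- ax - world$pos_c[k, 1]; dy <- ay - world$pos_c[k, 2]
      if (dx * dx + dy * dy <= rmin2) { ok <- FALSE; break }
    }
    if (ok) {
      world$pos_c[i, 1] <- ax; world$pos_c[i, 2] <- ay
    } else {
      snap[i] <- NA_integer_
    }
  }
  list(world = world, snap = snap)
}

# replacement target: uniform in the disk, at least r_min from every other
# agent (both species); errors after max_placement_attempts rejections
.place_replacement <- function(world, skip_target) {
  cfg <- world$cfg
  rmin2 <- cfg$r_min * cfg$r_min
  for (attempt in seq_len(cfg$max_placement_attempts)) {
    p <- .disk_point(cfg$R)
    clear <- TRUE
    for (k in seq_len(nrow(world$pos_c))) {
      dx <- p[1] - world$pos_c[k, 1]; dy <- p[2] - world$pos_c[k, 2]
      if (dx * dx + dy * dy < rmin2) { clear <- FALSE; break }
    }
    if (clear) {
      for (k in seq_len(nrow(world$pos_t))) {
        if (k == skip_target) next
        dx <- p[1] - world$pos_t[k, 1]; dy <- p[2] - world$pos_t[k, 2]
        if (dx * dx + dy * dy < rmin2) { clear <- FALSE; break }
      }
    }
    if (clear) return(p)
  }
  rlang::abort("placement failure: max_placement_attempts exceeded",
               class = "chase_placement_error")
}

#' Commit target moves, detect captures, replace captured targets
#'
#' Processes targets in a uniformly random order. A target with any updated
#' chaser within `eps_capture` of its current (pre-move) position is
#' captured: the nearest such chaser (ties to the lowest id) is credited, a
#' capture event is recorded at the target's position, and a replacement
#' target appears uniformly at random at least `r_min` from every agent, so
#' the target count never changes. Uncaptured targets move to their
#' attempted positions under the same-species exclusion rule.
#'
#' @param world A `chase_world` whose chasers were already committed.
#' @param proposals List from [propose_target_move()], one per target in id
#'   order.
#' @param dec Start-of-step decomposition (internal; supplies the
#'   `(n_G, n_D)` class of each capture).
#' @return A list: updated `world` and `captures`, a tibble with columns
#'   `t`, `chaser_id`, `strategy`, `target_id`, `x`, `y`, `n_G`, `n_D`,
#'   `in_set`.
#' @export
commit_target_moves_and_captures <- function(world, proposals, dec = NULL) {
  cfg <- world$cfg
  if (is.null(dec)) dec <- .decompose(world)
  n_c <- nrow(world$pos_c); n_t <- nrow(world$pos_t)
  rmin2 <- cfg$r_min * cfg$r_min
  eps2 <- cfg$eps_capture * cfg$eps_capture
  ev <- list()
  perm <- .fy_perm(n_t)
  for (idx in seq_len(n_t)) {
    j <- perm[idx]
    tx <- world$pos_t[j, 1]; ty <- world$pos_t[j, 2]
    best <- -1L; bestd2 <- Inf
    for (k in seq_len(n_c)) {
      dx <- world$pos_c[k, 1] - tx; dy <- world$pos_c[k, 2] - ty
      d2 <- dx * dx + dy * dy
      if (d2 <= eps2 && d2 < bestd2) { bestd2 <- d2; best <- k }
    }
    if (best > 0L) {
      g <- dec$n_g[j]; d_ <- dec$n_d[j]
      in_set <- !is.na(dec$nt[best]) && dec$nt[best] == j
      if (!in_set) {
        if (world$strategy[best] == 1L) g <- g + 1L else d_ <- d_ + 1L
      }
      ev[[length(ev) + 1L]] <- list(
        t = world$t + cfg$delta_t, chaser_id = best,
        strategy = world$strategy[best], target_id = j,
        x = tx, y = ty, n_G = g, n_D = d_, in_set = in_set)
      world$pos_t[j, ] <- .place_replacement(world, j)
    } else {
      ax <- proposals[[j]]$attempted[1]; ay <- proposals[[j]]$attempted[2]
      ok <- TRUE
      for (k in seq_len(n_t)) {
        if (k == j) next
        dx <- ax - world$pos_t[k, 1]; dy <- ay - world$pos_t[k, 2]
        if (dx * dx + dy * dy <= rmin2) { ok <- FALSE; break }
      }
      if (ok) { world$pos_t[j, 1] <- ax; world$pos_t[j, 2] <- ay }
    }
  }
  captures <- if (length(ev)) {
    tibble::tibble(
      t = vapply(ev, `[[`, numeric(1), "t"),
      chaser_id = vapply(ev, `[[`, integer(1), "chaser_id"),
      strategy = ifelse(vapply(ev, `[[`, integer(1), "strategy") == 1L,
                        "GCS", "DCS"),
      target_id = vapply(ev, `[[`, integer(1), "target_id"),
      x = vapply(ev, `[[`, numeric(1), "x"),
      y = vapply(ev, `[[`, numeric(1), "y"),
      n_G = vapply(ev, function(e) as.integer(e$n_G), integer(1)),
      n_D = vapply(ev, function(e) as.integer(e$n_D), integer(1)),
      in_set = vapply(ev, `[[`, logical(1), "in_set")
    )
  } else {
    tibble::tibble(t = numeric(0), chaser_id = integer(0),
                   strategy = character(0), target_id = integer(0),
                   x = numeric(0), y = numeric(0), n_G = integer(0),
                   n_D = integer(0), in_set = logical(0))
  }
  list(world = world, captures = captures)
}

#' Apply the imitation-learning rule (model C)
#'
#' Processes capture events in the order they occurred: for each, every
#' chaser within `r_learn` of the capture location adopts the capturer's
#' strategy as it stands at the moment of processing (a capturer converted
#' by an earlier event this step propagates its new strategy). A no-op for
#' models other than C.
#'
#' @param world A `chase_world`.
#' @param captures Capture tibble as produced by
#'   [commit_target_moves_and_captures()].
#' @return A list: updated `world` and `updates`, a tibble of
#'   `(chaser_id, old_strategy, new_strategy)` rows.
#' @export
apply_learning <- function(world, captures) {
  cfg <- world$cfg
  upd <- list()
  if (cfg$model == "C" && nrow(captures) > 0L) {
    rl2 <- cfg$r_learn * cfg$r_learn
    for (e in seq_len(nrow(captures))) {
      ex <- captures$x[e]; ey <- captures$y[e]
      s_new <- world$strategy[captures$chaser_id[e]]
      for (k in seq_len(nrow(world$pos_c))) {
        dx <- world$pos_c[k, 1] - ex; dy <- world$pos_c[k, 2] - ey
        if (dx * dx + dy * dy <= rl2 && world$strategy[k] != s_new) {
          upd[[length(upd) + 1L]] <- c(k, world$strategy[k], s_new)
          world$strategy[k] <- s_new
        }
      }
    }
  }
  updates <- if (length(upd)) {
    m <- do.call(rbind, upd)
    tibble::tibble(chaser_id = as.integer(m[, 1]),
                   old_strategy = ifelse(m[, 2] == 1L, "GCS", "DCS"),
                   new_strategy = ifelse(m[, 3] == 1L, "GCS", "DCS"))
  } else {
    tibble::tibble(chaser_id = integer(0), old_strategy = character(0),
                   new_strategy = character(0))
  }
  list(world = world, updates = updates)
}

#' One full reference step
#'
#' Chains the per-phase operations in procedure order and advances time by
#' `delta_t`. Slow (pure R) but exact: used as the bitwise oracle for
#' [sim_step()].
#'
#' @param world A `chase_world`.
#' @return A list: the new `world`, the `captures` tibble, and the learning
#'   `updates` tibble.
#' @export
reference_step <- function(world) {
  cfg <- world$cfg
  world <- advance_modes(world)
  dec <- .decompose(world)
  prop_c <- lapply(seq_len(nrow(world$pos_c)),
                   function(i) propose_chaser_move(world, i))
  prop_t <- lapply(seq_len(nrow(world$pos_t)),
                   function(j) propose_target_move(world, j))
  cm <- commit_chaser_moves(world, prop_c)
  tm <- commit_target_moves_and_captures(cm$world, prop_t, dec)
  lr <- apply_learning(tm$world, tm$captures)
  world <- lr$world
  world$t <- world$t + cfg$delta_t
  list(world = world, captures = tm$captures, updates = lr$updates)
}
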