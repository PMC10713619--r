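#' Mode-switch probabilities
#'
#' A chaser alternates between a hunting mode and a rest mode. The switch
#' probability ramps linearly with the time already spent in the current
#' mode: after hunting for `t_hunt` the probability of switching to rest is
#' `min(t_hunt / T_hunt, 1)`, and symmetrically for waking up from rest.
#' A spell therefore never exceeds its cap by more than one step.
#'
#' @param t_hunt,t_rest Time accumulated in the current spell (>= 0).
#' @param T_hunt,T_rest Maximal spell durations (> 0).
#' @return A probability in `[0, 1]`.
#' @examples
#' rest_probability(500, 1000)
#' hunt_probability(2000, 1000)
#' @export
rest_probability <- function(t_hunt, T_hunt) {
  stopifnot(all(t_hunt >= 0), all(T_hunt > 0))
  pmin(t_hunt / T_hunt, 1)
}

#' @rdname rest_probability
#' @export
hunt_probability <- function(t_rest, T_rest) {
  stopifnot(all(t_rest >= 0), all(T_rest > 0))
  pmin(t_rest / T_rest, 1)
}

#' Advance every chaser's mode by one step
#'
#' Performs the per-step mode draw for each chaser in id order, before any
#' movement: a hunting chaser switches to rest with probability
#' `rest_probability(t_hunt, T_hunt)`, a resting chaser wakes with
#' probability `hunt_probability(t_rest, T_rest)`. On a switch the timer of
#' the destination mode is reset to zero; after the draw the timer of the
#' (possibly new) current mode grows by `delta_t`, so the first draw of a
#' fresh spell always sees probability zero. One uniform is consumed per
#' chaser regardless of the outcome, which keeps the RNG stream aligned with
#' the compiled engine.
#'
#' @param world A `chase_world`.
#' @return The world with updated `mode`, `t_hunt`, `t_rest`.
#' @export
advance_modes <- function(world) {
  cfg <- world$cfg
  for (i in seq_len(nrow(world$pos_c))) {
    u <- stats::runif(1)
    if (world$mode[i] == 1L) {
      p <- min(world$t_hunt[i] / cfg$T_hunt, 1)
      if (u < p) { world$mode[i] <- 0L; world$t_rest[i] <- 0 }
    } else {
      p <- min(world$t_rest[i] / cfg$T_rest, 1)
      if (u < p) { world$mode[i] <- 1L; world$t_hunt[i] <- 0 }
    }
    if (world$mode[i] == 1L) {
      world$t_hunt[i] <- world$t_hunt[i] + cfg$delta_t
    } else {
      world$t_rest[i] <- world$t_rest[i] + cfg$delta_t
    }
  }
  world
}
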