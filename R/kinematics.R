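#' @name kinematics
#' @title Pure direction rules
#' @description
#' The per-agent direction computations used by the engine, exposed as pure
#' functions for inspection and testing. All of them operate on a
#' [chase_world] and an agent index, use the configuration stored in the
#' world, and return unit vectors (except [nearest_hazard()] and
#' [pursuit_context()], which return the underlying geometric quantities).
#'
#' * A target flees the nearest hazard -- a chaser or the boundary -- within
#'   `r_haz`, along `(r_T - r_H)/|r_T - r_H|`; with no hazard it walks in a
#'   random direction.
#' * A DCS chaser heads straight at its nearest target.
#' * A GCS chaser aims at the point `X = (n+1) r_T - sum(r_Cj)` over its
#'   reference group Gamma (all other chasers at least as close to the
#'   target), i.e. it steers the group centroid onto the target, possibly
#'   moving away from the target itself.
NULL

# index (and squared distance) of the nearest target to chaser i;
# first minimum wins, so ties break to the lowest target id
.nearest_target <- function(world, i) {
  cx <- world$pos_c[i, 1]; cy <- world$pos_c[i, 2]
  best <- -1L; bestd2 <- Inf
  for (j in seq_len(nrow(world$pos_t))) {
    dx <- world$pos_t[j, 1] - cx; dy <- world$pos_t[j, 2] - cy
    d2 <- dx * dx + dy * dy
    if (d2 < bestd2) { bestd2 <- d2; best <- j }
  }
  list(target_id = best, d2 = bestd2)
}

#' Locate a target's nearest hazard
#'
#' Scans every chaser (optionally excluding resting ones via the
#' `resting_are_hazards` switch) and the habitat boundary; the nearest
#' entity within `r_haz` wins, a chaser beating the boundary on an exact
#' tie. The boundary hazard point is the radial projection of the target
#' onto the circle of radius `R`; a target exactly at the centre has no
#' defined projection, but there the boundary distance `R` exceeds `r_haz`
#' for any valid configuration, so the boundary is simply excluded.
#'
#' @param world A `chase_world`.
#' @param target_id Target index.
#' @return A list with `kind` (`"NONE"`, `"CHASER"`, or `"BOUNDARY"`),
#'   `pos` (hazard position, `NULL` when `kind == "NONE"`), and `distance`.
#' @export
nearest_hazard <- function(world, target_id) {
  cfg <- world$cfg
  tx <- world$pos_t[target_id, 1]; ty <- world$pos_t[target_id, 2]
  best <- -1L; bestd2 <- Inf
  for (k in seq_len(nrow(world$pos_c))) {
    if (!cfg$resting_are_hazards && world$mode[k] != 1L) next
    dx <- world$pos_c[k, 1] - tx; dy <- world$pos_c[k, 2] - ty
    d2 <- dx * dx + dy * dy
    if (d2 < bestd2) { bestd2 <- d2; best <- k }
  }
  d_ch <- if (best > 0L) sqrt(bestd2) else Inf
  r_t <- sqrt(tx * tx + ty * ty)
  d_b <- cfg$R - r_t
  if (best > 0L && d_ch <= cfg$r_haz && d_ch <= d_b) {
    list(kind = "CHASER", pos = c(world$pos_c[best, 1], world$pos_c[best, 2]),
         distance = d_ch, chaser_id = best)
  } else if (d_b <= cfg$r_haz && r_t > 0) {
    s <- cfg$R / r_t
    list(kind = "BOUNDARY", pos = c(s * tx, s * ty), distance = d_b)
  } else {
    list(kind = "NONE", pos = NULL, distance = Inf)
  }
}

#' Flight direction of a target
#'
#' Directly away from the nearest hazard; a uniformly random unit vector
#' when no hazard lies within `r_haz`, or (degenerately) when the target
#' sits exactly on the hazard position.
#'
#' @inheritParams nearest_hazard
#' @return A unit-length numeric vector of length 2.
#' @export
target_direction <- function(world, target_id) {
  hz <- nearest_hazard(world, target_id)
  if (hz$kind == "NONE") return(.runit())
  vx <- world$pos_t[target_id, 1] - hz$pos[1]
  vy <- world$pos_t[target_id, 2] - hz$pos[2]
  nv <- sqrt(vx * vx + vy * vy)
  if (nv == 0) return(.runit())
  c(vx / nv, vy / nv)
}

#' Direct chasing direction
#'
#' Unit vector from a DCS chaser straight to its nearest target (ties broken
#' by lowest target id). The engine's snap rule fires before this is needed
#' at zero distance; as a defensive fallback a coincident chaser gets a
#' random direction.
#'
#' @param world A `chase_world`.
#' @param chaser_id Chaser index.
#' @return A unit-length numeric vector of length 2.
#' @export
dcs_direction <- function(world, chaser_id) {
  nt <- .nearest_target(world, chaser_id)
  d <- sqrt(nt$d2)
  if (d == 0) return(.runit())
  c((world$pos_t[nt$target_id, 1] - world$pos_c[chaser_id, 1]) / d,
    (world$pos_t[nt$target_id, 2] - world$pos_c[chaser_id, 2]) / d)
}

#' Group-pursuit context of a chaser
#'
#' For chaser `i` with nearest target `T_k` at distance `d`: the reference
#' group Gamma holds every other chaser (both strategies; resting chasers
#' included unless `resting_in_gamma` is off) whose distance to `T_k` is at
#' most `d` (closed comparison: "not farther"). The aim point is
#' `X = (n+1) r_Tk - sum_{j in Gamma} r_Cj`, the point that would put `T_k`
#' at the centroid of the group plus the focal chaser. With an empty group
#' `X` reduces to the target position itself.
#'
#' @inheritParams dcs_direction
#' @return A list: `chaser_id`, `target_id`, `d` (distance to the target),
#'   `gamma` (integer ids), `n` (its size), and `aim` (`X`, length-2).
#' @export
pursuit_context <- function(world, chaser_id) {
  cfg <- world$cfg
  nt <- .nearest_target(world, chaser_id)
  j <- nt$target_id
  tx <- world$pos_t[j, 1]; ty <- world$pos_t[j, 2]
  gamma <- integer(0)
  sx <- 0; sy <- 0
  for (k in seq_len(nrow(world$pos_c))) {
    if (k == chaser_id) next
    if (!cfg$resting_in_gamma && world$mode[k] != 1L) next
    dx <- tx - world$pos_c[k, 1]; dy <- ty - world$pos_c[k, 2]
    if (dx * dx + dy * dy <= nt$d2) {
      gamma <- c(gamma, k)
      sx <- sx + world$pos_c[k, 1]
      sy <- sy + world$pos_c[k, 2]
    }
  }
  n <- length(gamma)
  list(chaser_id = chaser_id, target_id = j, d = sqrt(nt$d2),
       gamma = gamma, n = n,
       aim = c((n + 1) * tx - sx, (n + 1) * ty - sy))
}

#' Group chasing direction
#'
#' Unit vector from a GCS chaser toward its aim point (see
#' [pursuit_context()]); this can point away from the target when the rest
#' of the group is already closer. With an empty reference group it equals
#' [dcs_direction()] exactly. A degenerate aim point coinciding with the
#' chaser (symmetric cancellation) falls back to a random unit direction.
#'
#' @inheritParams dcs_direction
#' @return A unit-length numeric vector of length 2.
#' @export
gcs_direction <- function(world, chaser_id) {
  ctx <- pursuit_context(world, chaser_id)
  vx <- ctx$aim[1] - world$pos_c[chaser_id, 1]
  vy <- ctx$aim[2] - world$pos_c[chaser_id, 2]
  nv <- sqrt(vx * vx + vy * vy)
  if (nv == 0) return(.runit())
  c(vx / nv, vy / nv)
}
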