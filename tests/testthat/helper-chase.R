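# Shared fixtures: all worlds are built in code, no stored data.

# small, fast configuration for structural tests
tiny_cfg <- function(...) {
  defaults <- list(N_C = 20L, N_T = 10L, T_max = 100, model = "B",
                   ss_window = c(0, 100), sample_every = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(chase_config, args)
}

# dense arena where chasers are much faster than targets, so captures,
# replacements, and learning fire within a few hundred steps
crowded_cfg <- function(...) {
  defaults <- list(N_C = 25L, N_T = 8L, R = 20, r_haz = 10, r_learn = 15,
                   v_T = 0.02, v_D = 0.3, v_G = 0.25, T_hunt = 50,
                   T_rest = 50, T_max = 200, model = "C",
                   ss_window = c(0, 200), sample_every = 10L,
                   enforce_speed_order = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(chase_config, args)
}

# hand-built world with explicit positions (bypasses random placement)
make_world <- function(cfg, chaser_pos, target_pos,
                       strategy = NULL, mode = NULL) {
  as_pos <- function(p) {
    if (is.matrix(p)) {
      matrix(as.numeric(p), ncol = 2)
    } else {
      matrix(as.numeric(p), ncol = 2, byrow = TRUE)
    }
  }
  chaser_pos <- as_pos(chaser_pos)
  target_pos <- as_pos(target_pos)
  n_c <- nrow(chaser_pos)
  if (is.null(strategy)) strategy <- rep(0L, n_c)
  if (is.null(mode)) mode <- rep(1L, n_c)
  structure(list(
    t = 0, pos_c = chaser_pos, strategy = as.integer(strategy),
    mode = as.integer(mode), t_hunt = rep(0, n_c), t_rest = rep(0, n_c),
    pos_t = target_pos, cfg = cfg
  ), class = "chase_world")
}
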