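test_that("initialization respects composition and spacing", {
  set.seed(3)
  w <- initialize_world(chase_config(model = "B", T_max = 100))
  expect_equal(sum(w$strategy == 1L), 50)
  expect_equal(sum(w$strategy == 0L), 50)
  set.seed(3)
  wg <- initialize_world(chase_config(model = "A_GCS", T_max = 100))
  expect_true(all(wg$strategy == 1L))
  expect_true(all(wg$mode == 1L))
  # same-species pairs at least r_min apart, everyone inside the disk
  dc <- stats::dist(w$pos_c)
  dt_ <- stats::dist(w$pos_t)
  expect_gte(min(dc), 0.15)
  expect_gte(min(dt_), 0.15)
  expect_true(all(rowSums(w$pos_c^2) <= 500^2))
  expect_true(all(rowSums(w$pos_t^2) <= 500^2))
})

test_that("chaser proposals snap, pursue, or wander by mode", {
  cfg <- tiny_cfg(N_C = 1L, N_T = 1L, v_D = 0.082)
  # nearest target within v_D*dt: snap onto it
  w <- make_world(cfg, c(0, 0), c(0.05, 0))
  pr <- propose_chaser_move(w, 1)
  expect_equal(pr$attempted, c(0.05, 0))
  expect_equal(pr$snap_target_id, 1L)
  # GCS with empty reference group: one v_G*dt step along the direct rule
  w <- make_world(cfg, c(0, 0), c(10, 0), strategy = 1L)
  pr <- propose_chaser_move(w, 1)
  expect_equal(pr$attempted, c(0.07, 0))
  expect_true(is.na(pr$snap_target_id))
  # resting chasers random-walk with the strategy's step length
  w <- make_world(cfg, c(0, 0), c(10, 0), mode = 0L)
  set.seed(8)
  pr <- propose_chaser_move(w, 1)
  expect_equal(sqrt(sum(pr$attempted^2)), 0.082, tolerance = 1e-12)
})

test_that("target proposals flee hazards and clamp to the disk", {
  cfg <- tiny_cfg(N_C = 1L, N_T = 1L)
  w <- make_world(cfg, c(90, 0), c(100, 0))
  expect_equal(propose_target_move(w, 1)$attempted, c(100.1, 0))
  # boundary hazard: one step back toward the centre
  w <- make_world(cfg, c(0, 0), c(499.95, 0))
  expect_equal(propose_target_move(w, 1)$attempted, c(499.85, 0))
  # no hazard: unit-speed random step
  w <- make_world(cfg, c(400, 400), c(0, 0))
  set.seed(8)
  pr <- propose_target_move(w, 1)
  expect_equal(sqrt(sum(pr$attempted^2)), 0.1, tolerance = 1e-12)
})

test_that("same-species exclusion lets exactly one of two colliders move", {
  cfg <- tiny_cfg(N_C = 2L, N_T = 1L)
  # both propose positions 0.1 apart (< r_min = 0.15)
  w <- make_world(cfg, c(-1, 0, 1, 0), c(0, 50))
  props <- list(list(attempted = c(-0.05, 0), snap_target_id = NA_integer_),
                list(attempted = c(0.05, 0), snap_target_id = NA_integer_))
  moved <- replicate(40, {
    set.seed(sample.int(1e6, 1))
    cm <- commit_chaser_moves(w, props)
    sum(cm$world$pos_c[, 1] != w$pos_c[, 1])
  })
  expect_true(all(moved == 1))
  # an isolated chaser always moves
  cfg1 <- tiny_cfg(N_C = 1L, N_T = 1L)
  w1 <- make_world(cfg1, c(0, 0), c(0, 50))
  cm <- commit_chaser_moves(w1, props[1])
  expect_equal(cm$world$pos_c[1, ], c(-0.05, 0))
})

test_that("captures remove, credit, and replace the target", {
  cfg <- tiny_cfg(N_C = 2L, N_T = 2L)
  # chaser 1 sits exactly on target 1 (as after a snap commit)
  w <- make_world(cfg, c(5, 5, 30, 30), c(5, 5, -40, 10))
  props <- list(list(attempted = c(5.1, 5)), list(attempted = c(-40, 10.1)))
  set.seed(21)
  out <- commit_target_moves_and_captures(w, props)
  expect_equal(nrow(out$captures), 1L)
  expect_equal(out$captures$chaser_id, 1L)
  expect_equal(out$captures$target_id, 1L)
  expect_equal(out$captures$x, 5)
  expect_equal(nrow(out$world$pos_t), 2L)  # replacement keeps the count
  # the replacement is elsewhere, min r_min from every agent
  new_pos <- out$world$pos_t[1, ]
  expect_false(isTRUE(all.equal(new_pos, c(5, 5))))
  d_all <- sqrt(c((new_pos[1] - out$world$pos_c[, 1])^2 +
                    (new_pos[2] - out$world$pos_c[, 2])^2,
                  (new_pos[1] - out$world$pos_t[2, 1])^2 +
                    (new_pos[2] - out$world$pos_t[2, 2])^2))
  expect_gte(min(d_all), cfg$r_min)
})

test_that("learning converts chasers within the learning radius only", {
  cfg <- crowded_cfg(N_C = 3L, N_T = 1L, r_learn = 200, R = 400,
                     r_haz = 50, model = "C")
  w <- make_world(cfg, c(0, 0, 100, 0, 250, 0), c(0, 0),
                  strategy = c(1L, 0L, 0L))
  captures <- tibble::tibble(t = 1, chaser_id = 1L, strategy = "GCS",
                             target_id = 1L, x = 0, y = 0, n_G = 1L,
                             n_D = 0L, in_set = TRUE)
  out <- apply_learning(w, captures)
  expect_equal(out$world$strategy, c(1L, 1L, 0L))  # 100 <= 200 < 250
  expect_equal(out$updates$chaser_id, 2L)
  # model B: learning disabled, identical strategies
  cfgB <- crowded_cfg(N_C = 3L, N_T = 1L, r_learn = 200, R = 400,
                      r_haz = 50, model = "B")
  wB <- w
  wB$cfg <- cfgB
  outB <- apply_learning(wB, captures)
  expect_identical(outB$world$strategy, wB$strategy)
})

test_that("chasers converge on one target, then all pursue the survivor", {
  # two near-stationary targets, four direct chasers; huge T_hunt keeps
  # everyone hunting
  cfg <- chase_config(N_C = 4L, N_T = 2L, v_T = 1e-9, v_D = 0.3, v_G = 0.25,
                      T_hunt = 1e8, T_rest = 1e3, T_max = 1e3, R = 400,
                      r_haz = 5, r_min = 0.15, model = "A_DCS",
                      ss_window = c(0, 1e3), enforce_speed_order = FALSE)
  w <- make_world(cfg, c(-10, 6, -10, -6, 10, 5, 12, -4), c(-14, 0, 16, 0))
  # chasers 1,2 are nearest to target 1; chasers 3,4 to target 2
  expect_equal(vapply(1:4, function(i) {
    groupchase:::.nearest_target(w, i)$target_id
  }, integer(1)), c(1L, 1L, 2L, 2L))
  set.seed(17)
  # every pre-capture step moves each chaser straight toward its own target
  caught <- integer(0)
  for (s in 1:300) {
    before <- w$pos_c
    nearest <- vapply(1:4, function(i) {
      groupchase:::.nearest_target(w, i)$target_id
    }, integer(1))
    res <- sim_step(w, 1)
    w <- res$world
    if (nrow(res$captures) > 0) {
      caught <- res$captures$target_id
      break
    }
    for (i in 1:4) {
      step_vec <- w$pos_c[i, ] - before[i, ]
      to_target <- w$pos_t[nearest[i], ] - before[i, ]
      if (sqrt(sum(step_vec^2)) > 0) {
        cosang <- sum(step_vec * to_target) /
          sqrt(sum(step_vec^2) * sum(to_target^2))
        expect_gt(cosang, 0.999)
      }
    }
  }
  expect_length(caught, 1L)
  survivor <- setdiff(1:2, caught)[1]
  # after the capture every chaser homes in on the surviving target
  # (the replacement spawned far away in the big disk under this seed)
  nearest_now <- vapply(1:4, function(i) {
    groupchase:::.nearest_target(w, i)$target_id
  }, integer(1))
  expect_true(all(nearest_now == survivor))
})

test_that("step preserves counts, containment, and the speed contract", {
  cfg <- crowded_cfg()
  set.seed(12)
  w <- initialize_world(cfg)
  vmax <- max(cfg$v_D, cfg$v_G, cfg$v_T) * cfg$delta_t
  for (k in 1:10) {
    before_c <- w$pos_c
    before_t <- w$pos_t
    res <- sim_step(w, 1)
    w <- res$world
    expect_equal(nrow(w$pos_c), cfg$N_C)
    expect_equal(nrow(w$pos_t), cfg$N_T)
    expect_true(all(rowSums(w$pos_c^2) <= cfg$R^2 + 1e-9))
    expect_true(all(rowSums(w$pos_t^2) <= cfg$R^2 + 1e-9))
    disp_c <- sqrt(rowSums((w$pos_c - before_c)^2))
    expect_true(all(disp_c <= vmax + 1e-12))
    # targets move at most v_T*dt unless teleported by replacement
    disp_t <- sqrt(rowSums((w$pos_t - before_t)^2))
    moved_normally <- setdiff(seq_len(cfg$N_T), res$captures$target_id)
    expect_true(all(disp_t[moved_normally] <= cfg$v_T * cfg$delta_t + 1e-12))
  }
})

test_that("learning dynamics absorb at homogeneous populations", {
  # a run that fixates keeps its strategy vector frozen afterwards
  cfg <- crowded_cfg(T_max = 400, sample_every = 1L)
  run <- NULL
  for (s in 1:10) {
    cand <- run_simulation(cfg, seed = s)
    if (cand$fixation$outcome != "none" && cand$fixation$time < 300) {
      run <- cand
      break
    }
  }
  expect_false(is.null(run))
  after <- run$series[run$series$t >= run$fixation$time, ]
  if (run$fixation$outcome == "GCS") {
    expect_true(all(after$n_gcs == cfg$N_C))
  } else {
    expect_true(all(after$n_gcs == 0L))
  }
  # starting homogeneous is an absorbing start, recorded at t = 0
  cfg1 <- crowded_cfg(gcs_fraction = 1, T_max = 50)
  r1 <- run_simulation(cfg1, seed = 1)
  expect_equal(r1$fixation$outcome, "GCS")
  expect_equal(r1$fixation$time, 0)
})

test_that("runs are deterministic in the seed and ensembles aggregate", {
  cfg <- crowded_cfg(T_max = 150)
  r1 <- run_simulation(cfg, seed = 5)
  r2 <- run_simulation(cfg, seed = 5)
  expect_identical(r1$captures, r2$captures)
  expect_identical(r1$world$pos_c, r2$world$pos_c)
  r3 <- run_simulation(cfg, seed = 6)
  expect_false(identical(r1$captures, r3$captures))
  # horizon T_max = 10 * delta_t executes exactly ten steps
  r10 <- run_simulation(crowded_cfg(T_max = 10), seed = 1)
  expect_equal(r10$world$t, 10)
  ens <- run_ensemble(cfg, 2, base_seed = 5)
  expect_identical(ens$runs[[1]]$captures, r1$captures)
  expect_equal(sum(ens$class_counts$H_G + ens$class_counts$H_D),
               sum(ens$runs[[1]]$captures$in_set) +
                 sum(ens$runs[[2]]$captures$in_set))
})
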