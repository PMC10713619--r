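test_that("set identification groups hunting chasers by nearest target", {
  cfg <- tiny_cfg(N_C = 3L, N_T = 8L)
  w <- make_world(cfg, c(10, 0, 10, 1, 11, 0),
                  rbind(matrix(200, 6, 2), c(10.5, 0.5), c(-200, -200)))
  s <- identify_sets(w)
  expect_equal(unique(s$target_id), 7L)
  expect_equal(sort(s$chaser_id), 1:3)
  # two sets: one lone direct chaser, one trio around the second target
  cfg2 <- tiny_cfg(N_C = 4L, N_T = 2L)
  w2 <- make_world(cfg2, c(-50, 0, 48, 2, 52, 2, 50, -3), c(-55, 0, 50, 0),
                   strategy = c(0L, 1L, 1L, 1L))
  s2 <- identify_sets(w2)
  expect_equal(s2$target_id[s2$chaser_id == 1], 1L)
  expect_equal(sort(s2$chaser_id[s2$target_id == 2]), 2:4)
  expect_equal(unique(s2$n_G[s2$target_id == 2]), 3L)
  # resting chasers pursue nothing
  w3 <- make_world(cfg2, c(-50, 0, 48, 2, 52, 2, 50, -3), c(-55, 0, 50, 0),
                   mode = rep(0L, 4))
  expect_equal(nrow(identify_sets(w3)), 0L)
})

test_that("hunting performance is captures per chaser per window", {
  events <- tibble::tibble(t = c(runif(200, 0, 2e4), runif(50, 2e4, 4e4)))
  h <- hunting_performance(events, n_chasers = 100, h_window = 2e4,
                           t_max = 4e4)
  expect_equal(h$h, c(2.0, 0.5))
  expect_equal(h$t, c(1e4, 3e4))
  # no captures at all
  h0 <- hunting_performance(tibble::tibble(t = numeric(0)), n_chasers = 100,
                            h_window = 2e4, t_max = 2e4)
  expect_equal(h0$h, 0)
})

test_that("stratified performance divides by time-averaged membership", {
  # 50 heterogeneous GCS captures against a time-average of 25 GCS chasers
  # in heterogeneous sets -> h = 2
  hb <- tibble::tibble(
    t = 1e4, steps = 2e4, capt_total = 60,
    capt_G_hom = 0, capt_G_het = 50, capt_D_hom = 10, capt_D_het = 0,
    occ_G_hom = 0, occ_G_het = 25 * 2e4, occ_D_hom = 4 * 2e4, occ_D_het = 0)
  run <- structure(list(cfg = tiny_cfg(), h_bins = hb), class = "chase_run")
  hs <- hunting_performance(run, stratified = TRUE)
  expect_equal(hs$h[hs$strategy == "GCS" & hs$category == "heterogeneous"], 2)
  expect_equal(hs$h[hs$strategy == "DCS" & hs$category == "homogeneous"], 2.5)
  # empty denominators are undefined, not zero
  expect_true(is.na(hs$h[hs$strategy == "GCS" & hs$category == "homogeneous"]))
})

test_that("fitness follows the relative-performance definition", {
  counts <- tibble::tibble(n_G = 1L, n_D = 1L, N = 100, H_G = 30, H_D = 10)
  ft <- compute_fitness_table(counts)
  expect_equal(ft$f_G, 1.5)
  expect_equal(ft$f_D, 0.5)
  expect_equal(attr(ft, "H_total"), 40)
  expect_equal(attr(ft, "NC_total"), 200)
  # equal ability in every class gives fitness one everywhere
  eq <- tibble::tibble(n_G = c(1L, 2L, 0L), n_D = c(1L, 1L, 2L),
                       N = c(100, 50, 80),
                       H_G = c(10, 10, 0), H_D = c(10, 5, 16))
  fte <- compute_fitness_table(eq)
  expect_equal(fte$f_G[1:2], c(1, 1))
  expect_equal(fte$f_D, c(1, 1, 1))
  expect_true(is.na(fte$f_G[3]))  # no GCS members in a (0,2) class
  expect_error(compute_fitness_table(
    tibble::tibble(n_G = 1L, n_D = 0L, N = 10, H_G = 0, H_D = 0)),
    class = "chase_no_captures")
})

test_that("accumulated class counts satisfy the exact fitness identity", {
  # independent accumulation in R from the per-phase operations, then the
  # algebraic identity sum(N_G f_G + N_D f_D) = NC_total on both tables
  cfg <- crowded_cfg(T_max = 300, ss_window = c(0, 300))
  set.seed(31)
  w <- initialize_world(cfg)
  acc <- list()
  for (s in 1:300) {
    w <- advance_modes(w)
    sets <- identify_sets(w)
    if (nrow(sets) > 0) {
      acc[[length(acc) + 1L]] <- dplyr::distinct(
        sets[, c("target_id", "n_G", "n_D")])
    }
    props_c <- lapply(seq_len(cfg$N_C), function(i) propose_chaser_move(w, i))
    props_t <- lapply(seq_len(cfg$N_T), function(j) propose_target_move(w, j))
    cm <- commit_chaser_moves(w, props_c)
    tm <- commit_target_moves_and_captures(cm$world, props_t)
    w <- apply_learning(tm$world, tm$captures)$world
    w$t <- w$t + cfg$delta_t
  }
  n_ref <- dplyr::count(dplyr::bind_rows(acc), n_G, n_D, name = "N")
  n_ref$N <- as.numeric(n_ref$N)
  n_ref$n_G <- as.integer(n_ref$n_G)
  n_ref$n_D <- as.integer(n_ref$n_D)
  set.seed(31)
  run <- run_simulation(cfg, seed = 31)
  n_opt <- run$class_counts[run$class_counts$N > 0, c("n_G", "n_D", "N")]
  expect_equal(as.data.frame(dplyr::arrange(n_ref, n_G, n_D)),
               as.data.frame(dplyr::arrange(n_opt, n_G, n_D)),
               ignore_attr = TRUE)
  ft <- fitness_table(run)
  lhs <- sum(ifelse(ft$n_G > 0, ft$n_G * ft$N * ft$f_G, 0) +
               ifelse(ft$n_D > 0, ft$n_D * ft$N * ft$f_D, 0))
  expect_equal(lhs / attr(ft, "NC_total"), 1, tolerance = 1e-12)
})

test_that("nash arrows mark profitable unilateral switches", {
  grid <- expand.grid(n_G = 0:3, n_D = 0:3)
  grid <- grid[grid$n_G + grid$n_D > 0, ]
  # a strictly DCS-favouring landscape: defection always pays
  tb <- tibble::tibble(n_G = grid$n_G, n_D = grid$n_D, N = 100,
                       H_G = NA, H_D = NA,
                       f_G = ifelse(grid$n_G > 0, 1, NA),
                       f_D = ifelse(grid$n_D > 0, 2, NA))
  na <- nash_arrows(tb, max_n = 2L)
  g2d <- na$arrows[na$arrows$arrow == "G2D", ]
  expect_setequal(paste(g2d$n_G, g2d$n_D),
                  paste(c(1, 1, 1, 2, 2, 2), c(0, 1, 2, 0, 1, 2)))
  expect_equal(nrow(na$arrows[na$arrows$arrow == "D2G", ]), 0L)
  # pure-DCS cells are the equilibria of this landscape
  expect_true(all(na$equilibria$n_G == 0))
  # flat landscape: strict inequalities never fire
  tb$f_G <- ifelse(grid$n_G > 0, 1, NA)
  tb$f_D <- ifelse(grid$n_D > 0, 1, NA)
  na_flat <- nash_arrows(tb, max_n = 2L)
  expect_equal(nrow(na_flat$arrows), 0L)
  # the published example: (1,2) is an equilibrium cell because both
  # switches lower fitness (1.4 -> 1.2 and 2.0 -> 1.2)
  cells <- tibble::tibble(
    n_G = c(1L, 0L, 2L), n_D = c(2L, 3L, 1L), N = 1,
    H_G = NA, H_D = NA,
    f_G = c(1.4, NA, 1.2), f_D = c(2.0, 1.2, NA))
  na2 <- nash_arrows(cells, max_n = 3L)
  expect_false(any(na2$arrows$n_G == 1 & na2$arrows$n_D == 2))
  expect_true(any(na2$equilibria$n_G == 1 & na2$equilibria$n_D == 2))
})

test_that("fixation detection and probabilities follow their definitions", {
  ser <- tibble::tibble(t = c(0, 1e5, 3e5), n_gcs = c(50L, 80L, 100L))
  fx <- detect_fixation(ser, 100L)
  expect_equal(fx$outcome, "GCS")
  expect_equal(fx$time, 3e5)
  expect_equal(detect_fixation(tibble::tibble(t = 0:2, n_gcs = c(30L, 40L,
                                                                 50L)),
                               100L)$outcome, "none")
  expect_equal(detect_fixation(tibble::tibble(t = 0, n_gcs = 0L),
                               100L)$time, 0)
  outcomes <- c(rep("GCS", 70), rep("DCS", 25), rep("none", 5))
  fp <- fixation_probability(outcomes)
  expect_equal(fp$p_fix[fp$outcome == "GCS"], 0.70)
  expect_equal(fp$p_fix[fp$outcome == "DCS"], 0.25)
  expect_lte(sum(fp$p_fix[fp$outcome != "none"]), 1)
  expect_equal(fp$se[fp$outcome == "GCS"], sqrt(0.7 * 0.3 / 100))
})

test_that("steady-state means average the window and propagate run spread", {
  const <- tibble::tibble(t = seq(0, 1e5, by = 1e4), h = 3)
  m <- steady_state_mean(const, c(2e4, 8e4))
  expect_equal(m$mean, 3)
  expect_equal(m$se, 0)
  expect_error(steady_state_mean(const, c(2e5, 3e5)),
               class = "chase_empty_window")
  ens <- tibble::tibble(run = rep(1:3, each = 4),
                        t = rep(c(1e4, 2e4, 3e4, 4e4), 3),
                        h = c(1, 1, 1, 9, 2, 2, 2, 9, 3, 3, 3, 9))
  m2 <- steady_state_mean(ens, c(0, 3e4))
  expect_equal(m2$mean, 2)
  expect_equal(m2$se, stats::sd(1:3) / sqrt(3))
  expect_equal(m2$n, 3L)
})
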