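test_that("choice model probabilities hit the calibrated anchors", {
  neutral <- data.frame(delta_theta = 0, delta_d = 0, amr = 1)
  expect_equal(choice_probability(neutral), 0.9)
  expect_gte(choice_probability(
    data.frame(delta_theta = -5, delta_d = 0, amr = 1)), 0.99)
  zero <- c(intercept = 0, delta_theta = 0, delta_d = 0, amr = 0)
  expect_equal(choice_probability(neutral, zero), 0.5)
  bad <- data.frame(delta_theta = Inf, delta_d = 0, amr = 1)
  expect_error(choice_probability(bad), "non-finite")
})

test_that("simulated choices are reproducible and converge to the model", {
  feats <- geometry_features(build_layout(5), 0)   # known P(right)
  p <- choice_probability(feats)
  set.seed(11); a <- simulate_choice(feats[rep(1, 50), ], sim_params())
  set.seed(11); b <- simulate_choice(feats[rep(1, 50), ], sim_params())
  expect_identical(a, b)
  n <- 4000
  set.seed(12)
  draws <- simulate_choice(feats[rep(1, n), ], sim_params())
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("trajectories: straight baseline, margin slowdown, determinism", {
  quiet <- sim_params(trajectory_jitter_sd = 0)
  straight <- simulate_trajectory(1, target_offset = 0, params = quiet)
  expect_lt(max(abs(straight$x_cm)), 1e-9)
  expect_equal(max(straight$y_cm), 750)
  # narrow margins (condition 6) slow the approach vs wide (condition 2)
  t2 <- simulate_trajectory(2, "right", 0, quiet)
  t6 <- simulate_trajectory(6, "right", 0, quiet)
  expect_lt(gait_speed(t6, "to_margin", build_layout(6)),
            gait_speed(t2, "to_margin", build_layout(2)))
  set.seed(4); a <- simulate_trajectory(3, "left", -30)
  set.seed(4); b <- simulate_trajectory(3, "left", -30)
  expect_identical(a, b)
  expect_error(simulate_trajectory(6, "middle", 0), "'arg' should be one of")
})

test_that("gaze streams follow the phase model", {
  # degenerate phase model: everything on the target, no jitter
  all_target <- data.frame(t_start = 0, t_end = 1, p_target = 1,
                           p_margin = 0, p_path = 0, p_none = 0)
  p <- sim_params(gaze_phase_model = all_target, gaze_jitter_sd = 0)
  set.seed(21)
  g <- simulate_gaze(6, 5, "right", 0, p)
  lab <- label_aoi(g$x_cm, g$y_cm, aoi_regions(6))
  expect_true(all(lab == "T"))
  # default late phase leaves almost no path/margin gaze probability
  gp <- default_gaze_phases()
  late <- gp[gp$t_start >= 0.8, ]
  expect_lte(late$p_margin + late$p_path, 0.05)
  # NOBST: mostly target, few path gazes
  set.seed(22)
  g0 <- simulate_gaze(1, 6, target_offset = 0, params = sim_params())
  lab0 <- label_aoi(g0$x_cm, g0$y_cm, aoi_regions(1))
  expect_gt(mean(lab0 == "T"), 0.6)
  expect_lt(mean(lab0 == "P"), 0.25)
})

test_that("phase-model validation rejects malformed inputs", {
  bad <- default_gaze_phases(); bad$p_target[1] <- 0.9
  expect_error(sim_params(gaze_phase_model = bad), "sum to 1")
  bad2 <- default_gaze_phases(); bad2$t_end[1] <- 0
  expect_error(sim_params(gaze_phase_model = bad2), "increasing")
})

test_that("judgment ratings follow the psychometric model", {
  noiseless <- sim_params(judgment_noise_sd = 0)
  set.seed(31)
  jd <- simulate_judgment(c(-35, -15, 0, 35), noiseless, n_raters = 3)
  expect_equal(jd$rating[jd$offset_cm == -15], rep(5, 3))  # the crossing
  expect_gt(min(jd$rating[jd$offset_cm == 35]), 9.99)      # saturated right
  # step-function limit
  step <- sim_params(judgment_noise_sd = 0, judgment_slope = 1e6)
  js <- simulate_judgment(c(-20, -10), step, n_raters = 1)
  expect_equal(sort(js$rating), c(0, 10))
  expect_error(simulate_judgment(c(0, 50)), "35 cm")
})

test_that("dataset generation: design size, determinism, trial invariants", {
  p1 <- sim_params(n_participants = 1, n_trials_per_cell = 1, seed = 3)
  d1 <- generate_dataset(p1)
  expect_equal(nrow(d1$trials), 24)
  # full default design: 12 participants x 24 cells x 3 trials
  full <- generate_dataset(sim_params(seed = 5), keep_samples = FALSE)
  expect_equal(nrow(full$trials), 864)
  d1b <- generate_dataset(p1)
  expect_identical(d1, d1b)
  # samples are time-ordered, start near the origin, end near the target
  for (id in d1$trials$trial_id[1:5]) {
    tr <- d1$trajectory[d1$trajectory$trial_id == id, ]
    expect_true(!is.unsorted(tr$t_s))
    expect_lt(abs(tr$x_cm[1]) + abs(tr$y_cm[1]), 1e-9)
    expect_gt(tr$y_cm[nrow(tr)], 740)
  }
  # chosen side matches the side of the obstacle the trajectory passes
  obs <- d1$trials[!is.na(d1$trials$chosen_side), ]
  for (i in seq_len(nrow(obs))) {
    tr <- obs[i, ]
    lay <- build_layout(tr$condition)
    traj <- d1$trajectory[d1$trajectory$trial_id == tr$trial_id, ]
    mid <- traj[which.min(abs(traj$y_cm -
      (lay$obstacle_distance + lay$obstacle_depth / 2))), ]
    expect_equal(if (mid$x_cm > lay$obstacle_lateral_offset) "right"
                 else "left", tr$chosen_side)
  }
})

test_that("gaze bias makes AMGR track the chosen side", {
  # conditions 4/5 give both left- and right-choosers
  p <- sim_params(n_participants = 4, n_trials_per_cell = 2, seed = 8)
  ds <- generate_dataset(p, conditions = c(4, 5), target_offsets = 0)
  a <- vapply(seq_len(nrow(ds$trials)), function(i) {
    tr <- ds$trials[i, ]
    g <- ds$gaze[ds$gaze$trial_id == tr$trial_id, ]
    amgr(g, aoi_regions(tr$condition))
  }, numeric(1))
  side <- ds$trials$chosen_side
  expect_gt(mean(a[side == "right"], na.rm = TRUE), 0)
  expect_lt(mean(a[side == "left"], na.rm = TRUE), 0)
})
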