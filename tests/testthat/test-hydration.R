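test_that("shell boundaries follow the ties-to-inner-shell convention", {
  cfg <- analysis_config()
  at <- data.frame(
    atom_id = 1:7,
    atom_name = c("C", "O", "H1", "H2", "O", "H1", "H2"),
    element = c("C", "O", "H", "H", "O", "H", "H"),
    residue_name = c("PSA", rep("HOH", 6)),
    residue_index = c(1, 2, 2, 2, 3, 3, 3),
    chain_id = "A",
    partial_charge = 0, lj_sigma = 1, lj_epsilon = 0,
    is_water = c(FALSE, rep(TRUE, 6)),
    is_hydrogen = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  sys <- solvated_system(at, water_molecules = rbind(2:4, 5:7),
                         solute_atom_ids = 1)
  # one water oxygen at exactly 3.5 A, one at 3.5 + 1e-6 A
  frame <- rbind(c(0, 0, 0),
                 c(3.5, 0, 0), c(4.3, 0.3, 0), c(4.3, -0.3, 0),
                 c(-3.5 - 1e-6, 0, 0), c(-4.3, 0.3, 0), c(-4.3, -0.3, 0))
  sh <- assign_shells(frame, sys, cfg)
  expect_equal(as.character(sh$shell), c("primary", "secondary"))
  expect_equal(sh$min_distance, c(3.5, 3.5 + 1e-6), tolerance = 1e-12)

  # a water at 2.0 A is primary; exactly 10.0 A is secondary (tie inward)
  frame[2, ] <- c(2, 0, 0); frame[5, ] <- c(-10, 0, 0)
  sh2 <- assign_shells(frame, sys, cfg)
  expect_equal(as.character(sh2$shell), c("primary", "secondary"))
})

test_that("shell assignment matches the brute-force oracle on random systems", {
  cfg <- analysis_config()
  for (seed in 1:6) {
    toy <- random_system(n_solute = sample(3:12, 1), n_waters = 40,
                         seed = 100 + seed)
    frame <- toy$frames$coords[[1]]
    got <- as.character(assign_shells(frame, toy$system, cfg)$shell)
    expect_equal(got, oracle_shells(frame, toy$system, cfg))
  }
})

test_that("shell counts partition the waters in every frame", {
  cfg <- analysis_config()
  toy <- random_system(6, 30, seed = 31)
  traj <- make_trajectory(toy, list(occupancy_pattern(1, c(2, 6)),
                                    occupancy_pattern(2, c(1, 10))),
                          n_frames = 10, jitter_sd = 0.04, seed = 32)
  sc <- shell_counts(traj, toy$system, cfg)
  expect_true(all(sc$n_primary + sc$n_secondary + sc$n_bulk == 30))
})

test_that("shell assignment is invariant under rigid rotation and translation", {
  cfg <- analysis_config()
  toy <- random_system(8, 25, seed = 41)
  frame <- toy$frames$coords[[1]]
  ref <- assign_shells(frame, toy$system, cfg)
  set.seed(42)
  rot <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
  moved <- frame %*% t(rot) + matrix(c(12, -7, 3), nrow(frame), 3,
                                     byrow = TRUE)
  got <- assign_shells(moved, toy$system, cfg)
  expect_equal(as.character(got$shell), as.character(ref$shell))
  expect_equal(got$min_distance, ref$min_distance, tolerance = 1e-9)
})

test_that("gap tolerance merges interior excursions like the interval oracle", {
  cfg <- analysis_config()
  toy <- make_toy_system(5, list(water_placement("primary", 2.8)), seed = 51)
  iv <- matrix(c(10, 20, 22, 30), ncol = 2, byrow = TRUE)
  traj <- make_trajectory(toy, list(occupancy_pattern(1, iv)),
                          n_frames = 40, jitter_sd = 0.03, seed = 52)
  merged <- residence_times(traj, toy$system, cfg, "primary",
                            gap_tolerance = 1)
  expect_equal(merged$runs$length, 21)
  split <- residence_times(traj, toy$system, cfg, "primary",
                           gap_tolerance = 0)
  expect_equal(split$runs$length, c(11, 9))

  # a water never in the shell yields no runs
  expect_equal(sum(split$runs$water_index != 1), 0)

  # non-uniform spacing with positive tolerance is undefined
  tr_nu <- frame_series(traj$coords[1:4], times = c(0, 1, 3, 10))
  expect_error(residence_times(tr_nu, toy$system, cfg, gap_tolerance = 1),
               "uniform")
})

test_that("Monte-Carlo shell volume matches the analytic single-atom sphere", {
  cfg <- analysis_config()
  at <- data.frame(atom_id = 1, atom_name = "C", element = "C",
                   residue_name = "PSA", residue_index = 1, chain_id = "A",
                   partial_charge = 0, lj_sigma = 1, lj_epsilon = 0,
                   is_water = FALSE, is_hydrogen = FALSE)
  sys <- solvated_system(at, solute_atom_ids = 1)
  frame <- matrix(0, 1, 3)
  sd_ <- shell_density(frame, sys, cfg, "primary", mc_samples = 4e4,
                       seed = 7)
  v_true <- 4 / 3 * pi * 3.5^3
  expect_lt(abs(sd_$volume - v_true), 3 * sd_$volume_se)
  expect_equal(sd_$density, 0)   # no waters in this system

  sec <- shell_density(frame, sys, cfg, "secondary", mc_samples = 4e4,
                       seed = 8)
  v_sec <- 4 / 3 * pi * (10^3 - 3.5^3)
  expect_lt(abs(sec$volume - v_sec), 3 * sec$volume_se)
})

test_that("shell density is linear in the shell water count", {
  cfg <- analysis_config()
  toy1 <- make_toy_system(6, lapply(c(2.5, 3.0), function(d)
    water_placement("primary", d)), seed = 61)
  toy2 <- make_toy_system(6, lapply(c(2.5, 3.0, 2.7, 3.2), function(d)
    water_placement("primary", d)), seed = 61)
  d1 <- shell_density(toy1$frames$coords[[1]], toy1$system, cfg, "primary",
                      mc_samples = 1e4, seed = 5)
  d2 <- shell_density(toy2$frames$coords[[1]], toy2$system, cfg, "primary",
                      mc_samples = 1e4, seed = 5)
  # same solute, same seed: identical volume estimate, doubled count
  expect_equal(d2$volume, d1$volume)
  expect_equal(d2$density, 2 * d1$density)
})

test_that("cumulative averages drop burn-in frames then average from scratch", {
  expect_equal(cumulative_average(c(1, 2, 3))$cum_avg, c(1, 1.5, 2))
  expect_equal(cumulative_average(rep(7, 5))$cum_avg, rep(7, 5))
  # 500 ns at 100 ps spacing with 40 ns burn-in: 4600 retained frames
  times <- seq(0, by = 100, length.out = 5000)
  ca <- cumulative_average(rnorm(5000), times, burn_in_time = 40000)
  expect_equal(nrow(ca), 4600)
  expect_error(cumulative_average(1:3, c(0, 1, 2), burn_in_time = 10),
               "discards all")
})
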