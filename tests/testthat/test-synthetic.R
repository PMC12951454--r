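test_that("toy systems realise their placement specification exactly", {
  cfg <- analysis_config()
  pl <- c(lapply(1:5, function(i) water_placement("primary", 2.5)),
          lapply(1:3, function(i) water_placement("secondary", 7.0)),
          list(water_placement("bulk", 12.5)))
  toy <- make_toy_system(10, pl, seed = 5)
  sh <- assign_shells(toy$frames$coords[[1]], toy$system, cfg)
  expect_equal(sum(sh$shell == "primary"), 5)
  expect_equal(sum(sh$shell == "secondary"), 3)
  expect_equal(sum(sh$shell == "bulk"), 1)
  # oxygens sit at the requested distance from the nearest heavy atom
  expect_lt(max(abs(sh$min_distance[1:5] - 2.5)), 1e-6)
  expect_lt(max(abs(sh$min_distance[6:8] - 7.0)), 1e-6)
  # no two water oxygens closer than 2 A
  o <- toy$frames$coords[[1]][sh$oxygen_atom, ]
  dmin <- min(dist(o))
  expect_gte(dmin, 2.0)
})

test_that("generators are deterministic for a fixed seed", {
  pl <- list(water_placement("primary"), water_placement("bulk"))
  a <- make_toy_system(7, pl, seed = 42)
  b <- make_toy_system(7, pl, seed = 42)
  expect_identical(a$frames$coords, b$frames$coords)
  c_ <- make_toy_system(7, pl, seed = 43)
  expect_false(identical(a$frames$coords, c_$frames$coords))

  t1 <- make_trajectory(a, list(occupancy_pattern(1, c(3, 9))),
                        n_frames = 12, seed = 9)
  t2 <- make_trajectory(a, list(occupancy_pattern(1, c(3, 9))),
                        n_frames = 12, seed = 9)
  expect_identical(t1$coords, t2$coords)

  d1 <- make_design_set("GAGAGAGAGA", 5, 2, 1, seed = 3)
  d2 <- make_design_set("GAGAGAGAGA", 5, 2, 1, seed = 3)
  expect_identical(d1$variants, d2$variants)
})

test_that("prescribed hydrogen-bond geometries are detected or rejected as built", {
  cfg <- analysis_config()
  lin <- make_toy_system(6, list(
    water_placement("primary", 2.8, hb_partner = 2, hb_geometry = "linear")),
    seed = 8)
  hb <- detect_hbonds(lin$frames$coords[[1]], lin$system, cfg)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$hb_class, "protein_water")
  expect_equal(hb$da_distance, 2.8, tolerance = 1e-9)
  expect_lt(hb$dha_deviation, 1e-6)

  # bent beyond the cutoff: rejected; bent inside: accepted at that angle
  for (theta in c(45, 60)) {
    bent <- make_toy_system(6, list(
      water_placement("primary", 2.8, hb_partner = 2, hb_geometry = "bent",
                      bend_angle = theta)), seed = 8)
    hbb <- detect_hbonds(bent$frames$coords[[1]], bent$system, cfg)
    expect_equal(nrow(hbb[hbb$hb_class == "protein_water", ]), 0)
  }
  bent20 <- make_toy_system(6, list(
    water_placement("primary", 2.8, hb_partner = 2, hb_geometry = "bent",
                    bend_angle = 20)), seed = 8)
  hb20 <- detect_hbonds(bent20$frames$coords[[1]], bent20$system, cfg)
  expect_equal(nrow(hb20), 1)
  expect_equal(hb20$dha_deviation, 20, tolerance = 1e-6)
})

test_that("trajectories realise occupancy patterns as residence runs", {
  toy <- random_system(8, 6, seed = 21)
  cfg <- analysis_config()
  traj <- make_trajectory(toy, list(occupancy_pattern(1, c(10, 50))),
                          n_frames = 100, jitter_sd = 0.05, seed = 22)
  rt <- residence_times(traj, toy$system, cfg, shell = "primary")
  runs1 <- rt$runs[rt$runs$water_index == 1, ]
  expect_equal(nrow(runs1), 1)
  expect_equal(runs1$start_frame, 10)
  expect_equal(runs1$length, 41)

  # two disjoint intervals give two runs of the constructed lengths,
  # matching the interval-arithmetic oracle
  iv <- matrix(c(10, 20, 22, 30), ncol = 2, byrow = TRUE)
  traj2 <- make_trajectory(toy, list(occupancy_pattern(2, iv)),
                           n_frames = 40, jitter_sd = 0.04, seed = 23)
  rt2 <- residence_times(traj2, toy$system, cfg, shell = "primary")
  runs2 <- rt2$runs[rt2$runs$water_index == 2, ]
  occ <- rep(FALSE, 40); occ[10:20] <- TRUE; occ[22:30] <- TRUE
  orc <- oracle_runs(occ, tol = 0)
  expect_equal(runs2$start_frame, unname(orc[, "start"]))
  expect_equal(runs2$length, unname(orc[, "length"]))

  # empty patterns: every water is bulk in every frame
  traj3 <- make_trajectory(toy, list(), n_frames = 5, seed = 24)
  sc <- shell_counts(traj3, toy$system, cfg)
  expect_true(all(sc$n_bulk == 6))
  expect_true(all(sc$n_primary == 0))
})

test_that("boundary-crossing jitter is refused", {
  toy <- make_toy_system(6, list(water_placement("primary", 2.8)), seed = 2)
  expect_error(
    make_trajectory(toy, list(occupancy_pattern(1, c(1, 5))), n_frames = 5,
                    jitter_sd = 0.5, seed = 3),
    "cross the shell boundary")
})

test_that("temperature-series generator stores recoverable ground truth", {
  # noise-free lines recovered exactly, including realistic magnitudes
  slopes <- c(I23 = -0.64, L71 = -5.3)
  ts <- make_nmr_tempseries(slopes, noise_sd = 0, seed = 1)
  tc <- temp_coefficient(ts)
  expect_equal(tc$slope[match(names(slopes), tc$residue)],
               unname(slopes), tolerance = 1e-9)
  expect_true(all(tc$r_squared > 1 - 1e-9))
  expect_error(make_nmr_tempseries(c(A = -5), temperatures = c(280, 290)),
               "3 temperatures")

  # Monte-Carlo: with 5 ppb noise over 8 points the mean recovered slope
  # over 200 seeds is within 0.5 ppb/K of the truth
  errs <- vapply(1:200, function(s) {
    tab <- make_nmr_tempseries(c(X = -3.0), noise_sd = 5, seed = s)
    temp_coefficient(tab)$slope + 3.0
  }, 0)
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("HDX generator thresholds follow the closed-form decay", {
  residues <- sprintf("r%02d", 1:76)
  tab <- make_hdx_table(residues, protected = residues[1:30], k_fast = 1.0,
                        k_slow = 0.01, times = c(0, 48))
  hp <- hdx_protection(tab, t = 48, thresholds = 0.2)
  # protected: exp(-0.01*48) = 0.619 >= 0.2; unprotected: exp(-48) < 0.2
  expect_equal(unname(hp$counts[1]), 30)
  prot_ratio <- hp$results$ratio[hp$results$residue %in% residues[1:30]]
  expect_equal(prot_ratio, rep(exp(-0.48), 30), tolerance = 1e-12)

  # fully protected at k_slow = 0: ratio exactly 1 at 48 h
  tab0 <- make_hdx_table("A", protected = "A", k_fast = 1, k_slow = 0)
  hp0 <- hdx_protection(tab0, t = 48, thresholds = 0.2)
  expect_equal(hp0$results$ratio, 1.0)
  expect_error(make_hdx_table("A", k_fast = 0.1, k_slow = 0.2))
  expect_error(make_hdx_table("A", times = c(24, 48)), "include 0")
})

test_that("design-set generator applies exactly the requested substitutions", {
  template <- paste(rep("A", 76), collapse = "")
  ds <- make_design_set(template, 10, extra_pos = 4, extra_neg = 5, seed = 6)
  for (v in ds$variants) {
    sm <- substitution_map(template, v)
    expect_equal(attr(sm, "count"), 9)
    expect_equal(sum(sm$to %in% c("K", "R")), 4)
    expect_equal(sum(sm$to %in% c("D", "E")), 5)
  }
  expect_error(make_design_set("KRDE", 1, 1, 1), "substitutable")
  empty <- make_design_set(template, 0, 1, 1, seed = 1)
  expect_length(empty$variants, 0)
  expect_error(enrichment_stats(empty), "empty")
})
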