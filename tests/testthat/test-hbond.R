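make_simple_system <- function(atoms, water_rows = NULL, bonds = NULL) {
  n <- nrow(atoms)
  defaults <- data.frame(
    atom_id = seq_len(n), chain_id = "A",
    partial_charge = 0, lj_sigma = 1, lj_epsilon = 0)
  at <- cbind(atoms, defaults[setdiff(names(defaults), names(atoms))])
  wm <- if (is.null(water_rows)) matrix(integer(0), ncol = 3) else water_rows
  solvated_system(at, bonds = if (is.null(bonds)) matrix(integer(0), ncol = 2)
                  else bonds,
                  water_molecules = wm,
                  solute_atom_ids = setdiff(seq_len(n), as.integer(wm)))
}

test_that("donor and acceptor resolution follows element and bonding rules", {
  cfg <- analysis_config()
  # backbone amide N-H plus carbonyl O plus a carbon-bound H
  at <- data.frame(
    atom_name = c("N", "H", "C", "O", "CA", "HA"),
    element = c("N", "H", "C", "O", "C", "H"),
    residue_name = "ALA", residue_index = 1,
    is_water = FALSE, is_hydrogen = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  sys <- make_simple_system(at)
  frame <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(0, 2, 0), c(0, 3.2, 0),
                 c(2, 2, 0), c(2, 3.09, 0))
  da <- find_donors_acceptors(sys, cfg, frame)
  expect_equal(da$donors$donor_atom, 1)       # N-H donor only
  expect_equal(da$donors$hydrogen_atom, 2)
  expect_setequal(da$acceptors, c(1, 4))      # N and O accept; C/H never

  # one water: one donor with two hydrogens, one acceptor
  atw <- data.frame(atom_name = c("O", "H1", "H2"),
                    element = c("O", "H", "H"),
                    residue_name = "HOH", residue_index = 1,
                    is_water = TRUE, is_hydrogen = c(FALSE, TRUE, TRUE))
  wsys <- make_simple_system(atw, water_rows = matrix(1:3, 1))
  wframe <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  wda <- find_donors_acceptors(wsys, cfg, wframe)
  expect_equal(nrow(wda$donors), 2)
  expect_equal(unique(wda$donors$donor_atom), 1)
  expect_equal(wda$acceptors, 1)

  # an orphan hydrogen (no heavy atom within 1.2 A, no bond) is an error
  frame_orphan <- frame
  frame_orphan[2, ] <- c(5, 5, 5)
  expect_error(find_donors_acceptors(sys, cfg, frame_orphan), "1.2 A")
})

test_that("the geometric criterion accepts collinear and rejects distant pairs", {
  cfg <- analysis_config()
  at <- data.frame(atom_name = c("O", "H1", "H2", "O"),
                   element = c("O", "H", "H", "O"),
                   residue_name = c("HOH", "HOH", "HOH", "PSA"),
                   residue_index = c(1, 1, 1, 2),
                   is_water = c(TRUE, TRUE, TRUE, FALSE),
                   is_hydrogen = c(FALSE, TRUE, TRUE, FALSE))
  sys <- make_simple_system(at, water_rows = matrix(1:3, 1))
  frame <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0), c(2.8, 0, 0))
  hb <- detect_hbonds(frame, sys, cfg)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$da_distance, 2.8)
  expect_lt(hb$dha_deviation, 1e-9)
  expect_equal(hb$hb_class, "protein_water")

  frame[4, ] <- c(4.0, 0, 0)   # beyond the 3.5 A distance cutoff
  expect_equal(nrow(detect_hbonds(frame, sys, cfg)), 0)
})

test_that("detected hydrogen bonds equal the exhaustive triple-loop oracle", {
  cfg <- analysis_config()
  for (seed in 1:4) {
    toy <- random_system(n_solute = 10, n_waters = 50, seed = 200 + seed)
    frame <- toy$frames$coords[[1]]
    got <- detect_hbonds(frame, toy$system, cfg)
    want <- oracle_hbonds(frame, toy$system, cfg)
    key <- function(df) sort(paste(df$donor_atom, df$acceptor_atom))
    expect_equal(key(got), key(want))
    if (nrow(got) > 0) {
      got_s <- got[order(got$donor_atom, got$acceptor_atom), ]
      want_s <- want[order(want$donor_atom, want$acceptor_atom), ]
      expect_equal(got_s$dha_deviation, want_s$dha_deviation,
                   tolerance = 1e-9)
      expect_equal(got_s$da_distance, want_s$da_distance, tolerance = 1e-9)
    }
  }
})

test_that("a single physical bond is counted once through its best hydrogen", {
  cfg <- analysis_config(hb_angle_cutoff = 80)
  # both water hydrogens point loosely toward the same acceptor
  at <- data.frame(atom_name = c("O", "H1", "H2", "N"),
                   element = c("O", "H", "H", "N"),
                   residue_name = c("HOH", "HOH", "HOH", "PSA"),
                   residue_index = c(1, 1, 1, 2),
                   is_water = c(TRUE, TRUE, TRUE, FALSE),
                   is_hydrogen = c(FALSE, TRUE, TRUE, FALSE))
  sys <- make_simple_system(at, water_rows = matrix(1:3, 1))
  h1 <- 0.9572 * c(cos(0.6), sin(0.6), 0)
  h2 <- 0.9572 * c(cos(-0.6), sin(-0.6), 0)
  frame <- rbind(c(0, 0, 0), h1, h2, c(2.9, 0, 0))
  hb <- detect_hbonds(frame, sys, cfg)
  expect_equal(nrow(hb), 1)
  # the kept hydrogen has the smaller deviation of the two
  dev_of <- function(h) {
    v1 <- -h; v2 <- c(2.9, 0, 0) - h
    180 - acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  expect_equal(hb$dha_deviation, min(dev_of(h1), dev_of(h2)),
               tolerance = 1e-9)
})

test_that("counts are monotone in both cutoffs and invariant to water order", {
  toy <- random_system(8, 40, seed = 71)
  frame <- toy$frames$coords[[1]]
  base <- analysis_config()
  n_base <- nrow(detect_hbonds(frame, toy$system, base))
  wider_d <- analysis_config(hb_distance_cutoff = 4.2)
  wider_a <- analysis_config(hb_angle_cutoff = 50)
  expect_gte(nrow(detect_hbonds(frame, toy$system, wider_d)), n_base)
  expect_gte(nrow(detect_hbonds(frame, toy$system, wider_a)), n_base)

  # permuting water enumeration leaves the water-water count unchanged
  sys <- toy$system
  perm <- sample(nrow(sys$water_molecules))
  sys_perm <- sys
  sys_perm$water_molecules <- sys$water_molecules[perm, , drop = FALSE]
  a <- detect_hbonds(frame, sys, base)
  b <- detect_hbonds(frame, sys_perm, base)
  expect_equal(sum(a$hb_class == "water_water"),
               sum(b$hb_class == "water_water"))
})

test_that("per-frame and per-residue aggregation match direct recomputation", {
  cfg <- analysis_config()
  toy <- make_toy_system(6, list(
    water_placement("primary", 2.8, hb_partner = 2, hb_geometry = "linear"),
    water_placement("secondary"), water_placement("bulk")), seed = 81)
  traj <- make_trajectory(toy, list(occupancy_pattern(1, c(1, 10)),
                                    occupancy_pattern(2, c(1, 10),
                                                      shell = "secondary")),
                          n_frames = 10, jitter_sd = 0, seed = 82)
  hc <- hbond_counts(traj, toy$system, cfg)
  for (f in c(1, 5, 10)) {
    hb <- detect_hbonds(traj$coords[[f]], toy$system, cfg)
    expect_equal(hc$n_protein_water[f], sum(hb$hb_class == "protein_water"))
  }
  # a persistent single donor bond gives a per-residue mean of 1.0
  pr <- per_residue_hbond_map(traj, toy$system, cfg)
  expect_equal(sum(pr$mean_protein_water), 1.0, tolerance = 1e-12)
  expect_equal(pr$mean_protein_water[pr$residue_index == 2], 1.0)
})
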