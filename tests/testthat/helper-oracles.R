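# Independent brute-force oracles, written as explicit scalar loops so they
# share no code path with the vectorised implementations they check.

oracle_min_dist <- function(points, ref) {
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    best <- Inf
    for (j in seq_len(nrow(ref))) {
      d <- sqrt(sum((points[i, ] - ref[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

oracle_shells <- function(frame, system, config) {
  heavy <- which(!system$atoms$is_hydrogen &
                   seq_len(nrow(system$atoms)) %in% system$solute_atom_ids)
  wm <- system$water_molecules
  shells <- character(nrow(wm))
  for (w in seq_len(nrow(wm))) {
    o <- wm[w, ][!system$atoms$is_hydrogen[wm[w, ]]]
    d <- oracle_min_dist(frame[o, , drop = FALSE],
                         frame[heavy, , drop = FALSE])
    shells[w] <- if (d <= config$primary_cutoff) "primary"
    else if (d <= config$secondary_cutoff) "secondary" else "bulk"
  }
  shells
}

# exhaustive donor x hydrogen x acceptor loop under the geometric criterion,
# with the same (D,A)-deduplication rule (best-deviation hydrogen)
oracle_hbonds <- function(frame, system, config) {
  atoms <- system$atoms
  polar <- c("N", "O")
  wat_of <- rep(NA_integer_, nrow(atoms))
  wm <- system$water_molecules
  if (nrow(wm) > 0) wat_of[as.integer(wm)] <- rep(seq_len(nrow(wm)), 3)

  h_of <- list()
  for (k in seq_len(nrow(system$bonds))) {
    i <- system$bonds[k, 1]; j <- system$bonds[k, 2]
    if (atoms$is_hydrogen[j] && !atoms$is_hydrogen[i]) {
      h_of[[as.character(i)]] <- c(h_of[[as.character(i)]], j)
    } else if (atoms$is_hydrogen[i] && !atoms$is_hydrogen[j]) {
      h_of[[as.character(j)]] <- c(h_of[[as.character(j)]], i)
    }
  }
  # hydrogens without bonds: nearest heavy atom within 1.2 A
  bonded_h <- unlist(h_of, use.names = FALSE)
  for (h in which(atoms$is_hydrogen)) {
    if (h %in% bonded_h) next
    heavies <- which(!atoms$is_hydrogen)
    best <- Inf; who <- NA
    for (j in heavies) {
      dj <- sqrt(sum((frame[h, ] - frame[j, ])^2))
      if (dj < best) { best <- dj; who <- j }
    }
    if (best <= 1.2) h_of[[as.character(who)]] <- c(h_of[[as.character(who)]], h)
  }

  donors <- intersect(as.integer(names(h_of)),
                      which(atoms$element %in% polar))
  acceptors <- which(atoms$element %in% polar)
  recs <- list()
  for (d_ in donors) {
    for (a_ in acceptors) {
      if (d_ == a_) next
      if (!is.na(wat_of[d_]) && !is.na(wat_of[a_]) &&
          wat_of[d_] == wat_of[a_]) next
      r_da <- sqrt(sum((frame[d_, ] - frame[a_, ])^2))
      if (r_da > config$hb_distance_cutoff) next
      best_dev <- Inf; best_h <- NA
      for (h_ in h_of[[as.character(d_)]]) {
        v1 <- frame[d_, ] - frame[h_, ]
        v2 <- frame[a_, ] - frame[h_, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        dev <- 180 - ang
        if (dev < best_dev) { best_dev <- dev; best_h <- h_ }
      }
      if (best_dev <= config$hb_angle_cutoff) {
        recs[[length(recs) + 1]] <- data.frame(
          donor_atom = d_, hydrogen_atom = best_h, acceptor_atom = a_,
          da_distance = r_da, dha_deviation = best_dev)
      }
    }
  }
  if (length(recs) == 0) {
    return(data.frame(donor_atom = integer(0), hydrogen_atom = integer(0),
                      acceptor_atom = integer(0)))
  }
  do.call(rbind, recs)
}

oracle_energy <- function(frame, atoms, groupA, groupB, config) {
  lj <- coul <- 0; n_pairs <- 0
  for (i in groupA) {
    for (j in groupB) {
      r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      if (r > config$energy_cutoff || r == 0) next
      sig <- (atoms$lj_sigma[i] + atoms$lj_sigma[j]) / 2
      eps <- sqrt(atoms$lj_epsilon[i] * atoms$lj_epsilon[j])
      lj <- lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      coul <- coul + 332.0637 * atoms$partial_charge[i] *
        atoms$partial_charge[j] / (config$dielectric * r)
      n_pairs <- n_pairs + 1
    }
  }
  list(lj = lj, coulomb = coul, total = lj + coul, n_pairs = n_pairs)
}

oracle_rg <- function(x, masses = rep(1, nrow(x))) {
  com <- c(sum(x[, 1] * masses), sum(x[, 2] * masses),
           sum(x[, 3] * masses)) / sum(masses)
  s <- 0
  for (i in seq_len(nrow(x))) s <- s + masses[i] * sum((x[i, ] - com)^2)
  sqrt(s / sum(masses))
}

# run lengths from explicit interval arithmetic over a logical occupancy
# vector, merging interior gaps of at most `tol` frames
oracle_runs <- function(occupied, tol = 0) {
  runs <- list()
  i <- 1; n <- length(occupied)
  while (i <= n) {
    if (!occupied[i]) { i <- i + 1; next }
    start <- i
    end <- i
    j <- i + 1
    while (j <= n) {
      if (occupied[j]) { end <- j; j <- j + 1; next }
      gap <- 0
      k <- j
      while (k <= n && !occupied[k]) { gap <- gap + 1; k <- k + 1 }
      if (gap <= tol && k <= n) { end <- k; j <- k + 1 } else break
    }
    runs[[length(runs) + 1]] <- c(start = start, length = end - start + 1)
    i <- end + 1
  }
  if (length(runs) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, runs)
}

# random toy system for property tests: solute cluster plus waters spread
# over all three shells
random_system <- function(n_solute, n_waters, seed,
                          config = analysis_config()) {
  # keep the solute surface large enough that the requested primary-shell
  # waters can coexist at >= 2 A separation
  n_solute <- max(n_solute, n_waters)
  set.seed(seed)
  shells <- sample(c("primary", "secondary", "bulk"), n_waters,
                   replace = TRUE)
  dists <- ifelse(shells == "primary", runif(n_waters, 2.4, 3.4),
                  ifelse(shells == "secondary", runif(n_waters, 4.0, 9.5),
                         runif(n_waters, 10.6, 15.0)))
  pl <- lapply(seq_len(n_waters), function(i)
    water_placement(shells[i], dists[i]))
  make_toy_system(n_solute, pl, seed = seed, config = config)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  outer(a, a) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s_
}
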