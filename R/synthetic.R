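# Water geometry constants (TIP3P-like rigid water)
OH_BOND <- 0.9572      # Angstrom
HOH_ANGLE <- 104.52    # degrees

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# any unit vector perpendicular to v
perp_unit <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(ref, v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v about unit axis k by angle (degrees)
rotate_about <- function(v, k, angle_deg) {
  th <- angle_deg * pi / 180
  k <- unit(k)
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# isotropic Gaussian displacement with norm truncated at 3 sd (resampled)
trunc_jitter <- function(sd) {
  if (sd <= 0) return(c(0, 0, 0))
  repeat {
    v <- stats::rnorm(3, sd = sd)
    if (sqrt(sum(v^2)) <= 3 * sd) return(v)
  }
}

#' Specify the placement of one synthetic water
#'
#' @param shell Target hydration shell under the active cutoffs.
#' @param target_distance Distance (Angstrom) from the water oxygen to the
#'   nearest solute heavy atom. Defaults per shell: 2.8 (primary), 6.5
#'   (secondary), 13.0 (bulk).
#' @param hb_partner Optional solute atom id the water donates a hydrogen
#'   bond to; required for `hb_geometry` other than `"none"`.
#' @param hb_geometry `"none"` (random orientation), `"linear"` (one O-H
#'   aimed exactly at the partner: donor-H...acceptor deviation 0) or
#'   `"bent"` (deviation exactly `bend_angle` degrees).
#' @param bend_angle Deviation from linearity (degrees, in (0, 90)) for
#'   `hb_geometry = "bent"`.
#' @return Object of class `"water_placement"`.
#' @export
water_placement <- function(shell = c("primary", "secondary", "bulk"),
                            target_distance = NULL, hb_partner = NULL,
                            hb_geometry = c("none", "linear", "bent"),
                            bend_angle = NULL) {
  shell <- match.arg(shell)
  hb_geometry <- match.arg(hb_geometry)
  if (is.null(target_distance)) {
    target_distance <- c(primary = 2.8, secondary = 6.5, bulk = 13.0)[[shell]]
  }
  if (hb_geometry != "none" && is.null(hb_partner)) {
    stop("hb_partner is required for hb_geometry = ", dQuote(hb_geometry))
  }
  if (hb_geometry == "bent") {
    if (is.null(bend_angle) || bend_angle <= 0 || bend_angle >= 90) {
      stop("bend_angle must lie in (0, 90) degrees")
    }
  }
  structure(list(shell = shell, target_distance = as.numeric(target_distance),
                 hb_partner = hb_partner, hb_geometry = hb_geometry,
                 bend_angle = bend_angle),
            class = "water_placement")
}

check_placement_shell <- function(p, config) {
  d <- p$target_distance
  ok <- switch(p$shell,
               primary = d > 0 && d <= config$primary_cutoff,
               secondary = d > config$primary_cutoff &&
                 d <= config$secondary_cutoff,
               bulk = d > config$secondary_cutoff)
  if (!ok) {
    stop(sprintf("target_distance %.2f A is inconsistent with shell %s",
                 d, dQuote(p$shell)))
  }
  invisible(p)
}

#' Build a toy solvated system with waters at prescribed shell distances
#'
#' The solute is a compact cluster of charged heavy pseudo-atoms (alternating
#' N/O elements, charges +0.5/-0.5 e, one residue per atom) on a jittered
#' cubic lattice. Each requested water oxygen is placed so its minimum
#' distance to the solute heavy atoms equals `target_distance` to within
#' 1e-6 Angstrom; waters with a prescribed hydrogen-bond geometry are
#' oriented so the donor-H...acceptor deviation toward `hb_partner` is
#' exactly 0 (linear) or `bend_angle` degrees (bent). Waters carry
#' TIP3P-like charges (O -0.834 e, H +0.417 e) with Lennard-Jones on oxygen
#' only. Output is deterministic for a fixed seed.
#'
#' @param n_solute Number of solute pseudo-atoms (>= 1).
#' @param placements List of [water_placement()] objects.
#' @param seed Integer seed.
#' @param config An [analysis_config()] defining the shell cutoffs.
#' @param solute_spacing Lattice spacing of the solute cluster (Angstrom).
#' @return List with `system` ([solvated_system()]) and `frames` (a
#'   single-frame [frame_series()]).
#' @export
make_toy_system <- function(n_solute, placements = list(), seed = 1,
                            config = analysis_config(),
                            solute_spacing = 2.5) {
  stopifnot(n_solute >= 1)
  set.seed(as.integer(seed))
  for (p in placements) {
    stopifnot(inherits(p, "water_placement"))
    check_placement_shell(p, config)
  }

  # compact convex cluster: pseudo-atoms on a Fibonacci-sphere shell, so
  # every atom is a hull vertex and a water placed radially outward from any
  # atom has that atom as its nearest solute neighbour
  if (n_solute == 1) {
    solute_xyz <- matrix(0, 1, 3)
  } else {
    r_shell <- solute_spacing * max(sqrt(n_solute) / 3.809, 0.5)
    i <- seq_len(n_solute) - 0.5
    phi <- acos(1 - 2 * i / n_solute)
    theta <- pi * (1 + sqrt(5)) * i
    radii <- r_shell + stats::runif(n_solute, -0.02, 0.02)
    solute_xyz <- cbind(radii * sin(phi) * cos(theta),
                        radii * sin(phi) * sin(theta),
                        radii * cos(phi))
  }
  dimnames(solute_xyz) <- NULL

  elements <- rep(c("N", "O"), length.out = n_solute)
  charges <- rep(c(0.5, -0.5), length.out = n_solute)
  solute_atoms <- data.frame(
    atom_id = seq_len(n_solute),
    atom_name = elements,
    element = elements,
    residue_name = "PSA",
    residue_index = seq_len(n_solute),
    chain_id = "A",
    partial_charge = charges,
    lj_sigma = 3.4,
    lj_epsilon = 0.1,
    is_water = FALSE,
    is_hydrogen = FALSE,
    stringsAsFactors = FALSE
  )

  centroid <- colMeans(solute_xyz)
  water_xyz <- NULL
  water_atoms <- NULL
  placed_O <- matrix(numeric(0), ncol = 3)
  next_id <- n_solute + 1L

  for (wi in seq_along(placements)) {
    p <- placements[[wi]]
    fixed_anchor <- !is.null(p$hb_partner)
    if (fixed_anchor && (p$hb_partner < 1 || p$hb_partner > n_solute)) {
      stop("hb_partner must be a solute atom id")
    }
    o_pos <- NULL
    for (try in seq_len(2000)) {
      if (fixed_anchor) {
        # partner-anchored: start radial, then small rotations off radial
        anchor <- p$hb_partner
        apos <- solute_xyz[anchor, ]
        u <- if (n_solute == 1 ||
                 sqrt(sum((apos - centroid)^2)) < 1e-9) {
          unit(stats::rnorm(3))
        } else unit(apos - centroid)
        dir <- if (try == 1) u else {
          rotate_about(u, perp_unit(unit(u + stats::rnorm(3, sd = 0.3))),
                       stats::runif(1, 2, 20))
        }
      } else {
        # free placement: random direction, anchored at the extreme atom
        # along it — convexity makes that atom the nearest by construction
        dir <- unit(stats::rnorm(3))
        anchor <- which.max(as.vector(solute_xyz %*% dir))
        apos <- solute_xyz[anchor, ]
      }
      cand <- apos + p$target_distance * dir
      md <- min_dist_to_set(matrix(cand, ncol = 3), solute_xyz)
      sep_ok <- nrow(placed_O) == 0 ||
        min(min_dist_to_set(matrix(cand, ncol = 3), placed_O)) >= 2.0
      if (abs(md - p$target_distance) <= 1e-6 && sep_ok) {
        o_pos <- cand
        break
      }
    }
    if (is.null(o_pos)) {
      stop(sprintf("placement %d unsatisfiable after bounded retries", wi))
    }

    if (p$hb_geometry == "none") {
      h1_dir <- unit(stats::rnorm(3))
    } else {
      a_pos <- solute_xyz[p$hb_partner, ]
      d_oa <- sqrt(sum((a_pos - o_pos)^2))
      theta <- if (p$hb_geometry == "linear") 0 else p$bend_angle
      # angle at the donor oxygen between O->H and O->A that realises a
      # D-H...A deviation of exactly theta (law of sines in the D-H-A
      # triangle): alpha = theta - asin((r_OH/d_OA) sin theta)
      th <- theta * pi / 180
      alpha <- th - asin(pmin(1, (OH_BOND / d_oa) * sin(th)))
      ahat <- unit(a_pos - o_pos)
      h1_dir <- unit(cos(alpha) * ahat + sin(alpha) * perp_unit(ahat))
    }
    axis <- perp_unit(h1_dir)
    h2_dir <- unit(rotate_about(h1_dir, axis, HOH_ANGLE))
    w_xyz <- rbind(o_pos, o_pos + OH_BOND * h1_dir, o_pos + OH_BOND * h2_dir)
    water_xyz <- rbind(water_xyz, w_xyz)
    placed_O <- rbind(placed_O, o_pos)
    water_atoms <- rbind(water_atoms, data.frame(
      atom_id = next_id + 0:2,
      atom_name = c("O", "H1", "H2"),
      element = c("O", "H", "H"),
      residue_name = "HOH",
      residue_index = wi,
      chain_id = "W",
      partial_charge = c(-0.834, 0.417, 0.417),
      lj_sigma = c(3.15061, 0, 0),
      lj_epsilon = c(0.1521, 0, 0),
      is_water = TRUE,
      is_hydrogen = c(FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE
    ))
    next_id <- next_id + 3L
  }

  atoms <- rbind(solute_atoms, water_atoms)
  n_w <- length(placements)
  wm <- if (n_w > 0) {
    matrix(n_solute + rep((seq_len(n_w) - 1) * 3, each = 3) + 1:3,
           ncol = 3, byrow = TRUE)
  } else matrix(integer(0), ncol = 3)
  system <- solvated_system(atoms, bonds = water_oh_bonds(wm, atoms),
                            water_molecules = wm,
                            solute_atom_ids = seq_len(n_solute))
  coords <- rbind(solute_xyz, water_xyz)
  dimnames(coords) <- NULL
  list(system = system, frames = frame_series(coords))
}

#' Prescribe primary-shell occupancy intervals for one water
#'
#' @param water_index Index of the water (row of `water_molecules`).
#' @param intervals Two-column matrix (or vector of length 2) of inclusive
#'   1-based `[start, end]` frame index pairs; must be sorted and
#'   non-overlapping.
#' @param shell Shell occupied during the intervals (`"primary"` by default;
#'   `"secondary"` generalises the pattern). Outside the intervals the water
#'   sits beyond the secondary cutoff (bulk).
#' @return Object of class `"occupancy_pattern"`.
#' @export
occupancy_pattern <- function(water_index, intervals,
                              shell = c("primary", "secondary")) {
  shell <- match.arg(shell)
  if (is.vector(intervals)) intervals <- matrix(intervals, ncol = 2,
                                                byrow = TRUE)
  intervals <- matrix(as.integer(intervals), ncol = 2)
  stopifnot(nrow(intervals) >= 1, all(intervals[, 1] <= intervals[, 2]),
            all(intervals >= 1))
  if (nrow(intervals) > 1) {
    if (any(diff(intervals[, 1]) <= 0) ||
        any(intervals[-1, 1] <= intervals[-nrow(intervals), 2])) {
      stop("intervals must be sorted and non-overlapping")
    }
  }
  structure(list(water_index = as.integer(water_index),
                 intervals = intervals, shell = shell),
            class = "occupancy_pattern")
}

#' Generate a trajectory with prescribed shell occupancy
#'
#' Every frame starts from the toy system's geometry: the solute moves
#' rigidly (a common truncated-Gaussian translation per frame), and each
#' water is translated onto its "in" position (inside the pattern's shell)
#' during its occupancy intervals and onto a bulk position beyond the
#' secondary cutoff otherwise, then jittered by an isotropic Gaussian of
#' standard deviation `jitter_sd` truncated at 3 sd. The truncation bound is
#' checked against every shell-boundary margin up front, so jitter can never
#' flip a shell assignment; waters not named in any pattern are bulk in all
#' frames.
#'
#' @param toy Output of [make_toy_system()] (list with `system`, `frames`),
#'   or a `solvated_system` together with `base_frame`.
#' @param patterns List of [occupancy_pattern()] objects.
#' @param n_frames Number of frames.
#' @param dt Frame spacing (ps), > 0.
#' @param jitter_sd Gaussian jitter standard deviation (Angstrom).
#' @param seed Integer seed.
#' @param config An [analysis_config()].
#' @param base_frame Coordinates to use when `toy` is a bare system.
#' @return A [frame_series()].
#' @export
make_trajectory <- function(toy, patterns = list(), n_frames = 100, dt = 1,
                            jitter_sd = 0.05, seed = 1,
                            config = analysis_config(), base_frame = NULL) {
  if (inherits(toy, "solvated_system")) {
    system <- toy
    if (is.null(base_frame)) stop("base_frame required with a bare system")
  } else {
    system <- toy$system
    base_frame <- toy$frames$coords[[1]]
  }
  base_frame <- check_frame(base_frame, system)
  stopifnot(dt > 0, n_frames >= 1, jitter_sd >= 0)
  set.seed(as.integer(seed))

  n_w <- nrow(system$water_molecules)
  for (p in patterns) {
    stopifnot(inherits(p, "occupancy_pattern"))
    if (p$water_index < 1 || p$water_index > n_w) {
      stop("pattern references water ", p$water_index,
           " but the system has ", n_w, " waters")
    }
    if (any(p$intervals > n_frames)) {
      stop("pattern interval exceeds n_frames")
    }
  }
  pattern_of <- rep(NA_integer_, n_w)
  for (i in seq_along(patterns)) {
    w <- patterns[[i]]$water_index
    if (!is.na(pattern_of[w])) stop("water ", w, " has multiple patterns")
    pattern_of[w] <- i
  }

  heavy <- solute_heavy_ids(system)
  solute_xyz <- base_frame[heavy, , drop = FALSE]
  o_ids <- water_oxygen_ids(system)
  pc <- config$primary_cutoff
  sc <- config$secondary_cutoff

  # per-water "in"/"out" oxygen targets along the outward axis through the
  # nearest solute heavy atom, with their realised shell margins
  in_pos <- out_pos <- matrix(NA_real_, n_w, 3)
  margin <- rep(Inf, n_w + 1)
  for (w in seq_len(n_w)) {
    o <- base_frame[o_ids[w], ]
    d_all <- min_dist_to_set(matrix(o, ncol = 3), solute_xyz)
    nearest <- which.min(cross_dist(matrix(o, ncol = 3), solute_xyz))
    apos <- solute_xyz[nearest, ]
    u <- if (d_all < 1e-9) unit(stats::rnorm(3)) else unit(o - apos)

    shell_in <- if (!is.na(pattern_of[w])) patterns[[pattern_of[w]]]$shell
                else "primary"
    d_in_target <- if (shell_in == "primary") min(2.8, 0.8 * pc)
                   else (pc + sc) / 2
    keep_current <- (shell_in == "primary" && d_all <= 0.8 * pc) ||
      (shell_in == "secondary" && d_all > 1.1 * pc && d_all <= 0.9 * sc)
    in_pos[w, ] <- if (keep_current) o else apos + d_in_target * u
    m_in <- min_dist_to_set(in_pos[w, , drop = FALSE], solute_xyz)
    m_in_margin <- if (shell_in == "primary") pc - m_in
                   else min(sc - m_in, m_in - pc)

    d_out <- sc + max(3, 6 * jitter_sd)
    for (grow in 1:20) {
      cand <- apos + d_out * u
      m_out <- min_dist_to_set(matrix(cand, ncol = 3), solute_xyz)
      if (m_out - sc > 3 * jitter_sd) break
      d_out <- d_out + 2
    }
    out_pos[w, ] <- apos + d_out * u
    margin[w] <- min(if (!is.na(pattern_of[w])) m_in_margin else Inf,
                     m_out - sc)
  }
  if (any(3 * jitter_sd >= margin)) {
    bad <- which(3 * jitter_sd >= margin)[1]
    stop(sprintf(paste0("jitter_sd %.3f A can cross the shell boundary for ",
                        "water %d (margin %.3f A)"), jitter_sd, bad,
                 margin[bad]))
  }

  wm <- system$water_molecules
  coords <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- base_frame
    g <- trunc_jitter(jitter_sd)
    fr <- sweep(fr, 2, -g)   # rigid whole-system translation
    for (w in seq_len(n_w)) {
      inside <- FALSE
      if (!is.na(pattern_of[w])) {
        iv <- patterns[[pattern_of[w]]]$intervals
        inside <- any(iv[, 1] <= f & f <= iv[, 2])
      }
      target <- if (inside) in_pos[w, ] else out_pos[w, ]
      shift <- target + g + trunc_jitter(jitter_sd) - fr[wm[w, 1], ]
      fr[wm[w, ], ] <- sweep(fr[wm[w, ], , drop = FALSE], 2, -shift)
    }
    coords[[f]] <- fr
  }
  frame_series(coords, times = (seq_len(n_frames) - 1) * dt)
}

#' Synthetic amide-shift temperature series with known slopes
#'
#' Generates `shift(T) = intercept + slope * (T - T0) + noise` per residue,
#' shifts in ppm, slopes specified and stored as ground truth in ppb/K.
#'
#' @param slopes Named numeric vector: residue id -> slope in ppb/K.
#' @param temperatures Temperatures in K (>= 3 values). Default 281-320 K in
#'   5 K increments.
#' @param noise_sd Gaussian noise on each shift, in ppb.
#' @param seed Integer seed.
#' @param intercepts Optional named intercepts (ppm); random near 8.3 ppm
#'   otherwise.
#' @return An `"observable_table"` of kind `"tempseries"` whose
#'   `ground_truth` attribute stores the true slopes.
#' @export
make_nmr_tempseries <- function(slopes, temperatures = seq(281, 320, by = 5),
                                noise_sd = 0, seed = 1, intercepts = NULL) {
  if (length(temperatures) < 3) stop("need at least 3 temperatures")
  if (is.null(names(slopes)) || any(!nzchar(names(slopes)))) {
    stop("slopes must be a named vector (residue ids)")
  }
  set.seed(as.integer(seed))
  t0 <- min(temperatures)
  if (is.null(intercepts)) {
    intercepts <- stats::setNames(8.3 + stats::runif(length(slopes), -0.5, 0.5),
                                  names(slopes))
  }
  rows <- expand.grid(residue = names(slopes),
                      temperature_K = as.numeric(temperatures),
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$residue, names(slopes)), rows$temperature_K), ]
  slope_ppm <- slopes[rows$residue] / 1000
  rows$shift_ppm <- intercepts[rows$residue] +
    slope_ppm * (rows$temperature_K - t0) +
    stats::rnorm(nrow(rows), sd = noise_sd / 1000)
  truth <- data.frame(residue = names(slopes),
                      slope_ppb_per_K = as.numeric(slopes),
                      intercept_ppm = as.numeric(intercepts[names(slopes)]),
                      t0_K = t0, stringsAsFactors = FALSE)
  new_observable_table(rows, "tempseries", ground_truth = truth)
}

#' Synthetic hydrogen-deuterium exchange intensity table
#'
#' Per-residue mono-exponential decay `I(t) = exp(-k t)`, with `k = k_slow`
#' for the designated protected residues and `k = k_fast` otherwise. The
#' protected membership is stored as ground truth.
#'
#' @param residues Character or integer vector of all residue ids.
#' @param protected Subset of `residues` that exchange slowly.
#' @param k_fast Fast (unprotected) exchange rate, 1/h; must exceed `k_slow`.
#' @param k_slow Slow (protected) exchange rate, 1/h, >= 0.
#' @param times Exchange times in hours; must contain 0.
#' @param noise_sd Optional Gaussian intensity noise.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An `"observable_table"` of kind `"hdx"` with ground truth.
#' @export
make_hdx_table <- function(residues, protected = character(0), k_fast = 1.0,
                           k_slow = 0.01, times = c(0, 48), noise_sd = 0,
                           seed = 1) {
  stopifnot(k_fast > k_slow, k_slow >= 0)
  if (!0 %in% times) stop("times must include 0")
  residues <- as.character(residues)
  protected <- as.character(protected)
  if (!all(protected %in% residues)) {
    stop("protected residues must be a subset of residues")
  }
  set.seed(as.integer(seed))
  k <- ifelse(residues %in% protected, k_slow, k_fast)
  rows <- expand.grid(residue = residues, time_h = sort(as.numeric(times)),
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$residue, residues), rows$time_h), ]
  rows$intensity <- exp(-k[match(rows$residue, residues)] * rows$time_h) +
    if (noise_sd > 0) stats::rnorm(nrow(rows), sd = noise_sd) else 0
  truth <- data.frame(residue = residues,
                      protected = residues %in% protected,
                      rate_per_h = k, stringsAsFactors = FALSE)
  new_observable_table(rows, "hdx", ground_truth = truth)
}

#' Generate a variant set with controlled charged-residue enrichment
#'
#' Each variant differs from the template by exactly `extra_pos`
#' substitutions to K/R and `extra_neg` substitutions to D/E, at distinct
#' randomly chosen positions that are not already charged (not K/R/D/E). The
#' per-variant charge-count deltas are stored as ground truth.
#'
#' @param template Template amino-acid sequence (one-letter codes).
#' @param n_variants Number of variants (>= 0).
#' @param extra_pos Added positive (K/R) substitutions per variant.
#' @param extra_neg Added negative (D/E) substitutions per variant.
#' @param seed Integer seed.
#' @return Object of class `"design_set"`: list with `template`, `variants`
#'   (named character vector) and `ground_truth` (per-variant deltas).
#' @export
make_design_set <- function(template, n_variants, extra_pos, extra_neg,
                            seed = 1) {
  check_sequence(template, "template")
  stopifnot(n_variants >= 0, extra_pos >= 0, extra_neg >= 0)
  set.seed(as.integer(seed))
  chars <- strsplit(template, "")[[1]]
  open <- which(!chars %in% c("K", "R", "D", "E"))
  need <- extra_pos + extra_neg
  if (length(open) < need) {
    stop(sprintf("template has %d substitutable positions but %d are needed",
                 length(open), need))
  }
  variants <- character(n_variants)
  for (v in seq_len(n_variants)) {
    pos <- sample(open, need)
    vc <- chars
    if (extra_pos > 0) {
      vc[pos[seq_len(extra_pos)]] <- sample(c("K", "R"), extra_pos,
                                            replace = TRUE)
    }
    if (extra_neg > 0) {
      vc[pos[extra_pos + seq_len(extra_neg)]] <- sample(c("D", "E"), extra_neg,
                                                        replace = TRUE)
    }
    variants[v] <- paste(vc, collapse = "")
  }
  names(variants) <- sprintf("variant_%03d", seq_len(n_variants))
  truth <- data.frame(variant_id = names(variants),
                      delta_positive = rep(as.integer(extra_pos), n_variants),
                      delta_negative = rep(as.integer(extra_neg), n_variants),
                      stringsAsFactors = FALSE)
  structure(list(template = template, variants = variants,
                 ground_truth = truth),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf("Design set: %d variants over a %d-residue template\n",
              length(x$variants), nchar(x$template)))
  invisible(x)
}
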