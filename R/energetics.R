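# Coulomb constant in kcal * Angstrom / (mol * e^2)
COULOMB_K <- 332.0637

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Sums, over all cross pairs within `energy_cutoff`, the 12-6
#' Lennard-Jones term `4 eps [(sigma/r)^12 - (sigma/r)^6]` with
#' Lorentz-Berthelot mixing (arithmetic-mean sigma, geometric-mean epsilon)
#' and the Coulomb term `k_C q_i q_j / (eps_r r)` with
#' `k_C = 332.0637 kcal A / (mol e^2)`. Plain truncation at the cutoff: no
#' switching function, no long-range correction.
#'
#' @param frame Coordinate matrix.
#' @param system A [solvated_system()].
#' @param groupA,groupB Disjoint integer vectors of atom ids.
#' @param config An [analysis_config()] (cutoff and dielectric).
#' @return List of class `"energy_breakdown"`: `lj`, `coulomb`, `total`
#'   (kcal/mol) and `n_pairs_within_cutoff`.
#' @export
nonbonded_energy <- function(frame, system, groupA, groupB,
                             config = analysis_config()) {
  frame <- check_frame(frame, system)
  groupA <- as.integer(groupA); groupB <- as.integer(groupB)
  if (length(intersect(groupA, groupB)) > 0) {
    stop("groups overlap: ",
         paste(utils::head(intersect(groupA, groupB), 5), collapse = ", "))
  }
  a <- system$atoms
  need <- c(groupA, groupB)
  bad <- need[is.na(a$partial_charge[need]) | is.na(a$lj_sigma[need]) |
                is.na(a$lj_epsilon[need])]
  if (length(bad) > 0) {
    stop("missing charge/LJ parameters for atom(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (length(groupA) == 0 || length(groupB) == 0) {
    return(energy_breakdown(0, 0, 0L))
  }

  lj <- coulomb <- 0
  n_pairs <- 0L
  chunks <- split(groupB, ceiling(seq_along(groupB) / 3000))
  for (gb in chunks) {
    r <- cross_dist(frame[groupA, , drop = FALSE],
                    frame[gb, , drop = FALSE])
    within <- r <= config$energy_cutoff & r > 0
    if (!any(within)) next
    idx <- which(within, arr.ind = TRUE)
    i <- groupA[idx[, 1]]; j <- gb[idx[, 2]]
    rij <- r[within]
    sig <- (a$lj_sigma[i] + a$lj_sigma[j]) / 2
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    sr6 <- (sig / rij)^6
    lj <- lj + sum(4 * eps * (sr6^2 - sr6))
    coulomb <- coulomb +
      sum(COULOMB_K * a$partial_charge[i] * a$partial_charge[j] /
            (config$dielectric * rij))
    n_pairs <- n_pairs + length(rij)
  }
  energy_breakdown(lj, coulomb, n_pairs)
}

energy_breakdown <- function(lj, coulomb, n_pairs) {
  structure(list(lj = lj, coulomb = coulomb, total = lj + coulomb,
                 n_pairs_within_cutoff = as.integer(n_pairs)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("LJ %.4f + Coulomb %.4f = %.4f kcal/mol (%d pairs)\n",
              x$lj, x$coulomb, x$total, x$n_pairs_within_cutoff))
  invisible(x)
}

#' Protein-water interaction energy along a trajectory
#'
#' Per-frame [nonbonded_energy()] between the solute atoms and all water
#' atoms, plus the cumulative average of the total after the configured
#' burn-in.
#'
#' @param series A [frame_series()].
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @return List with `per_frame` (data.frame `frame`, `time`, `lj`,
#'   `coulomb`, `total`, `n_pairs`) and `cumulative`
#'   (see [cumulative_average()], applied to `total`).
#' @export
protein_water_energy_series <- function(series, system,
                                        config = analysis_config()) {
  stopifnot(inherits(series, "frame_series"))
  groupA <- system$solute_atom_ids
  groupB <- as.integer(system$water_molecules)
  per <- lapply(seq_along(series$coords), function(f) {
    e <- nonbonded_energy(series$coords[[f]], system, groupA, groupB, config)
    data.frame(frame = f, time = series$times[f], lj = e$lj,
               coulomb = e$coulomb, total = e$total,
               n_pairs = e$n_pairs_within_cutoff)
  })
  per <- do.call(rbind, per)
  list(per_frame = per,
       cumulative = cumulative_average(per$total, per$time,
                                       config$burn_in_time))
}

#' Radius of gyration of an atom selection
#'
#' `Rg = sqrt( sum m_i |r_i - r_com|^2 / sum m_i )` with the mass-weighted
#' centroid `r_com`; unit masses by default.
#'
#' @param frame Coordinate matrix.
#' @param selection Integer atom ids (default: all rows of `frame`).
#' @param masses Optional masses, one per selected atom.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL) {
  frame <- matrix(as.numeric(frame), ncol = 3)
  if (is.null(selection)) selection <- seq_len(nrow(frame))
  if (length(selection) == 0) stop("empty selection")
  x <- frame[selection, , drop = FALSE]
  if (is.null(masses)) masses <- rep(1, nrow(x))
  stopifnot(length(masses) == nrow(x))
  mtot <- sum(masses)
  if (mtot <= 0) stop("total mass must be positive")
  com <- colSums(x * masses) / mtot
  sqrt(sum(masses * rowSums(sweep(x, 2, com)^2)) / mtot)
}

#' Per-frame radius of gyration
#'
#' @param series A [frame_series()].
#' @param selection Atom ids (default all).
#' @param masses Optional masses.
#' @return data.frame with columns `frame`, `time`, `rg`.
#' @export
rg_series <- function(series, selection = NULL, masses = NULL) {
  stopifnot(inherits(series, "frame_series"))
  rg <- vapply(series$coords, radius_of_gyration, 0, selection = selection,
               masses = masses)
  data.frame(frame = seq_along(rg), time = series$times, rg = rg)
}

#' Detect an unfolding onset from an Rg series
#'
#' The baseline is the mean Rg over the first `baseline_window` frames; the
#' first frame whose Rg exceeds `factor` times that baseline is returned,
#' `NA` when the series never exceeds it.
#'
#' @param rg Numeric per-frame Rg series (or the data.frame from
#'   [rg_series()]).
#' @param baseline_window Number of leading frames defining the baseline
#'   (>= 2).
#' @param factor Exceedance factor (> 1), default 1.5.
#' @return Frame index of the first exceedance, or `NA_integer_`.
#' @export
detect_unfolding <- function(rg, baseline_window = max(2, length(rg) %/% 20),
                             factor = 1.5) {
  if (is.data.frame(rg)) rg <- rg$rg
  stopifnot(baseline_window >= 2, factor > 1)
  if (length(rg) < baseline_window) {
    stop("series shorter than the baseline window")
  }
  baseline <- mean(rg[seq_len(baseline_window)])
  hit <- which(rg > factor * baseline)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
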