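#' Assign waters to hydration shells for one frame
#'
#' For every water molecule the minimum Euclidean distance from its oxygen
#' to any solute heavy (non-hydrogen) atom is computed; the water is
#' `primary` when that distance is `<= primary_cutoff` (ties to the inner
#' shell), `secondary` when in `(primary_cutoff, secondary_cutoff]`, and
#' `bulk` beyond.
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @return data.frame with one row per water: `water_index`, `oxygen_atom`,
#'   `min_distance`, `shell` (factor primary/secondary/bulk).
#' @export
assign_shells <- function(frame, system, config = analysis_config()) {
  frame <- check_frame(frame, system)
  heavy <- solute_heavy_ids(system)
  if (length(heavy) == 0) stop("system has no solute heavy atoms")
  o_ids <- water_oxygen_ids(system)
  n_w <- length(o_ids)
  if (n_w == 0) {
    return(data.frame(water_index = integer(0), oxygen_atom = integer(0),
                      min_distance = numeric(0),
                      shell = shell_factor(character(0))))
  }
  d <- min_dist_to_set(frame[o_ids, , drop = FALSE],
                       frame[heavy, , drop = FALSE])
  shell <- ifelse(d <= config$primary_cutoff, "primary",
                  ifelse(d <= config$secondary_cutoff, "secondary", "bulk"))
  data.frame(water_index = seq_len(n_w), oxygen_atom = o_ids,
             min_distance = d, shell = shell_factor(shell))
}

shell_factor <- function(x) factor(x, levels = c("primary", "secondary",
                                                 "bulk"))

#' Per-frame hydration-shell water counts
#'
#' @param series A [frame_series()].
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @return data.frame with columns `frame`, `time`, `n_primary`,
#'   `n_secondary`, `n_bulk`; the three counts sum to the number of waters
#'   in every frame.
#' @export
shell_counts <- function(series, system, config = analysis_config()) {
  stopifnot(inherits(series, "frame_series"))
  res <- lapply(seq_along(series$coords), function(f) {
    sh <- assign_shells(series$coords[[f]], system, config)$shell
    tab <- table(sh)
    data.frame(frame = f, time = series$times[f],
               n_primary = as.integer(tab[["primary"]]),
               n_secondary = as.integer(tab[["secondary"]]),
               n_bulk = as.integer(tab[["bulk"]]))
  })
  do.call(rbind, res)
}

#' Residence runs of waters in a hydration shell
#'
#' A run is a maximal stretch of frames in which a water occupies the given
#' shell, allowing interior excursions of at most `gap_tolerance` consecutive
#' frames. Run length is counted in frames; `length_time` converts by the
#' frame spacing.
#'
#' @param series A [frame_series()].
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @param shell `"primary"`, `"secondary"` or `"bulk"`.
#' @param gap_tolerance Maximum interior excursion, in frames (>= 0). With a
#'   positive tolerance the frame spacing must be uniform (time-based run
#'   lengths are otherwise undefined).
#' @return List with `runs` (data.frame `water_index`, `shell`,
#'   `start_frame`, `length`, `length_time`) and `summary` (n_runs,
#'   mean/max length in frames and ps).
#' @export
residence_times <- function(series, system, config = analysis_config(),
                            shell = "primary", gap_tolerance = 0) {
  stopifnot(inherits(series, "frame_series"), gap_tolerance >= 0)
  shell <- match.arg(shell, c("primary", "secondary", "bulk"))
  n_frames <- length(series$coords)
  dts <- diff(series$times)
  uniform <- length(dts) == 0 || max(abs(dts - dts[1])) < 1e-9 * max(dts[1], 1)
  if (gap_tolerance > 0 && !uniform) {
    stop("gap_tolerance > 0 requires uniform frame spacing")
  }
  dt <- if (length(dts) > 0) mean(dts) else 1

  occ <- vapply(seq_len(n_frames), function(f) {
    as.character(assign_shells(series$coords[[f]], system, config)$shell) ==
      shell
  }, logical(nrow(system$water_molecules)))
  occ <- matrix(occ, ncol = n_frames)   # waters x frames

  runs <- list()
  for (w in seq_len(nrow(occ))) {
    v <- occ[w, ]
    if (gap_tolerance > 0) v <- fill_gaps(v, gap_tolerance)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep) > 0) {
      runs[[length(runs) + 1]] <- data.frame(
        water_index = w, shell = shell, start_frame = starts[keep],
        length = r$lengths[keep], length_time = r$lengths[keep] * dt)
    }
  }
  runs <- if (length(runs) > 0) do.call(rbind, runs) else {
    data.frame(water_index = integer(0), shell = character(0),
               start_frame = integer(0), length = integer(0),
               length_time = numeric(0))
  }
  rownames(runs) <- NULL
  summary <- list(
    n_runs = nrow(runs),
    mean_length = if (nrow(runs) > 0) mean(runs$length) else NA_real_,
    max_length = if (nrow(runs) > 0) max(runs$length) else NA_real_,
    mean_time = if (nrow(runs) > 0) mean(runs$length_time) else NA_real_,
    max_time = if (nrow(runs) > 0) max(runs$length_time) else NA_real_)
  list(runs = runs, summary = summary)
}

# set interior FALSE gaps of length <= tol to TRUE (gaps at either edge of
# the series are not interior and stay)
fill_gaps <- function(v, tol) {
  r <- rle(v)
  n <- length(r$values)
  if (n >= 3) {
    interior <- which(!r$values & r$lengths <= tol)
    interior <- interior[interior > 1 & interior < n]
    r$values[interior] <- TRUE
  }
  inverse.rle(r)
}

#' Monte-Carlo shell volume and water density
#'
#' The shell volume is estimated by rejection sampling: uniform points are
#' drawn in the solute heavy-atom bounding box padded by `secondary_cutoff`
#' on every side, and the fraction whose minimum distance to the solute
#' heavy atoms falls inside the shell's distance band, times the box volume,
#' estimates the shell volume. Density is the frame's shell water count per
#' estimated volume.
#'
#' @param frame Coordinate matrix.
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @param shell `"primary"` or `"secondary"`.
#' @param mc_samples Number of Monte-Carlo points (>= 1e4).
#' @param seed Integer seed.
#' @return List: `density` (waters per cubic Angstrom), `n_waters`, `volume`
#'   (cubic Angstrom), `volume_se` (Monte-Carlo standard error), `mc_samples`.
#' @export
shell_density <- function(frame, system, config = analysis_config(),
                          shell = "primary", mc_samples = 1e4,
                          seed = config$seed) {
  stopifnot(mc_samples >= 1e4)
  shell <- match.arg(shell, c("primary", "secondary"))
  frame <- check_frame(frame, system)
  heavy <- solute_heavy_ids(system)
  if (length(heavy) == 0) stop("system has no solute heavy atoms")
  ref <- frame[heavy, , drop = FALSE]
  pad <- config$secondary_cutoff
  lo <- apply(ref, 2, min) - pad
  hi <- apply(ref, 2, max) + pad
  box_vol <- prod(hi - lo)

  set.seed(as.integer(seed))
  pts <- cbind(stats::runif(mc_samples, lo[1], hi[1]),
               stats::runif(mc_samples, lo[2], hi[2]),
               stats::runif(mc_samples, lo[3], hi[3]))
  # chunked to bound the distance-matrix memory
  inside <- logical(mc_samples)
  idx <- split(seq_len(mc_samples), ceiling(seq_len(mc_samples) / 20000))
  for (ii in idx) {
    d <- min_dist_to_set(pts[ii, , drop = FALSE], ref)
    inside[ii] <- if (shell == "primary") d <= config$primary_cutoff else
      d > config$primary_cutoff & d <= config$secondary_cutoff
  }
  p_hat <- mean(inside)
  volume <- p_hat * box_vol
  if (volume <= 0) stop("estimated shell volume is zero; increase mc_samples")
  volume_se <- box_vol * sqrt(p_hat * (1 - p_hat) / mc_samples)
  n_w <- sum(as.character(assign_shells(frame, system, config)$shell) == shell)
  list(density = n_w / volume, n_waters = n_w, volume = volume,
       volume_se = volume_se, mc_samples = as.integer(mc_samples))
}

#' Cumulative (running) average after an equilibration burn-in
#'
#' Frames with `time < burn_in_time` are discarded; the k-th output value is
#' the mean of the first k retained values.
#'
#' @param values Per-frame numeric series.
#' @param times Frame times (ps), same length as `values`.
#' @param burn_in_time Burn-in span (ps).
#' @return data.frame with columns `time`, `value`, `cum_avg` over the
#'   retained frames.
#' @export
cumulative_average <- function(values, times = seq_along(values) - 1,
                               burn_in_time = 0) {
  stopifnot(length(values) == length(times))
  keep <- times >= burn_in_time
  if (!any(keep)) {
    stop(sprintf("burn-in of %g ps discards all %d frames", burn_in_time,
                 length(values)))
  }
  v <- values[keep]
  data.frame(time = times[keep], value = v,
             cum_avg = cumsum(v) / seq_along(v))
}
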