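box_stats <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             mean = mean(x))
}

#' Comparative hydration study of two trajectories
#'
#' Computes, for each trajectory and after the configured burn-in, the
#' per-frame distributions of: primary- and secondary-shell water counts,
#' protein-water hydrogen bonds, water-water hydrogen bonds per shell, and
#' the total protein-water interaction energy. Reports box-plot statistics
#' (min, Q1, median, Q3, max, mean) per metric and the A - B difference of
#' means.
#'
#' @param trajA,trajB Lists with elements `system` ([solvated_system()]) and
#'   `frames` ([frame_series()]), e.g. from [make_toy_system()] +
#'   [make_trajectory()].
#' @param config A single [analysis_config()] applied to both trajectories.
#' @param labels Length-2 character vector naming the trajectories.
#' @return Object of class `"hydration_study"`: list with `summary`
#'   (long data.frame of box statistics), `differences` (named numeric,
#'   mean A - mean B per metric), `per_frame` (list of the two per-frame
#'   metric tables) and `config`.
#' @export
run_hydration_study <- function(trajA, trajB, config = analysis_config(),
                                labels = c("A", "B")) {
  stopifnot(length(labels) == 2)
  metrics <- function(traj) {
    sc <- shell_counts(traj$frames, traj$system, config)
    hb <- hbond_counts(traj$frames, traj$system, config)
    en <- protein_water_energy_series(traj$frames, traj$system, config)
    keep <- sc$time >= config$burn_in_time
    if (!any(keep)) stop("burn-in discards all frames")
    data.frame(frame = sc$frame[keep], time = sc$time[keep],
               n_primary = sc$n_primary[keep],
               n_secondary = sc$n_secondary[keep],
               n_protein_water_hb = hb$n_protein_water[keep],
               n_water_water_hb_primary = hb$n_water_water_primary[keep],
               n_water_water_hb_secondary = hb$n_water_water_secondary[keep],
               energy_total = en$per_frame$total[keep])
  }
  mA <- metrics(trajA)
  mB <- metrics(trajB)
  cols <- setdiff(names(mA), c("frame", "time"))
  summary <- do.call(rbind, lapply(cols, function(cn) {
    rbind(cbind(metric = cn, label = labels[1], box_stats(mA[[cn]])),
          cbind(metric = cn, label = labels[2], box_stats(mB[[cn]])))
  }))
  rownames(summary) <- NULL
  differences <- vapply(cols, function(cn) mean(mA[[cn]]) - mean(mB[[cn]]), 0)
  structure(list(summary = summary, differences = differences,
                 per_frame = stats::setNames(list(mA, mB), labels),
                 config = config),
            class = "hydration_study")
}

#' @export
print.hydration_study <- function(x, ...) {
  cat("Comparative hydration study\n")
  print(x$summary, digits = 4)
  cat("\nDifferences of means (", names(x$per_frame)[1], " - ",
      names(x$per_frame)[2], "):\n", sep = "")
  print(round(x$differences, 4))
  invisible(x)
}

demo_assert <- function(ok, stage) {
  if (!isTRUE(ok)) stop("synthetic demo failed at stage: ", stage,
                        call. = FALSE)
  invisible(TRUE)
}

#' End-to-end synthetic study with ground-truth assertions
#'
#' Builds a "reference" toy system and an "enhanced-hydration" counterpart
#' (more primary-shell waters donating linear hydrogen bonds), trajectories
#' with prescribed occupancy, synthetic NMR temperature-series, HDX and
#' relaxation data, and a variant design set; runs every analysis stage and
#' asserts that each recovers the construction's ground truth. Writes stage
#' tables and a run manifest when `out_dir` is given.
#'
#' @param seed Integer seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for tables and the manifest.
#' @param n_frames Trajectory length in frames.
#' @param n_variants Design-set size.
#' @return Invisibly, a list of stage results (`study`, `tempco`, `hdx`,
#'   `tauc`, `enrichment`, `manifest`).
#' @export
run_synthetic_demo <- function(seed = 1, out_dir = NULL, n_frames = 40,
                               n_variants = 200) {
  seed <- as.integer(seed)
  config <- analysis_config(burn_in_time = 5, seed = seed)

  # -- hydration pair: reference vs enhanced ------------------------------
  ref_pl <- c(
    lapply(1:3, function(i) water_placement("primary", 2.8, hb_partner = 2 * i,
                                            hb_geometry = "linear")),
    lapply(1:3, function(i) water_placement("secondary")),
    lapply(1:2, function(i) water_placement("bulk")))
  enh_pl <- c(
    lapply(1:6, function(i) water_placement("primary", 2.8, hb_partner = 2 * i,
                                            hb_geometry = "linear")),
    lapply(1:4, function(i) water_placement("secondary")),
    lapply(1:2, function(i) water_placement("bulk")))
  ref <- make_toy_system(14, ref_pl, seed = seed)
  enh <- make_toy_system(14, enh_pl, seed = seed + 1)

  stay <- function(n_wat, n_primary, n_secondary) {
    c(lapply(seq_len(n_primary), function(w)
        occupancy_pattern(w, c(1, n_frames), shell = "primary")),
      lapply(n_primary + seq_len(n_secondary), function(w)
        occupancy_pattern(w, c(1, n_frames), shell = "secondary")))
  }
  trajR <- list(system = ref$system,
                frames = make_trajectory(ref, stay(8, 3, 3), n_frames,
                                         dt = 1, jitter_sd = 0.05,
                                         seed = seed + 2, config = config))
  trajE <- list(system = enh$system,
                frames = make_trajectory(enh, stay(12, 6, 4), n_frames,
                                         dt = 1, jitter_sd = 0.05,
                                         seed = seed + 3, config = config))

  scR <- shell_counts(trajR$frames, ref$system, config)
  scE <- shell_counts(trajE$frames, enh$system, config)
  demo_assert(all(scR$n_primary == 3) && all(scR$n_secondary == 3),
              "reference shell counts")
  demo_assert(all(scE$n_primary == 6) && all(scE$n_secondary == 4),
              "enhanced shell counts")

  study <- run_hydration_study(trajE, trajR, config,
                               labels = c("enhanced", "reference"))
  demo_assert(study$differences[["n_primary"]] == 3, "primary-count delta")
  demo_assert(study$differences[["n_protein_water_hb"]] > 0,
              "protein-water HB ordering")

  # -- NMR observables ----------------------------------------------------
  slopes <- c(I23 = -0.64, K27 = 0.49, T55 = 0.33, L71 = -5.3, G10 = -7.5)
  ts <- make_nmr_tempseries(slopes, noise_sd = 0, seed = seed + 4)
  tc <- temp_coefficient(ts, threshold = config$tempco_threshold)
  demo_assert(max(abs(tc$slope[match(names(slopes), tc$residue)] -
                        slopes)) < 1e-9, "temperature-coefficient recovery")
  demo_assert(identical(tc$hb_classified[match(c("I23", "L71"), tc$residue)],
                        c(TRUE, FALSE)), "temperature-coefficient thresholds")

  residues <- sprintf("R%02d", 1:76)
  protected <- residues[1:30]
  hdx <- make_hdx_table(residues, protected, k_fast = 1.0, k_slow = 0.01,
                        times = c(0, 48), seed = seed + 5)
  hp <- hdx_protection(hdx, t = 48, thresholds = config$hdx_threshold)
  demo_assert(unname(hp$counts[1]) == 30, "HDX protection count")

  tauc_true <- 4.15
  field <- 850
  ratio <- r2r1_from_tauc(tauc_true, field)
  tauc <- tauc_from_relaxation(r1 = 1.5, r2 = 1.5 * ratio, field_1H = field)
  demo_assert(abs(tauc - tauc_true) < 1e-6, "tau_c round trip")

  # -- sequence charges ---------------------------------------------------
  template <- paste(rep("GASTV", 16), collapse = "")   # 80-mer, uncharged
  ds <- make_design_set(template, n_variants, extra_pos = 4, extra_neg = 5,
                        seed = seed + 6)
  es <- enrichment_stats(ds)
  demo_assert(abs(es$mean_delta_pct_positive - 4 / 80 * 100) < 1e-12 &&
                abs(es$mean_delta_pct_negative - 5 / 80 * 100) < 1e-12,
              "enrichment recovery")

  manifest <- list(
    tool = paste("hydrashell",
                 as.character(utils::packageVersion("hydrashell"))),
    seed = seed,
    n_frames = n_frames,
    n_variants = n_variants,
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- list(study = study, tempco = tc, hdx = hp, tauc = tauc,
                 enrichment = es, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(study$summary, "study_summary.tsv")
    wt(data.frame(metric = names(study$differences),
                  mean_difference = unname(study$differences)),
       "study_differences.tsv")
    wt(tc, "temp_coefficients.tsv")
    wt(hp$results, "hdx_protection.tsv")
    wt(es$per_variant, "enrichment_per_variant.tsv")
    write_trajectory(ref$system, trajR$frames,
                     file.path(out_dir, "reference_trajectory.pdb"))
    write_trajectory(enh$system, trajE$frames,
                     file.path(out_dir, "enhanced_trajectory.pdb"))
    manifest$input_digests <- as.list(tools::md5sum(
      file.path(out_dir, c("reference_trajectory.pdb",
                           "enhanced_trajectory.pdb"))))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
    result$manifest <- manifest
  }
  invisible(result)
}
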