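#' Analysis configuration
#'
#' Bundle of every geometric and numerical cutoff used by the pipeline.
#' Defaults follow the standard hydration-analysis conventions: a primary
#' hydration shell within 3.5 Angstrom of solute heavy atoms, a secondary
#' shell out to 10 Angstrom, a geometric hydrogen-bond criterion of 3.5
#' Angstrom donor-acceptor distance with at most 30 degrees deviation from
#' linearity, a 12 Angstrom plain cutoff for nonbonded energies, and a
#' 40 ns (40000 ps) equilibration burn-in.
#'
#' @param primary_cutoff Outer radius of the primary hydration shell
#'   (Angstrom). A water belongs to the primary shell when the minimum
#'   distance from its oxygen to any solute heavy atom is `<=` this value.
#' @param secondary_cutoff Outer radius of the secondary shell (Angstrom);
#'   waters with minimum distance in `(primary_cutoff, secondary_cutoff]`
#'   are secondary, beyond that bulk.
#' @param hb_distance_cutoff Hydrogen-bond distance cutoff (Angstrom),
#'   applied to the donor-acceptor heavy-atom distance by default (see
#'   `hb_distance_mode`).
#' @param hb_angle_cutoff Maximum deviation of the donor-H...acceptor angle
#'   from linearity (degrees) for a hydrogen bond.
#' @param hb_distance_mode `"donor_acceptor"` (default) applies
#'   `hb_distance_cutoff` to the D-A heavy-atom distance; `"hydrogen_acceptor"`
#'   applies it to the H-A distance, for sensitivity checks.
#' @param energy_cutoff Pair-distance cutoff for nonbonded energies
#'   (Angstrom); plain truncation, no switching, no long-range correction.
#' @param dielectric Relative dielectric constant in the Coulomb term.
#' @param burn_in_time Equilibration span discarded before averaging (ps):
#'   frames with time strictly below this are dropped.
#' @param hdx_threshold Default intensity-ratio threshold for calling a
#'   residue protected in hydrogen-deuterium exchange.
#' @param tempco_threshold Temperature-coefficient threshold (ppb/K); slopes
#'   strictly above it are classified as intramolecularly hydrogen bonded.
#' @param charge_scheme `"KR_DE"` counts K/R positive and D/E negative with
#'   histidine neutral; `"KRH_DE"` adds histidine to the positives.
#' @param include_sulfur Whether sulfur participates as hydrogen-bond
#'   donor/acceptor (default `FALSE`).
#' @param water_residues Residue names recognised as water.
#' @param seed Default seed for stochastic stages (Monte-Carlo volume,
#'   generators).
#'
#' @return An object of class `"analysis_config"` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$primary_cutoff
analysis_config <- function(primary_cutoff = 3.5,
                            secondary_cutoff = 10.0,
                            hb_distance_cutoff = 3.5,
                            hb_angle_cutoff = 30,
                            hb_distance_mode = c("donor_acceptor", "hydrogen_acceptor"),
                            energy_cutoff = 12.0,
                            dielectric = 1.0,
                            burn_in_time = 40000,
                            hdx_threshold = 0.2,
                            tempco_threshold = -5.0,
                            charge_scheme = c("KR_DE", "KRH_DE"),
                            include_sulfur = FALSE,
                            water_residues = c("HOH", "WAT", "TIP3", "SOL"),
                            seed = 1L) {
  hb_distance_mode <- match.arg(hb_distance_mode)
  charge_scheme <- match.arg(charge_scheme)
  cfg <- list(
    primary_cutoff = as.numeric(primary_cutoff),
    secondary_cutoff = as.numeric(secondary_cutoff),
    hb_distance_cutoff = as.numeric(hb_distance_cutoff),
    hb_angle_cutoff = as.numeric(hb_angle_cutoff),
    hb_distance_mode = hb_distance_mode,
    energy_cutoff = as.numeric(energy_cutoff),
    dielectric = as.numeric(dielectric),
    burn_in_time = as.numeric(burn_in_time),
    hdx_threshold = as.numeric(hdx_threshold),
    tempco_threshold = as.numeric(tempco_threshold),
    charge_scheme = charge_scheme,
    include_sulfur = isTRUE(include_sulfur),
    water_residues = as.character(water_residues),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$primary_cutoff > 0,
    cfg$primary_cutoff < cfg$secondary_cutoff,
    cfg$hb_distance_cutoff > 0,
    cfg$hb_angle_cutoff > 0, cfg$hb_angle_cutoff < 90,
    cfg$energy_cutoff > 0,
    cfg$dielectric > 0,
    cfg$burn_in_time >= 0,
    cfg$hdx_threshold >= 0
  )
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()] exactly; keys absent from
#' the file keep their defaults. Unknown keys are an error, so typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"analysis_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param config An `"analysis_config"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Hydration analysis configuration\n")
  cat(sprintf("  shells: primary <= %.2f A, secondary <= %.2f A\n",
              x$primary_cutoff, x$secondary_cutoff))
  cat(sprintf("  H-bond: d(%s) <= %.2f A, deviation <= %.1f deg\n",
              if (x$hb_distance_mode == "donor_acceptor") "D-A" else "H-A",
              x$hb_distance_cutoff, x$hb_angle_cutoff))
  cat(sprintf("  energy: cutoff %.1f A, dielectric %.2f\n",
              x$energy_cutoff, x$dielectric))
  cat(sprintf("  burn-in: %g ps; charge scheme: %s\n",
              x$burn_in_time, x$charge_scheme))
  invisible(x)
}
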