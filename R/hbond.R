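#' Resolve hydrogen-bond donors and acceptors
#'
#' Donors are N or O heavy atoms carrying at least one covalently bound
#' hydrogen; acceptors are all N and O atoms (sulfur optionally included via
#' `config$include_sulfur`). Hydrogen attachment uses the system's bond list
#' when present; otherwise each hydrogen is attached to the nearest heavy
#' atom within 1.2 Angstrom of it in `frame`, and a hydrogen with no such
#' neighbour is an error.
#'
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @param frame Coordinates, required only when bonds must be inferred by
#'   proximity.
#' @return List with `donors` (data.frame `donor_atom`, `hydrogen_atom`, one
#'   row per D-H pair) and `acceptors` (integer atom ids).
#' @export
find_donors_acceptors <- function(system, config = analysis_config(),
                                  frame = NULL) {
  atoms <- system$atoms
  polar <- c("N", "O", if (config$include_sulfur) "S")
  h_ids <- which(atoms$is_hydrogen)
  heavy_of_h <- rep(NA_integer_, length(h_ids))

  if (nrow(system$bonds) > 0) {
    b <- system$bonds
    for (k in seq_len(nrow(b))) {
      i <- b[k, 1]; j <- b[k, 2]
      if (atoms$is_hydrogen[i] && !atoms$is_hydrogen[j]) {
        heavy_of_h[match(i, h_ids)] <- j
      } else if (atoms$is_hydrogen[j] && !atoms$is_hydrogen[i]) {
        heavy_of_h[match(j, h_ids)] <- i
      }
    }
  }
  unresolved <- which(is.na(heavy_of_h))
  if (length(unresolved) > 0) {
    if (is.null(frame)) {
      stop("hydrogens without bonds need a frame for proximity attachment")
    }
    frame <- check_frame(frame, system)
    heavy_ids <- which(!atoms$is_hydrogen)
    hp <- frame[h_ids[unresolved], , drop = FALSE]
    d <- cross_dist(hp, frame[heavy_ids, , drop = FALSE])
    nearest <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(nrow(d)), nearest)]
    orphan <- which(dmin > 1.2)
    if (length(orphan) > 0) {
      stop("hydrogen atom(s) with no heavy atom within 1.2 A: ",
           paste(h_ids[unresolved][orphan], collapse = ", "))
    }
    heavy_of_h[unresolved] <- heavy_ids[nearest]
  }

  donors <- data.frame(donor_atom = heavy_of_h, hydrogen_atom = h_ids)
  donors <- donors[atoms$element[donors$donor_atom] %in% polar, , drop = FALSE]
  rownames(donors) <- NULL
  acceptors <- which(atoms$element %in% polar)
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds in one frame by the geometric criterion
#'
#' A hydrogen bond is recorded for each (donor, H, acceptor) triple whose
#' donor-acceptor distance is within `hb_distance_cutoff` (or H-acceptor
#' distance, under `hb_distance_mode = "hydrogen_acceptor"`) and whose
#' D-H...A angle deviates from linearity by at most `hb_angle_cutoff`
#' degrees. Pairs within one water molecule are excluded; when several
#' hydrogens of one donor satisfy the criterion toward the same acceptor
#' only the best (smallest-deviation) hydrogen is kept, so one physical
#' bond is never counted twice. Records are classified `protein_water`,
#' `water_water` or `protein_protein`, and `shell_context` is the hydration
#' shell of the participating water (the donor water, for water-water
#' bonds; `other` for protein-protein).
#'
#' @param frame Coordinate matrix.
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @param da Optional precomputed [find_donors_acceptors()] result.
#' @return data.frame with columns `donor_atom`, `hydrogen_atom`,
#'   `acceptor_atom`, `da_distance`, `dha_deviation`, `hb_class`,
#'   `shell_context`.
#' @export
detect_hbonds <- function(frame, system, config = analysis_config(),
                          da = NULL) {
  frame <- check_frame(frame, system)
  if (is.null(da)) da <- find_donors_acceptors(system, config, frame)
  empty <- data.frame(donor_atom = integer(0), hydrogen_atom = integer(0),
                      acceptor_atom = integer(0), da_distance = numeric(0),
                      dha_deviation = numeric(0), hb_class = character(0),
                      shell_context = character(0))
  if (nrow(da$donors) == 0 || length(da$acceptors) == 0) return(empty)

  wat_of <- water_index_of_atoms(system)
  d_atoms <- da$donors$donor_atom
  h_atoms <- da$donors$hydrogen_atom
  a_atoms <- da$acceptors

  ref_atoms <- if (config$hb_distance_mode == "donor_acceptor") d_atoms else
    h_atoms
  dist_da <- cross_dist(frame[ref_atoms, , drop = FALSE],
                        frame[a_atoms, , drop = FALSE])
  cand <- which(dist_da <= config$hb_distance_cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  di <- d_atoms[cand[, 1]]
  hi <- h_atoms[cand[, 1]]
  ai <- a_atoms[cand[, 2]]
  keep <- di != ai &
    !(!is.na(wat_of[di]) & !is.na(wat_of[ai]) & wat_of[di] == wat_of[ai])
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]

  # deviation of the D-H...A angle from 180 degrees
  v1 <- frame[di, , drop = FALSE] - frame[hi, , drop = FALSE]
  v2 <- frame[ai, , drop = FALSE] - frame[hi, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  dev <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- dev <= config$hb_angle_cutoff
  if (!any(ok)) return(empty)
  di <- di[ok]; hi <- hi[ok]; ai <- ai[ok]; dev <- dev[ok]

  heavy_d <- sqrt(rowSums((frame[di, , drop = FALSE] -
                             frame[ai, , drop = FALSE])^2))
  rec <- data.frame(donor_atom = di, hydrogen_atom = hi, acceptor_atom = ai,
                    da_distance = heavy_d, dha_deviation = dev)
  # one record per (D, A) pair: keep the best-deviation hydrogen
  rec <- rec[order(rec$donor_atom, rec$acceptor_atom, rec$dha_deviation), ]
  rec <- rec[!duplicated(rec[c("donor_atom", "acceptor_atom")]), ]
  rownames(rec) <- NULL

  dw <- wat_of[rec$donor_atom]
  aw <- wat_of[rec$acceptor_atom]
  rec$hb_class <- ifelse(!is.na(dw) & !is.na(aw), "water_water",
                         ifelse(is.na(dw) & is.na(aw), "protein_protein",
                                "protein_water"))
  shells <- assign_shells(frame, system, config)
  wshell <- as.character(shells$shell)
  ctx_water <- ifelse(!is.na(dw), dw, aw)
  rec$shell_context <- ifelse(is.na(ctx_water), "other",
                              ifelse(wshell[ctx_water] == "bulk", "other",
                                     wshell[ctx_water]))
  rec
}

#' Per-frame hydrogen-bond counts
#'
#' Counts, per frame: all protein-water hydrogen bonds, and water-water
#' hydrogen bonds whose donor water sits in the primary or secondary shell.
#'
#' @param series A [frame_series()].
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @return data.frame with columns `frame`, `time`, `n_protein_water`,
#'   `n_water_water_primary`, `n_water_water_secondary`.
#' @export
hbond_counts <- function(series, system, config = analysis_config()) {
  stopifnot(inherits(series, "frame_series"))
  da <- find_donors_acceptors(system, config, series$coords[[1]])
  res <- lapply(seq_along(series$coords), function(f) {
    hb <- detect_hbonds(series$coords[[f]], system, config, da = da)
    ww <- hb[hb$hb_class == "water_water", , drop = FALSE]
    data.frame(frame = f, time = series$times[f],
               n_protein_water = sum(hb$hb_class == "protein_water"),
               n_water_water_primary = sum(ww$shell_context == "primary"),
               n_water_water_secondary = sum(ww$shell_context == "secondary"))
  })
  do.call(rbind, res)
}

#' Per-residue hydrogen-bond map over a trajectory
#'
#' Protein-water hydrogen bonds are attributed to the protein residue of
#' their protein partner; water-water hydrogen bonds are attributed to every
#' solute residue with a heavy atom within `primary_cutoff` of either
#' participating water oxygen. Values are means over the frames retained
#' after `burn_in` (ps).
#'
#' @param series A [frame_series()].
#' @param system A [solvated_system()].
#' @param config An [analysis_config()].
#' @param burn_in Burn-in time in ps (default 0: all frames).
#' @return data.frame with columns `residue_index`, `mean_protein_water`,
#'   `mean_water_water`.
#' @export
per_residue_hbond_map <- function(series, system, config = analysis_config(),
                                  burn_in = 0) {
  stopifnot(inherits(series, "frame_series"))
  keep <- which(series$times >= burn_in)
  if (length(keep) == 0) stop("burn-in discards all frames")
  atoms <- system$atoms
  solute_res <- sort(unique(atoms$residue_index[system$solute_atom_ids]))
  pw <- ww <- stats::setNames(numeric(length(solute_res)),
                              as.character(solute_res))
  da <- find_donors_acceptors(system, config, series$coords[[keep[1]]])
  o_ids <- water_oxygen_ids(system)
  heavy <- solute_heavy_ids(system)

  for (f in keep) {
    frame <- series$coords[[f]]
    hb <- detect_hbonds(frame, system, config, da = da)
    p <- hb[hb$hb_class == "protein_water", , drop = FALSE]
    if (nrow(p) > 0) {
      prot_atom <- ifelse(is.na(water_index_of_atoms(system)[p$donor_atom]),
                          p$donor_atom, p$acceptor_atom)
      t_ <- table(as.character(atoms$residue_index[prot_atom]))
      pw[names(t_)] <- pw[names(t_)] + as.integer(t_)
    }
    w <- hb[hb$hb_class == "water_water", , drop = FALSE]
    if (nrow(w) > 0) {
      wat_of <- water_index_of_atoms(system)
      for (k in seq_len(nrow(w))) {
        o1 <- o_ids[wat_of[w$donor_atom[k]]]
        o2 <- o_ids[wat_of[w$acceptor_atom[k]]]
        d1 <- sqrt(rowSums(sweep(frame[heavy, , drop = FALSE], 2,
                                 frame[o1, ])^2))
        d2 <- sqrt(rowSums(sweep(frame[heavy, , drop = FALSE], 2,
                                 frame[o2, ])^2))
        near <- unique(atoms$residue_index[heavy[
          d1 <= config$primary_cutoff | d2 <= config$primary_cutoff]])
        near <- as.character(near)
        ww[near] <- ww[near] + 1
      }
    }
  }
  n <- length(keep)
  data.frame(residue_index = solute_res,
             mean_protein_water = as.numeric(pw) / n,
             mean_water_water = as.numeric(ww) / n)
}
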