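#' Read a (multi-model) PDB file into a system plus frame series
#'
#' Each `MODEL` block becomes one frame; a file without `MODEL` records is a
#' single frame. Waters are identified by residue name (`HOH`, `WAT`, `TIP3`,
#' `SOL` by default), hydrogens by the element columns 77-78 with a
#' leading-`H` atom-name fallback. Partial charges and Lennard-Jones
#' parameters are not part of PDB; they can be supplied through `param_table`
#' (matched on residue name + atom name) and otherwise stay `NA`, except that
#' recognised waters receive TIP3P-like defaults when `water_defaults = TRUE`.
#'
#' @param path Path to a PDB file.
#' @param config An [analysis_config()]; supplies the water residue-name
#'   allowlist.
#' @param param_table Optional data.frame with columns `residue_name`,
#'   `atom_name`, `partial_charge`, `lj_sigma`, `lj_epsilon`.
#' @param param_file Optional path to a delimited file with those columns
#'   (used when `param_table` is `NULL`).
#' @param water_defaults Assign TIP3P-like charges (O -0.834 e, H +0.417 e)
#'   and oxygen-only LJ to recognised waters lacking explicit parameters.
#' @param times Optional frame times (ps); defaults to `0, 1, ...` frames.
#'
#' @return A list with elements `system` ([solvated_system()]) and
#'   `frames` ([frame_series()]).
#' @export
read_structure <- function(path, config = analysis_config(),
                           param_table = NULL, param_file = NULL,
                           water_defaults = TRUE, times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  n <- nrow(atom)
  if (n == 0) stop("no ATOM/HETATM records in ", path)

  element <- trimws(atom$elesy)
  infer <- !nzchar(element) | is.na(element)
  if (any(infer)) element[infer] <- infer_element(atom$elety[infer])
  element <- normalize_element(element)

  atoms <- data.frame(
    atom_id = seq_len(n),
    atom_name = trimws(atom$elety),
    element = element,
    residue_name = trimws(atom$resid),
    residue_index = as.integer(atom$resno),
    chain_id = ifelse(is.na(atom$chain) | !nzchar(atom$chain), "A",
                      as.character(atom$chain)),
    partial_charge = NA_real_,
    lj_sigma = NA_real_,
    lj_epsilon = NA_real_,
    stringsAsFactors = FALSE
  )
  atoms$is_water <- atoms$residue_name %in% config$water_residues
  atoms$is_hydrogen <- atoms$element == "H"

  if (is.null(param_table) && !is.null(param_file)) {
    param_table <- utils::read.table(param_file, header = TRUE, sep = "",
                                     stringsAsFactors = FALSE)
  }
  if (!is.null(param_table)) {
    atoms <- apply_param_table(atoms, param_table)
  }
  if (water_defaults) atoms <- apply_tip3p_defaults(atoms)

  wm <- build_water_molecules(atoms)
  solute_ids <- setdiff(seq_len(n), as.integer(wm))
  bonds <- water_oh_bonds(wm, atoms)
  system <- solvated_system(atoms, bonds = bonds, water_molecules = wm,
                            solute_atom_ids = solute_ids)

  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  list(system = system, frames = frame_series(coords, times = times))
}

# Pre-scan the raw lines: per-model atom counts must agree and every
# coordinate field must parse, otherwise error with the offending line.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)
  for (i in atom_lines) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      field <- substr(lines[i], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(field)))) {
        stop(sprintf("unparseable coordinate field %s on line %d of %s",
                     dQuote(trimws(field)), i, path))
      }
    }
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1) {
      stop(sprintf("inconsistent atom count across models in %s: %s",
                   path, paste(counts, collapse = ", ")))
    }
    attr(counts, "n_models") <- length(model_starts)
    return(invisible(counts))
  }
  invisible(length(atom_lines))
}

infer_element <- function(atom_name) {
  nm <- trimws(atom_name)
  # hydrogens named 1H.., 2H.., H.., HB2 etc.
  el <- substr(gsub("^[0-9]+", "", nm), 1, 1)
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("NA", "CL", "MG", "ZN", "FE", "BR")] <-
    c("Na", "Cl", "Mg", "Zn", "Fe", "Br")[match(
      two[two %in% c("NA", "CL", "MG", "ZN", "FE", "BR")],
      c("NA", "CL", "MG", "ZN", "FE", "BR"))]
  el
}

normalize_element <- function(el) {
  el <- trimws(el)
  one <- nchar(el) == 1
  el[one] <- toupper(el[one])
  el[!one] <- paste0(toupper(substr(el[!one], 1, 1)),
                     tolower(substr(el[!one], 2, nchar(el[!one]))))
  el
}

apply_param_table <- function(atoms, param_table) {
  req <- c("residue_name", "atom_name", "partial_charge", "lj_sigma",
           "lj_epsilon")
  missing_cols <- setdiff(req, names(param_table))
  if (length(missing_cols) > 0) {
    stop("param table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(atoms$residue_name, atoms$atom_name)
  pkey <- paste(param_table$residue_name, param_table$atom_name)
  if (anyDuplicated(pkey)) stop("duplicate residue/atom keys in param table")
  hit <- match(key, pkey)
  ok <- !is.na(hit)
  atoms$partial_charge[ok] <- param_table$partial_charge[hit[ok]]
  atoms$lj_sigma[ok] <- param_table$lj_sigma[hit[ok]]
  atoms$lj_epsilon[ok] <- param_table$lj_epsilon[hit[ok]]
  atoms
}

# TIP3P-like water parameters: charges on all three sites, LJ on oxygen only
apply_tip3p_defaults <- function(atoms) {
  w <- atoms$is_water
  no_q <- w & is.na(atoms$partial_charge)
  atoms$partial_charge[no_q & !atoms$is_hydrogen] <- -0.834
  atoms$partial_charge[no_q & atoms$is_hydrogen] <- 0.417
  no_lj <- w & is.na(atoms$lj_sigma)
  atoms$lj_sigma[no_lj & !atoms$is_hydrogen] <- 3.15061
  atoms$lj_epsilon[w & is.na(atoms$lj_epsilon) & !atoms$is_hydrogen] <- 0.1521
  atoms$lj_sigma[w & is.na(atoms$lj_sigma)] <- 0
  atoms$lj_epsilon[w & is.na(atoms$lj_epsilon)] <- 0
  atoms
}

build_water_molecules <- function(atoms) {
  widx <- which(atoms$is_water)
  if (length(widx) == 0) return(matrix(integer(0), ncol = 3))
  grp <- paste(atoms$chain_id[widx], atoms$residue_index[widx],
               atoms$residue_name[widx])
  parts <- split(widx, grp)
  wm <- lapply(parts, function(ids) {
    if (length(ids) != 3) {
      stop(sprintf("water residue with %d atoms (ids %s); expected O,H,H",
                   length(ids), paste(ids, collapse = ",")))
    }
    o <- ids[!atoms$is_hydrogen[ids]]
    h <- ids[atoms$is_hydrogen[ids]]
    if (length(o) != 1) {
      stop("water residue without exactly one heavy atom: ids ",
           paste(ids, collapse = ","))
    }
    c(o, h)
  })
  wm <- do.call(rbind, wm)
  wm[order(wm[, 1]), , drop = FALSE]
}

water_oh_bonds <- function(wm, atoms) {
  if (nrow(wm) == 0) return(matrix(integer(0), ncol = 2))
  rbind(cbind(wm[, 1], wm[, 2]), cbind(wm[, 1], wm[, 3]))
}

#' Write a system and its frames as a multi-model PDB
#'
#' One `MODEL` block per frame, fixed-column PDB with the element symbol in
#' columns 77-78, so that [read_structure()] round-trips coordinates to the
#' 1e-3 Angstrom precision of the format. Charges/LJ parameters are not part
#' of PDB; use [write_param_table()] alongside when they must survive.
#'
#' @param system A [solvated_system()].
#' @param frames A [frame_series()] (or a single `n x 3` matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(system, frames, path) {
  if (is.matrix(frames)) frames <- frame_series(frames)
  stopifnot(inherits(system, "solvated_system"),
            inherits(frames, "frame_series"))
  if (frames$n_atoms != nrow(system$atoms)) {
    stop("frame series does not match system atom count")
  }
  a <- system$atoms
  xyz <- do.call(rbind, lapply(frames$coords, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = a$atom_id, elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

#' Write a side-car nonbonded parameter table
#'
#' @param system A [solvated_system()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_param_table <- function(system, path) {
  a <- system$atoms
  tab <- unique(data.frame(residue_name = a$residue_name,
                           atom_name = a$atom_name,
                           partial_charge = a$partial_charge,
                           lj_sigma = a$lj_sigma,
                           lj_epsilon = a$lj_epsilon,
                           stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
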