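#' Solvated system container
#'
#' Holds the static description of a solute-plus-water system: one row per
#' atom, covalent bonds, the water-molecule index and the solute partition.
#' Coordinates live separately in a [frame_series()] so one topology can be
#' paired with many frames.
#'
#' @param atoms data.frame with columns `atom_id` (integer, 1..n), `atom_name`,
#'   `element`, `residue_name`, `residue_index`, `chain_id`,
#'   `partial_charge` (e), `lj_sigma` (Angstrom), `lj_epsilon` (kcal/mol),
#'   `is_water` (logical), `is_hydrogen` (logical). Charges/LJ may be `NA`
#'   when not supplied; energy routines check for them.
#' @param bonds two-column integer matrix of bonded atom-id pairs (may have
#'   zero rows).
#' @param water_molecules three-column integer matrix, one row per water,
#'   columns `O`, `H1`, `H2` (atom ids).
#' @param solute_atom_ids integer vector of solute atom ids.
#'
#' @return Object of class `"solvated_system"`.
#' @export
solvated_system <- function(atoms, bonds = matrix(integer(0), ncol = 2),
                            water_molecules = matrix(integer(0), ncol = 3),
                            solute_atom_ids = integer(0)) {
  req <- c("atom_id", "atom_name", "element", "residue_name", "residue_index",
           "chain_id", "partial_charge", "lj_sigma", "lj_epsilon",
           "is_water", "is_hydrogen")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, req]
  n <- nrow(atoms)
  if (any(!nzchar(atoms$element))) stop("every atom needs a non-empty element")
  if (!identical(atoms$is_hydrogen, atoms$element == "H")) {
    stop("is_hydrogen must match element == 'H'")
  }
  if (any(atoms$lj_sigma < 0, na.rm = TRUE) ||
      any(atoms$lj_epsilon < 0, na.rm = TRUE)) {
    stop("LJ parameters must be non-negative")
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (max(bonds) > n || min(bonds) < 1)) {
    stop("bonds reference atoms outside the system")
  }
  water_molecules <- matrix(as.integer(water_molecules), ncol = 3)
  solute_atom_ids <- as.integer(solute_atom_ids)
  wat_ids <- as.integer(water_molecules)
  if (length(intersect(solute_atom_ids, wat_ids)) > 0) {
    stop("solute and water atom sets overlap")
  }
  if (!setequal(c(solute_atom_ids, wat_ids), seq_len(n))) {
    stop("solute and water atom sets must partition all atoms")
  }
  if (nrow(water_molecules) > 0) {
    n_heavy <- rowSums(matrix(!atoms$is_hydrogen[water_molecules],
                              ncol = 3))
    if (any(n_heavy != 1L)) {
      stop("each water triple must have exactly one non-hydrogen atom")
    }
  }
  structure(list(atoms = atoms, bonds = bonds,
                 water_molecules = water_molecules,
                 solute_atom_ids = solute_atom_ids),
            class = "solvated_system")
}

#' @export
print.solvated_system <- function(x, ...) {
  cat(sprintf("Solvated system: %d atoms (%d solute, %d waters)\n",
              nrow(x$atoms), length(x$solute_atom_ids),
              nrow(x$water_molecules)))
  invisible(x)
}

# solute heavy-atom ids (the reference set for shell distances)
solute_heavy_ids <- function(system) {
  ids <- system$solute_atom_ids
  ids[!system$atoms$is_hydrogen[ids]]
}

# oxygen atom id per water (the single non-hydrogen member of each triple)
water_oxygen_ids <- function(system) {
  wm <- system$water_molecules
  if (nrow(wm) == 0) return(integer(0))
  hyd <- matrix(system$atoms$is_hydrogen[wm], ncol = 3)
  wm[cbind(seq_len(nrow(wm)), max.col(!hyd, ties.method = "first"))]
}

# atom id -> water index (NA for non-water atoms)
water_index_of_atoms <- function(system) {
  idx <- rep(NA_integer_, nrow(system$atoms))
  wm <- system$water_molecules
  if (nrow(wm) > 0) idx[as.integer(wm)] <- rep(seq_len(nrow(wm)), 3)
  idx
}

#' Ordered coordinate frames
#'
#' The trajectory abstraction every metric consumes: a list of `n_atoms x 3`
#' coordinate matrices (Angstrom) with strictly increasing time stamps (ps).
#'
#' @param coords A single `n x 3` matrix or a list of them, all with the same
#'   number of rows.
#' @param times Numeric vector of frame times in ps, strictly increasing;
#'   defaults to `0, 1, 2, ...`.
#' @param box Optional orthorhombic box lengths (length-3 numeric, Angstrom).
#' @return Object of class `"frame_series"`.
#' @export
frame_series <- function(coords, times = NULL, box = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  stopifnot(length(coords) >= 1)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  n_atoms <- nrow(coords[[1]])
  if (!all(vapply(coords, nrow, 0L) == n_atoms)) {
    stop("all frames must have the same number of atoms")
  }
  if (is.null(times)) times <- seq_len(length(coords)) - 1
  times <- as.numeric(times)
  if (length(times) != length(coords)) {
    stop("times must have one entry per frame")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(list(n_atoms = n_atoms, coords = coords, times = times, box = box),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("Frame series: %d frames x %d atoms, t = %g..%g ps\n",
              length(x$coords), x$n_atoms, x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$coords)

check_frame <- function(frame, system) {
  frame <- as.matrix(frame)
  if (nrow(frame) != nrow(system$atoms) || ncol(frame) != 3) {
    stop(sprintf("frame has %d x %d coordinates but the system has %d atoms",
                 nrow(frame), ncol(frame), nrow(system$atoms)))
  }
  storage.mode(frame) <- "double"
  frame
}

# Minimum Euclidean distance from each row of `points` to the rows of `ref`.
# Vectorised |p - r|^2 = |p|^2 + |r|^2 - 2 p.r expansion; clamped at zero
# before the square root to absorb round-off.
min_dist_to_set <- function(points, ref) {
  points <- matrix(as.numeric(points), ncol = 3)
  ref <- matrix(as.numeric(ref), ncol = 3)
  if (nrow(ref) == 0) stop("reference point set is empty")
  if (nrow(points) == 0) return(numeric(0))
  d2 <- outer(rowSums(points^2), rowSums(ref^2), "+") -
    2 * tcrossprod(points, ref)
  sqrt(pmax(apply(d2, 1, min), 0))
}

# Full cross pair-distance matrix (rows of a x rows of b)
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
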