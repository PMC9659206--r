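#' Molecular structure container
#'
#' A `structure3d` is the package's central container: an ordered atom table
#' plus an explicit bond graph. All downstream analyses (remodelling, metal-site
#' geometry, trajectory statistics) consume only this type and [trajectory3d].
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `chain`, `insert`, `altloc`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `het` (logical: HETATM record). Missing optional
#'   columns are filled with defaults.
#' @param bonds two-column integer matrix of atom indices (unordered pairs),
#'   or NULL for no recorded bonds.
#' @param title free-text title.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, bonds = NULL, title = "") {
  defaults <- list(serial = seq_len(nrow(atoms)), element = "", res_name = "UNK",
                   res_id = 1L, chain = "A", insert = "", altloc = "",
                   occupancy = 1, b_factor = 0, het = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  stopifnot(all(c("name", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$b_factor < 0)) stop("negative B-factor")
  atoms$res_id <- as.integer(atoms$res_id)
  rownames(atoms) <- NULL
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > nrow(atoms)))
      stop("bond indices out of range")
    bonds <- normalize_bonds(bonds)
  }
  key <- paste(atoms$chain, atoms$res_id, atoms$insert, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_id, name, altloc) among atoms: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out <- list(atoms = atoms, bonds = bonds, title = title)
  class(out) <- "structure3d"
  out
}

# canonical bond representation: i < j, unique rows, sorted
normalize_bonds <- function(bonds) {
  if (!nrow(bonds)) return(matrix(integer(0), ncol = 2))
  b <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  b <- unique(b)
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues, %d bonds%s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "res_id", "insert")])),
              nrow(x$bonds),
              if (nzchar(x$title)) paste0(" -- ", x$title) else ""))
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#' @param s a [structure3d].
#' @return n x 3 numeric matrix (angstrom).
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s a [structure3d].
#' @param xyz n x 3 numeric matrix.
#' @return the updated structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "structure3d"), nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Trajectory container
#'
#' Ordered coordinate frames over a fixed topology with an explicit frame
#' spacing in picoseconds.
#'
#' @param topology a [structure3d] whose atoms define the frame layout.
#' @param frames list of n_atoms x 3 coordinate matrices (angstrom).
#' @param frame_spacing_ps picoseconds between consecutive frames (> 0).
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, frames, frame_spacing_ps = 40) {
  stopifnot(inherits(topology, "structure3d"), frame_spacing_ps > 0,
            length(frames) >= 1)
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n)
      stop(sprintf("frame %d has %d atoms, topology has %d",
                   i, nrow(frames[[i]]), n))
  }
  out <- list(topology = topology, frames = frames,
              frame_spacing_ps = frame_spacing_ps)
  class(out) <- "trajectory3d"
  out
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("trajectory3d: %d frames x %d atoms, %g ps/frame (%g ns total)\n",
              length(x$frames), nrow(x$topology$atoms), x$frame_spacing_ps,
              length(x$frames) * x$frame_spacing_ps / 1000))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory3d].
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Select atoms of a structure
#'
#' Filters the atom table by any combination of chain, residue id (scalar,
#' vector or range), residue name, atom name and element. Criteria combine
#' with AND; each accepts a vector of allowed values. Returns indices in the
#' original atom order.
#'
#' @param s a [structure3d].
#' @param chain,res_id,res_name,atom_name,element optional filters.
#' @param het NULL for all records, TRUE/FALSE to restrict to HETATM/ATOM.
#' @return integer vector of atom indices (possibly empty, with a warning).
#' @export
select_atoms <- function(s, chain = NULL, res_id = NULL, res_name = NULL,
                         atom_name = NULL, element = NULL, het = NULL) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))     keep <- keep & a$chain %in% chain
  if (!is.null(res_id))    keep <- keep & a$res_id %in% as.integer(res_id)
  if (!is.null(res_name))  keep <- keep & a$res_name %in% res_name
  if (!is.null(atom_name)) keep <- keep & a$name %in% atom_name
  if (!is.null(element))   keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(het))       keep <- keep & a$het == het
  idx <- which(keep)
  if (!length(idx)) warning("selection matched no atoms")
  idx
}

# index of a single named atom; errors if absent or ambiguous
atom_index <- function(s, res_id, name, chain = NULL) {
  a <- s$atoms
  hit <- which(a$res_id == res_id & a$name == name &
                 (if (is.null(chain)) TRUE else a$chain == chain))
  if (length(hit) == 0)
    stop(sprintf("atom %s of residue %d not found", name, res_id))
  if (length(hit) > 1)
    stop(sprintf("atom %s of residue %d is ambiguous (specify chain)", name, res_id))
  hit
}

# coordinates of a single named atom
atom_xyz <- function(s, res_id, name, chain = NULL) {
  unlist(s$atoms[atom_index(s, res_id, name, chain), c("x", "y", "z")],
         use.names = FALSE)
}
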